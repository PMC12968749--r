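#' Cluster accessions on genetic similarity
#'
#' Partitions accessions into `k` clusters by iterative reassignment on their
#' allele-sharing similarity, the stratification step of diverse-set
#' selection. Each accession is represented by its row of the similarity
#' matrix, so a cluster center is the vector of average similarities between
#' the cluster's members and every accession. Each iteration assigns every
#' accession to the center offering it the highest average similarity (ties
#' broken toward the lowest cluster index), then recomputes centers as
#' cluster means; iteration stops when no label changes, when a pass would
#' increase the mean within-cluster dissimilarity (the pass is rejected), or
#' at `max_iter`.
#'
#' Initialization is a seeded farthest-point scheme: the first center is a
#' uniformly drawn accession and each further center is the accession with
#' the largest distance to its nearest chosen center. After convergence, any
#' accessions at distance exactly 0 from each other are merged into a single
#' label; if that empties a cluster, the emptied label is reseeded with the
#' distinct-genotype unit least similar to its current center. The merge pass
#' is skipped (with a warning) when `k` exceeds the number of distinct
#' genotypes, where nonempty clusters and co-labelled duplicates cannot both
#' hold.
#'
#' @param D An `ibs_dist` object from [pairwise_distance()].
#' @param k Number of clusters, `1 <= k <= n` accessions.
#' @param seed Integer seed; identical inputs and seed give identical labels.
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `cluster_assignment`: list with `k`, `labels`
#'   (named integer vector, values in `0:(k-1)`), `n_iterations`,
#'   `converged`, `seed` and `objective` (mean within-cluster dissimilarity
#'   after each assignment pass).
#' @examples
#' sim <- simulate_collection(n_accessions = 40, n_snps = 300, seed = 7)
#' A <- kmeans_cluster(pairwise_distance(sim$genotypes), k = 5, seed = 1)
#' cluster_sizes(A)
#' @export
kmeans_cluster <- function(D, k, seed = 1, max_iter = 100) {
  stopifnot(inherits(D, "ibs_dist"))
  n <- length(D$accession_ids)
  check_scalar_number(k, "k", min = 1)
  if (k != round(k)) abort_fmt("`k` must be an integer")
  if (k > n) abort_fmt("k = %d exceeds the %d accessions", k, n)
  k <- as.integer(k)
  S <- similarity(D)
  d <- D$d

  # seeded farthest-point initialization
  set.seed(derive_seed(seed, 101))
  centers_idx <- integer(k)
  centers_idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    dmin <- d[, centers_idx[1L]]
    for (c in 2L:k) {
      cand <- which.max(dmin)           # ties -> lowest index
      centers_idx[c] <- cand
      dmin <- pmin(dmin, d[, cand])
    }
  }
  centers <- S[centers_idx, , drop = FALSE]   # k x n

  lab <- integer(0)
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    new_lab <- max.col(t(centers), ties.method = "first")
    new_lab <- fix_empty_clusters(new_lab, centers, k)
    if (length(lab) && identical(new_lab, lab)) {
      converged <- TRUE
      iter <- iter - 1L                 # confirming pass changed nothing
      break
    }
    obj <- within_cluster_dissimilarity(d, new_lab, k)
    if (length(objective) && obj > objective[length(objective)] + 1e-12) {
      converged <- TRUE                 # pass would worsen the partition
      iter <- iter - 1L
      break
    }
    objective <- c(objective, obj)
    lab <- new_lab
    centers <- cluster_means(S, lab, k)
  }
  if (!length(lab)) lab <- new_lab

  lab <- merge_zero_distance(lab, d, S, k)
  lab <- as.integer(factor(lab, levels = sort(unique(lab)))) # compact, but keep k labels
  # relabel to 0-based contiguous order of first appearance of original labels
  labels <- lab - 1L
  names(labels) <- D$accession_ids
  structure(list(k = k, labels = labels, n_iterations = iter,
                 converged = converged, seed = seed, objective = objective),
            class = "cluster_assignment")
}

# mean over accessions of their average distance to co-members (0 for singletons)
within_cluster_dissimilarity <- function(d, lab, k) {
  tot <- 0
  for (c in seq_len(k)) {
    idx <- which(lab == c)
    if (length(idx) > 1L) {
      tot <- tot + sum(d[idx, idx]) / (length(idx) - 1L)
    }
  }
  tot / length(lab)
}

cluster_means <- function(S, lab, k) {
  centers <- matrix(0, k, ncol(S))
  for (c in seq_len(k)) {
    idx <- which(lab == c)
    centers[c, ] <- if (length(idx) == 1L) S[idx, ] else colMeans(S[idx, , drop = FALSE])
  }
  centers
}

# reassign the weakest-affiliated accession of a multi-member cluster to any
# label that came out empty
fix_empty_clusters <- function(lab, centers, k) {
  repeat {
    empty <- setdiff(seq_len(k), unique(lab))
    if (!length(empty)) return(lab)
    aff <- centers[cbind(lab, seq_along(lab))]
    movable <- lab %in% which(tabulate(lab, k) > 1L)
    aff[!movable] <- Inf
    lab[which.min(aff)] <- empty[1L]
  }
}

# post-pass: force zero-distance accessions into one label, then repair any
# emptied clusters by pulling in the least-affiliated distinct-genotype unit
merge_zero_distance <- function(lab, d, S, k) {
  adj <- d == 0
  diag(adj) <- FALSE
  if (!any(adj)) return(lab)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  units <- comp$membership
  n_units <- comp$no
  if (k > n_units) {
    warning(sprintf(paste0("k = %d exceeds the %d distinct genotypes; ",
                           "zero-distance accessions left in separate clusters"),
                    k, n_units), call. = FALSE)
    return(lab)
  }
  for (u in which(tabulate(units, n_units) > 1L)) {
    idx <- which(units == u)
    lab[idx] <- lab[idx[1L]]
  }
  repeat {
    empty <- setdiff(seq_len(k), unique(lab))
    if (!length(empty)) return(lab)
    centers <- cluster_means(S, lab, k)
    heads <- which(!duplicated(units))            # one accession per unit
    aff <- centers[cbind(lab[heads], heads)]
    sizes <- table(factor(lab[heads], levels = seq_len(k)))
    movable <- sizes[lab[heads]] > 1L             # keep donor clusters nonempty
    aff[!movable] <- Inf
    mv <- heads[which.min(aff)]
    lab[units == units[mv]] <- empty[1L]
  }
}

#' Cluster sizes of an assignment
#'
#' @param A A `cluster_assignment`.
#' @return Named integer vector: label (0-based) to member count.
#' @export
cluster_sizes <- function(A) {
  stopifnot(inherits(A, "cluster_assignment"))
  out <- tabulate(A$labels + 1L, A$k)
  names(out) <- as.character(0:(A$k - 1L))
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sz <- cluster_sizes(x)
  cat(sprintf("cluster_assignment: %d accessions in k = %d clusters (seed %d)\n",
              length(x$labels), x$k, x$seed))
  cat(sprintf("  %s after %d iteration(s); cluster sizes %d-%d\n",
              if (x$converged) "converged" else "iteration cap reached",
              x$n_iterations, min(sz), max(sz)))
  invisible(x)
}
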