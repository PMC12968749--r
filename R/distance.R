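#' Pairwise allele-sharing genetic distances
#'
#' Computes the identity-by-state distance between every pair of accessions:
#' \deqn{d_{ij} = \sum_l g_{ij,l} / N_{ij}} where the per-locus difference
#' \eqn{g} is 0 for identical homozygotes, 1 for opposite homozygotes, 0.5
#' for a heterozygote against a homozygote, and — by default — 1 for two
#' heterozygotes. Loci with a missing call in either accession are excluded
#' from both the numerator and the compared-locus count \eqn{N_{ij}}.
#'
#' The heterozygote-vs-heterozygote weight of 1 treats two heterozygous calls
#' as fully different. Under genotypic identity two heterozygotes at a
#' biallelic locus carry the same alleles, so `het_het = 0` is offered as an
#' alternative convention; all other rules are unaffected. Distance is
#' invariant under swapping which allele is coded 0 vs 2 at any locus.
#'
#' @param G A [genotype_matrix()].
#' @param het_het Per-locus difference assigned to a het/het pair: `1`
#'   (default) or `0`.
#' @return An object of class `ibs_dist`: a list with `accession_ids`, the
#'   symmetric distance matrix `d` (diagonal 0), the symmetric
#'   compared-locus-count matrix `n_loci` (diagonal = the accession's
#'   non-missing call count) and the `het_het` rule used.
#' @examples
#' G <- simulate_collection(n_accessions = 20, n_snps = 200, seed = 1)$genotypes
#' D <- pairwise_distance(G)
#' range(D$d)
#' @export
pairwise_distance <- function(G, het_het = 1) {
  if (!nrow(G) || !ncol(G)) abort_fmt("genotype matrix is empty")
  if (!het_het %in% c(0, 1)) abort_fmt("`het_het` must be 0 or 1")
  X <- unclass(G)
  A <- matrix(0, nrow(X), ncol(X)); A[!is.na(X) & X == 0L] <- 1
  B <- matrix(0, nrow(X), ncol(X)); B[!is.na(X) & X == 1L] <- 1
  C <- matrix(0, nrow(X), ncol(X)); C[!is.na(X) & X == 2L] <- 1
  N <- tcrossprod(A + B + C)
  AC <- tcrossprod(A, C)
  AB <- tcrossprod(A, B)
  BC <- tcrossprod(B, C)
  gsum <- AC + t(AC) + 0.5 * (AB + t(AB) + BC + t(BC)) +
    het_het * tcrossprod(B)
  Nint <- round(N)
  zero <- which(Nint == 0 & upper.tri(Nint), arr.ind = TRUE)
  if (nrow(zero)) {
    abort_fmt("distance undefined for pair (%s, %s): no shared non-missing loci",
              rownames(X)[zero[1L, 1L]], rownames(X)[zero[1L, 2L]])
  }
  d <- gsum / N
  diag(d) <- 0
  dimnames(d) <- list(rownames(X), rownames(X))
  storage.mode(Nint) <- "integer"
  dimnames(Nint) <- dimnames(d)
  structure(list(accession_ids = rownames(X), d = d, n_loci = Nint,
                 het_het = het_het),
            class = "ibs_dist")
}

#' @export
print.ibs_dist <- function(x, ...) {
  n <- length(x$accession_ids)
  off <- x$d[upper.tri(x$d)]
  cat(sprintf("ibs_dist: %d accessions, %d pairs (het/het rule = %g)\n",
              n, length(off), x$het_het))
  if (length(off)) {
    cat(sprintf("  distance range [%.4f, %.4f], mean %.4f; zero-distance pairs: %d\n",
                min(off), max(off), mean(off), sum(off == 0)))
  }
  invisible(x)
}

#' Similarity matrix from a distance object
#'
#' @param D An `ibs_dist` object.
#' @return The symmetric matrix `1 - d` (diagonal 1).
#' @export
similarity <- function(D) {
  stopifnot(inherits(D, "ibs_dist"))
  1 - D$d
}

#' Redundancy groups of near-identical accessions
#'
#' Single-linkage grouping: accessions are joined by an edge wherever their
#' similarity (`1 - d`) strictly exceeds `threshold`, and the connected
#' components of that graph with at least two members are the redundancy
#' groups. Under single linkage, membership in a group is exactly "similar to
#' at least one other accession above the threshold". The count of accessions
#' that are 100% identical to at least one other accession is reported
#' alongside.
#'
#' @param D An `ibs_dist` object.
#' @param threshold Similarity threshold in (0, 1); default `0.999`
#'   (">99.9% identity").
#' @return An object of class `redundancy_groups`: list with `threshold`,
#'   `groups` (list of accession-id character vectors, each of size >= 2,
#'   largest first), `n_in_groups` and `n_identical` (accessions at distance
#'   exactly 0 from some other accession).
#' @export
redundancy_groups <- function(D, threshold = 0.999) {
  stopifnot(inherits(D, "ibs_dist"))
  check_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1) abort_fmt("`threshold` must be in (0, 1)")
  s <- similarity(D)
  adj <- s > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  keep <- which(comp$csize >= 2L)
  groups <- lapply(keep, function(ci) D$accession_ids[comp$membership == ci])
  groups <- groups[order(-lengths(groups))]
  identical_any <- apply(D$d == 0 & !diag(TRUE, nrow(D$d)), 1L, any)
  structure(list(threshold = threshold, groups = groups,
                 n_in_groups = sum(lengths(groups)),
                 n_identical = sum(identical_any)),
            class = "redundancy_groups")
}

#' @export
print.redundancy_groups <- function(x, ...) {
  cat(sprintf("redundancy_groups: %d groups at similarity > %g\n",
              length(x$groups), x$threshold))
  cat(sprintf("  accessions in groups: %d; 100%% identical to another: %d\n",
              x$n_in_groups, x$n_identical))
  if (length(x$groups)) {
    sz <- lengths(x$groups)
    cat(sprintf("  group sizes: %s\n",
                paste(utils::head(sort(sz, decreasing = TRUE), 10L),
                      collapse = ", ")))
  }
  invisible(x)
}
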