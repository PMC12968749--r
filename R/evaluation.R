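#' Polymorphic-SNP retention of a subset
#'
#' A SNP counts as retained in a subset when at least two distinct alleles
#' are observed among the subset's non-missing calls; a heterozygous call
#' contributes both alleles, so a single heterozygote retains the SNP. The
#' percentage is taken against one of two denominators: the full panel SNP
#' count (`"panel"`, the whole-collection convention) or the number of SNPs
#' polymorphic within a reference accession set (`"reference_polymorphic"`,
#' the per-MG convention, defaulting to the whole collection as reference).
#'
#' @param G A [genotype_matrix()].
#' @param subset Character vector of accession ids (non-empty, all in `G`).
#' @param denominator_mode `"panel"` or `"reference_polymorphic"`.
#' @param reference Accession ids defining the reference panel when
#'   `denominator_mode = "reference_polymorphic"`; defaults to all
#'   accessions of `G`.
#' @return An object of class `retention_report`: list with `subset_size`,
#'   `polymorphic_snps`, `total_snps_denominator` and `percent_retained`.
#' @export
polymorphic_retention <- function(G, subset,
                                  denominator_mode = c("panel",
                                                       "reference_polymorphic"),
                                  reference = NULL) {
  denominator_mode <- match.arg(denominator_mode)
  subset <- as.character(subset)
  if (!length(subset)) abort_fmt("`subset` must be non-empty")
  missing_ids <- setdiff(subset, rownames(G))
  if (length(missing_ids)) abort_fmt("unknown accession in subset: %s",
                                     missing_ids[1L])
  npoly <- sum(polymorphic_snp_mask(G, subset))
  denom <- if (denominator_mode == "panel") {
    ncol(G)
  } else {
    ref <- if (is.null(reference)) rownames(G) else as.character(reference)
    sum(polymorphic_snp_mask(G, ref))
  }
  pct <- if (denom == 0) 0 else 100 * npoly / denom
  structure(list(subset_size = length(subset), polymorphic_snps = npoly,
                 total_snps_denominator = denom, percent_retained = pct),
            class = "retention_report")
}

polymorphic_snp_mask <- function(G, subset) {
  X <- unclass(G)[subset, , drop = FALSE]
  has_het <- colSums(X == 1L, na.rm = TRUE) > 0L
  has0 <- colSums(X == 0L, na.rm = TRUE) > 0L
  has2 <- colSums(X == 2L, na.rm = TRUE) > 0L
  has_het | (has0 & has2)
}

#' @export
print.retention_report <- function(x, ...) {
  cat(sprintf("retention_report: %d accessions retain %d / %d SNPs (%.2f%%)\n",
              x$subset_size, x$polymorphic_snps, x$total_snps_denominator,
              x$percent_retained))
  invisible(x)
}

#' Replicate comparison of diverse sets against random sets
#'
#' For each requested sample size the collection is clustered once at
#' `k = size`, then `replicates` diverse sets (one random pick per cluster,
#' independently seeded) and `replicates` random sets are drawn and their
#' polymorphic-SNP retention computed. Per size the report carries each
#' arm's mean, min, max and SD of the retained percentages and a two-sample
#' Welch t-test of DS vs RS with significance flags at the 5% and 1% levels.
#'
#' @param G A [genotype_matrix()].
#' @param sizes Integer vector of subset sizes (each `<= n` accessions).
#' @param replicates Replicates per arm (default 10, minimum 2).
#' @param seed Integer master seed; every clustering and draw derives its own
#'   sub-seed from it.
#' @param meta Optional accession metadata forwarded to
#'   [build_diverse_set()].
#' @param denominator_mode,reference Retention denominator convention, see
#'   [polymorphic_retention()].
#' @param het_het Heterozygote rule for [pairwise_distance()].
#' @param D Optional precomputed `ibs_dist` for `G` (skips recomputation).
#' @return An object of class `comparison_report`: list with `summary` (one
#'   row per size), `replicates` (per-size DS and RS percent vectors),
#'   `n_replicates` and `seed`.
#' @examples
#' sim <- simulate_collection(n_accessions = 60, n_snps = 400, seed = 3)
#' compare_ds_rs(sim$genotypes, sizes = c(10, 20), replicates = 5, seed = 1)
#' @export
compare_ds_rs <- function(G, sizes, replicates = 10, seed = 1, meta = NULL,
                          denominator_mode = "panel", reference = NULL,
                          het_het = 1, D = NULL) {
  check_scalar_number(replicates, "replicates", min = 2)
  sizes <- as.integer(sizes)
  bad <- sizes[sizes > nrow(G) | sizes < 1L]
  if (length(bad)) abort_fmt("size %d exceeds the %d accessions", bad[1L], nrow(G))
  if (is.null(D)) D <- pairwise_distance(G, het_het = het_het)
  ids <- rownames(G)
  rep_list <- list()
  rows <- list()
  for (s in sizes) {
    A <- kmeans_cluster(D, s, seed = derive_seed(seed, 503, s))
    ds_pct <- vapply(seq_len(replicates), function(r) {
      ds <- build_diverse_set(A, meta = meta, seed = derive_seed(seed, 509, s, r))
      polymorphic_retention(G, ds$picks$accession_id, denominator_mode,
                            reference)$percent_retained
    }, numeric(1L))
    rs_pct <- vapply(seq_len(replicates), function(r) {
      rs <- build_random_set(ids, s, seed = derive_seed(seed, 521, s, r))
      polymorphic_retention(G, rs, denominator_mode, reference)$percent_retained
    }, numeric(1L))
    tt <- welch_or_constant(ds_pct, rs_pct)
    rows[[length(rows) + 1L]] <- data.frame(
      size = s,
      ds_mean = mean(ds_pct), ds_min = min(ds_pct), ds_max = max(ds_pct),
      ds_sd = sd(ds_pct),
      rs_mean = mean(rs_pct), rs_min = min(rs_pct), rs_max = max(rs_pct),
      rs_sd = sd(rs_pct),
      t_statistic = tt$statistic, p_value = tt$p.value,
      significant_at_5pct = tt$p.value < 0.05,
      significant_at_1pct = tt$p.value < 0.01)
    rep_list[[as.character(s)]] <- list(ds = ds_pct, rs = rs_pct)
  }
  structure(list(summary = do.call(rbind, rows), replicates = rep_list,
                 n_replicates = as.integer(replicates), seed = seed),
            class = "comparison_report")
}

# Welch t-test that degrades gracefully when both arms are constant
# (no variation to capture -> no evidence of a difference)
welch_or_constant <- function(a, b) {
  out <- tryCatch(t.test(a, b, var.equal = FALSE),
                  error = function(e) NULL)
  if (!is.null(out) && is.finite(out$p.value)) {
    list(statistic = unname(out$statistic), p.value = out$p.value)
  } else {
    list(statistic = NA_real_,
         p.value = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: %d replicates per arm (seed %d)\n",
              x$n_replicates, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  size %4d: DS %.2f%% (sd %.2f)  RS %.2f%% (sd %.2f)  p = %.3g%s\n",
                s$size[i], s$ds_mean[i], s$ds_sd[i], s$rs_mean[i], s$rs_sd[i],
                s$p_value[i],
                if (isTRUE(s$significant_at_1pct[i])) " **"
                else if (isTRUE(s$significant_at_5pct[i])) " *" else ""))
  }
  invisible(x)
}

#' Consistency of retention estimated from a SNP subset
#'
#' Checks whether diversity retention predicted from a reduced SNP panel
#' transfers to the full panel: a random SNP subset is drawn, diverse sets
#' are built on the subset's distances, and each diverse set's retention is
#' computed twice — against the SNP subset and against all SNPs — reporting
#' the per-size difference of means.
#'
#' @param G A [genotype_matrix()].
#' @param subset_snp_count Number of SNPs to draw (at most the panel size).
#' @param sizes Integer vector of diverse-set sizes.
#' @param replicates Diverse-set replicates per size.
#' @param seed Integer master seed.
#' @param het_het Heterozygote rule for [pairwise_distance()].
#' @return Data frame with one row per size: `size`, `mean_subset_pct`,
#'   `mean_full_pct`, `mean_difference` (subset minus full).
#' @export
retention_consistency <- function(G, subset_snp_count, sizes, replicates = 10,
                                  seed = 1, het_het = 1) {
  m <- ncol(G)
  check_scalar_number(subset_snp_count, "subset_snp_count", min = 1)
  if (subset_snp_count > m) {
    abort_fmt("subset_snp_count = %d exceeds the %d SNPs", subset_snp_count, m)
  }
  set.seed(derive_seed(seed, 601))
  snp_sub <- sort(sample.int(m, subset_snp_count))
  Gsub <- G[, snp_sub]
  Dsub <- pairwise_distance(Gsub, het_het = het_het)
  rows <- list()
  for (s in as.integer(sizes)) {
    A <- kmeans_cluster(Dsub, s, seed = derive_seed(seed, 607, s))
    sub_pct <- full_pct <- numeric(replicates)
    for (r in seq_len(replicates)) {
      ds <- build_diverse_set(A, seed = derive_seed(seed, 613, s, r))
      picks <- ds$picks$accession_id
      sub_pct[r] <- polymorphic_retention(Gsub, picks, "panel")$percent_retained
      full_pct[r] <- polymorphic_retention(G, picks, "panel")$percent_retained
    }
    rows[[length(rows) + 1L]] <- data.frame(
      size = s, mean_subset_pct = mean(sub_pct),
      mean_full_pct = mean(full_pct),
      mean_difference = mean(sub_pct) - mean(full_pct))
  }
  do.call(rbind, rows)
}

#' Histogram of pairwise distances
#'
#' Bins the unordered pairwise distances with a dedicated bin for exact-zero
#' distances (identical accessions) and lower-open, upper-closed interval
#' bins, so a distance equal to an upper edge falls in that bin and nothing
#' is double-counted. Distances above the last edge go to an overflow bin.
#'
#' @param D An `ibs_dist` object.
#' @param bin_edges Strictly increasing positive upper edges; the default
#'   `0.05, 0.10, ..., 0.50` gives bins `0`, `(0, 0.05]`, `(0.05, 0.10]`, ...
#' @return An object of class `distance_distribution`: list with `table`
#'   (bin label, count), `n_pairs`, `n_below_0.10` (pairs with `d < 0.10`,
#'   zeros included), `mean` and `sd` over all pairs.
#' @export
distance_distribution <- function(D, bin_edges = seq(0.05, 0.50, by = 0.05)) {
  stopifnot(inherits(D, "ibs_dist"))
  if (any(diff(bin_edges) <= 0) || any(bin_edges <= 0)) {
    abort_fmt("`bin_edges` must be strictly increasing and positive")
  }
  dvals <- D$d[upper.tri(D$d)]
  zero <- sum(dvals == 0)
  pos <- dvals[dvals > 0]
  breaks <- c(0, bin_edges, Inf)
  cnt <- tabulate(findInterval(pos, breaks, left.open = TRUE), length(breaks) - 1L)
  labs <- c(sprintf("(%g, %g]", breaks[seq_along(bin_edges)], bin_edges),
            sprintf("> %g", bin_edges[length(bin_edges)]))
  tab <- data.frame(bin = c("0", labs), count = c(zero, cnt),
                    stringsAsFactors = FALSE)
  if (tab$count[nrow(tab)] == 0L) tab <- tab[-nrow(tab), , drop = FALSE]
  structure(list(table = tab, n_pairs = length(dvals),
                 n_below_0.10 = sum(dvals < 0.10),
                 mean = mean(dvals), sd = sd(dvals)),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("distance_distribution: %d pairs, mean %.3f, sd %.3f, d<0.10: %d\n",
              x$n_pairs, x$mean, x$sd, x$n_below_0.10))
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  %-12s %d\n", x$table$bin[i], x$table$count[i]))
  }
  invisible(x)
}

#' Plateau size of a retention curve
#'
#' The smallest sample size after which the retention curve has flattened:
#' the first size such that every later consecutive step gains less than
#' `epsilon` percentage points. The last size never qualifies vacuously, so
#' a curve that is still climbing returns `NA`.
#'
#' @param curve Named numeric vector: names are sample sizes, values mean
#'   percent retained. At least two points.
#' @param epsilon Per-step gain (percentage points) below which the curve
#'   counts as flat.
#' @return The plateau size (numeric) or `NA` if the curve never flattens.
#' @examples
#' plateau_size(c(`25` = 80, `100` = 92, `300` = 96, `500` = 96.4,
#'                `700` = 96.5), epsilon = 0.5)
#' @export
plateau_size <- function(curve, epsilon) {
  sizes <- as.numeric(names(curve))
  if (length(curve) < 2L || anyNA(sizes)) {
    abort_fmt("`curve` needs >= 2 points named by their sizes")
  }
  if (any(diff(sizes) <= 0)) abort_fmt("sizes must be strictly increasing")
  check_scalar_number(epsilon, "epsilon", min = 0)
  gains <- diff(as.numeric(curve))
  for (i in seq_len(length(curve) - 1L)) {
    if (all(gains[i:length(gains)] < epsilon)) return(sizes[i])
  }
  NA_real_
}
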