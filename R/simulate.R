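#' Simulate a structured inbred germplasm collection
#'
#' Generates a genotype matrix and metadata table with the statistical
#' features a large selfing-crop genebank panel shows: several
#' subpopulations, a sizeable share of exact and near-duplicate accessions,
#' low residual heterozygosity, missing calls, and maturity-group labels
#' correlated with subpopulation.
#'
#' Ancestral allele frequencies are drawn uniformly on
#' `[maf_floor, 1 - maf_floor]`; each subpopulation's frequencies follow a
#' Balding-Nichols beta around the ancestral frequency with spread set by
#' `fst`, so one knob controls how separable the subpopulations are.
#' Subpopulation sizes are geometrically skewed (largest to smallest about
#' 20:1), as genebank strata are: the small strata carry the rare,
#' subpopulation-private alleles whose capture separates stratified from
#' random sampling. Unique
#' accessions are sampled as mostly homozygous genotypes (heterozygote
#' probability `het_rate` per locus). A `duplicate_fraction` share of the
#' collection belongs to duplicate groups: group sizes are drawn from a
#' skewed (geometric, minimum 2) distribution — many pairs, few large
#' groups — and each non-head member copies an earlier member of its group
#' with per-locus re-randomization probability `near_dup_error_rate`.
#' Missing calls are applied last. Maturity groups are assigned by
#' subpopulation (subpopulations spread across the MG scale) with small
#' random spillover into adjacent MGs; duplicates inherit their source's MG.
#'
#' @param n_accessions,n_snps Collection dimensions.
#' @param n_subpops Number of subpopulations (`<= n_accessions`).
#' @param fst Differentiation parameter in (0, 1); higher separates
#'   subpopulations more cleanly.
#' @param duplicate_fraction Fraction of accessions belonging to duplicate
#'   groups (heads plus copies), in `[0, 1)`.
#' @param near_dup_error_rate Per-locus probability that a copy re-draws its
#'   call instead of inheriting it.
#' @param het_rate Per-locus residual heterozygosity probability. The
#'   default `1e-4` reflects processed selfing-crop array data, where
#'   residual heterozygous calls are rare; note that under the default
#'   het/het = 1 distance rule a shared heterozygous call keeps even exact
#'   duplicates off distance 0, so raising this materially changes
#'   redundancy behaviour.
#' @param missing_rate Per-call missing probability.
#' @param maf_floor Minimum ancestral allele frequency, in `[0, 0.5)`.
#' @param seed Integer seed; the whole collection is reproducible from it.
#' @return List with `genotypes` (a [genotype_matrix()]) and `meta` (an
#'   [accession_meta()] table). The true duplicate groups and subpopulation
#'   assignment are attached as attributes `duplicate_groups` and `subpop`
#'   of `genotypes`.
#' @examples
#' sim <- simulate_collection(n_accessions = 50, n_snps = 300, seed = 2)
#' sim$genotypes
#' @export
simulate_collection <- function(n_accessions = 500, n_snps = 5000,
                                n_subpops = 10, fst = 0.25,
                                duplicate_fraction = 0.25,
                                near_dup_error_rate = 1e-4,
                                het_rate = 1e-4, missing_rate = 0.02,
                                maf_floor = 0.005, seed = 1) {
  check_scalar_number(n_accessions, "n_accessions", min = 1)
  check_scalar_number(n_snps, "n_snps", min = 1)
  check_scalar_number(n_subpops, "n_subpops", min = 1)
  if (n_subpops > n_accessions) {
    abort_fmt("n_subpops = %d exceeds n_accessions = %d", n_subpops, n_accessions)
  }
  check_scalar_number(fst, "fst")
  if (fst <= 0 || fst >= 1) abort_fmt("`fst` must be in (0, 1)")
  check_scalar_number(duplicate_fraction, "duplicate_fraction", min = 0)
  if (duplicate_fraction >= 1) abort_fmt("`duplicate_fraction` must be < 1")
  for (nm in c("near_dup_error_rate", "het_rate", "missing_rate")) {
    check_scalar_number(get(nm), nm, min = 0, max = 1)
  }
  check_scalar_number(maf_floor, "maf_floor", min = 0, max = 0.5)
  n <- as.integer(n_accessions)
  m <- as.integer(n_snps)
  K <- as.integer(n_subpops)

  set.seed(derive_seed(seed, 701))
  p_anc <- runif(m, maf_floor, 1 - maf_floor)
  shp <- (1 - fst) / fst
  p_sub <- matrix(0, K, m)
  for (s in seq_len(K)) {
    p_sub[s, ] <- pmin(pmax(rbeta(m, p_anc * shp, (1 - p_anc) * shp),
                            1e-6), 1 - 1e-6)
  }

  # duplicate-group structure: skewed sizes, total = duplicate_fraction * n
  n_red <- round(duplicate_fraction * n)
  if (n_red == 1L) n_red <- 0L
  grp_sizes <- integer(0)
  while (sum(grp_sizes) < n_red) {
    grp_sizes <- c(grp_sizes, 2L + stats::rgeom(1L, prob = 0.35))
  }
  if (length(grp_sizes)) {
    over <- sum(grp_sizes) - n_red
    last <- length(grp_sizes)
    if (grp_sizes[last] - over >= 2L) {
      grp_sizes[last] <- grp_sizes[last] - over
    } else {
      grp_sizes <- grp_sizes[-last]
      short <- n_red - sum(grp_sizes)
      if (short == 1L && length(grp_sizes)) {
        grp_sizes[1L] <- grp_sizes[1L] + 1L
      } else if (short >= 2L) {
        grp_sizes <- c(grp_sizes, short)
      }
    }
  }
  n_copies <- sum(pmax(grp_sizes - 1L, 0L))
  n_fresh <- n - n_copies

  # fresh genotypes over subpopulations of geometrically skewed sizes
  # (genebank strata are heavily unbalanced; small strata carry the private
  # alleles whose capture separates stratified from random sampling)
  w <- exp(-0.35 * (seq_len(K) - 1L))
  counts <- pmax(2L, round(n_fresh * w / sum(w)))
  while (sum(counts) > n_fresh) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n_fresh) counts[which.max(w)] <- counts[which.max(w)] + 1L
  subpop <- integer(n)
  subpop[seq_len(n_fresh)] <- sample(rep(seq_len(K), counts))
  calls <- matrix(NA_integer_, n, m)
  for (i in seq_len(n_fresh)) {
    p <- p_sub[subpop[i], ]
    g <- ifelse(runif(m) < p, 2L, 0L)
    g[runif(m) < het_rate] <- 1L
    calls[i, ] <- g
  }

  # heads drawn among fresh accessions; copies fill the tail rows
  duplicate_groups <- list()
  if (length(grp_sizes)) {
    heads <- sample.int(n_fresh, length(grp_sizes))
    nxt <- n_fresh + 1L
    for (gi in seq_along(grp_sizes)) {
      members <- heads[gi]
      for (j in seq_len(grp_sizes[gi] - 1L)) {
        src <- members[sample.int(length(members), 1L)]
        g <- calls[src, ]
        redo <- runif(m) < near_dup_error_rate
        if (any(redo)) {
          p <- p_sub[subpop[src], redo, drop = TRUE]
          gnew <- ifelse(runif(sum(redo)) < p, 2L, 0L)
          gnew[runif(sum(redo)) < het_rate] <- 1L
          g[redo] <- gnew
        }
        calls[nxt, ] <- g
        subpop[nxt] <- subpop[src]
        members <- c(members, nxt)
        nxt <- nxt + 1L
      }
      duplicate_groups[[gi]] <- members
    }
  }

  if (missing_rate > 0) {
    calls[matrix(runif(n * m) < missing_rate, n, m)] <- NA_integer_
  }

  # maturity groups: subpopulations spread along the MG scale, +-1 spillover
  base_mg <- round(seq(1, length(mg_levels), length.out = K))
  mg_idx <- base_mg[subpop]
  shift <- sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(0.05, 0.9, 0.05))
  mg_idx <- pmin(pmax(mg_idx + shift, 1L), length(mg_levels))
  for (grp in duplicate_groups) mg_idx[grp] <- mg_idx[grp[1L]]

  ids <- sprintf("ACC%04d", seq_len(n))
  G <- genotype_matrix(calls, accession_ids = ids,
                       snp_ids = sprintf("SNP%05d", seq_len(m)),
                       chromosome = as.character(1L + (seq_len(m) - 1L) %% 20L),
                       position_bp = seq_len(m) * 1000L)
  attr(G, "duplicate_groups") <- lapply(duplicate_groups, function(i) ids[i])
  attr(G, "subpop") <- stats::setNames(subpop, ids)
  meta <- accession_meta(ids, species = "max",
                         maturity_group = mg_levels[mg_idx])
  list(genotypes = G, meta = meta)
}

#' Overwrite accessions with exact copies of a group head
#'
#' Spikes ground-truth duplicate groups into a genotype matrix: within each
#' listed group every member's calls are overwritten with the first member's
#' calls, so redundancy detection has an exactly known answer.
#'
#' @param G A [genotype_matrix()].
#' @param groups List of character vectors of accession ids; groups must not
#'   overlap and every id must exist in `G`.
#' @return The modified `genotype_matrix`.
#' @export
spike_known_truth <- function(G, groups) {
  if (!length(groups)) return(G)
  all_ids <- unlist(groups)
  if (anyDuplicated(all_ids)) {
    abort_fmt("groups overlap at accession %s", all_ids[duplicated(all_ids)][1L])
  }
  unknown <- setdiff(all_ids, rownames(G))
  if (length(unknown)) abort_fmt("unknown accession: %s", unknown[1L])
  for (grp in groups) {
    head_row <- unclass(G)[grp[1L], ]
    for (id in grp[-1L]) {
      G[id, ] <- head_row
    }
  }
  G
}
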