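#' Read PLINK PED/MAP text genotypes
#'
#' Parses the classic PLINK text dialect: a PED file with six leading columns
#' (family, individual, paternal, maternal, sex, phenotype) followed by two
#' allele columns per SNP, and a MAP file with four columns (chromosome, SNP
#' id, genetic distance, physical position). The individual id (column 2)
#' becomes the accession id.
#'
#' Allele coding is anchored per locus: the first non-"0" allele observed in
#' file order becomes the code-0 allele, the second becomes the code-2
#' allele. An allele of `"0"` in either slot marks the call missing. More
#' than two distinct non-zero alleles at a locus is an error (only biallelic
#' markers are supported).
#'
#' A PED file carries no record of which allele was coded as the reference,
#' so first-seen anchoring recovers the original coding only when the first
#' non-missing call at every locus involves the code-0 allele. When exact
#' call codes matter (round trips, text/binary cross-checks), pass `alleles`
#' to anchor the coding explicitly; it then takes precedence over the
#' first-seen rule, just as BIM A1/A2 do in [read_bed()].
#'
#' @param ped_path Path to the PED file.
#' @param map_path Path to the MAP file.
#' @param alleles Optional n_snps x 2 character matrix fixing, per locus,
#'   the code-0 (first column) and code-2 (second column) alleles.
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path, alleles = NULL) {
  map <- read_map_file(map_path)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort_fmt("PED file '%s' is empty", ped_path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(map)
  want <- 6L + 2L * m
  nf <- lengths(toks)
  if (any(nf != want)) {
    abort_fmt("PED line %d has %d fields; expected %d for %d SNPs",
              which(nf != want)[1L], nf[nf != want][1L], want, m)
  }
  tab <- do.call(rbind, toks)
  ids <- tab[, 2L]
  if (anyDuplicated(ids)) {
    abort_fmt("duplicate accession id in PED: %s", ids[duplicated(ids)][1L])
  }
  n <- length(ids)
  if (!is.null(alleles)) {
    alleles <- as.matrix(alleles)
    if (!identical(dim(alleles), c(m, 2L))) {
      abort_fmt("`alleles` must be a %d x 2 matrix", m)
    }
  }
  calls <- matrix(NA_integer_, n, m)
  anchor <- matrix(NA_character_, m, 2L)
  for (j in seq_len(m)) {
    a1 <- tab[, 5L + 2L * j]
    a2 <- tab[, 6L + 2L * j]
    obs <- c(rbind(a1, a2))        # file order: both alleles of row 1, then row 2, ...
    seen <- unique(obs[obs != "0"])
    if (length(seen) > 2L) {
      abort_fmt("locus %s has %d distinct alleles; only biallelic markers supported",
                map$snp_id[j], length(seen))
    }
    if (is.null(alleles)) {
      if (length(seen) == 0L) seen <- c("A", "B")
      if (length(seen) == 1L) seen <- c(seen, setdiff(c("A", "B"), seen)[1L])
    } else {
      if (length(setdiff(seen, alleles[j, ]))) {
        abort_fmt("locus %s contains allele '%s' absent from the supplied anchoring",
                  map$snp_id[j], setdiff(seen, alleles[j, ])[1L])
      }
      seen <- alleles[j, ]
    }
    anchor[j, ] <- seen
    miss <- a1 == "0" | a2 == "0"
    dose <- (a1 == seen[2L]) + (a2 == seen[2L])
    dose[miss] <- NA_integer_
    calls[, j] <- as.integer(dose)
  }
  genotype_matrix(calls, accession_ids = ids, snp_ids = map$snp_id,
                  chromosome = map$chromosome, position_bp = map$position_bp,
                  alleles = anchor)
}

read_map_file <- function(map_path) {
  lines <- readLines(map_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(toks) != 4L)) {
    abort_fmt("MAP line %d does not have 4 columns", which(lengths(toks) != 4L)[1L])
  }
  tab <- do.call(rbind, toks)
  ids <- tab[, 2L]
  if (anyDuplicated(ids)) abort_fmt("duplicate SNP id in MAP: %s",
                                    ids[duplicated(ids)][1L])
  data.frame(chromosome = tab[, 1L], snp_id = ids,
             genetic_dist = as.numeric(tab[, 3L]),
             position_bp = as.integer(tab[, 4L]),
             stringsAsFactors = FALSE)
}

#' Write PLINK PED/MAP text genotypes
#'
#' Inverse of [read_ped_map()]. Family and individual ids are both set to the
#' accession id; parental ids, sex and phenotype are written as `0 0 0 -9`.
#' Missing calls are written as the `0 0` allele pair.
#'
#' @param G A [genotype_matrix()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `G`.
#' @export
write_ped_map <- function(G, ped_path, map_path) {
  al <- attr(G, "alleles")
  m <- ncol(G)
  map <- sprintf("%s\t%s\t0\t%d", attr(G, "chromosome"), colnames(G),
                 attr(G, "position_bp"))
  writeLines(map, map_path)
  X <- unclass(G)
  rows <- vapply(seq_len(nrow(X)), function(i) {
    g <- X[i, ]
    a <- character(2L * m)
    idx1 <- seq(1L, by = 2L, length.out = m)
    a[idx1]      <- ifelse(is.na(g), "0", ifelse(g == 2L, al[, 2L], al[, 1L]))
    a[idx1 + 1L] <- ifelse(is.na(g), "0", ifelse(g == 0L, al[, 1L], al[, 2L]))
    paste(c(rownames(X)[i], rownames(X)[i], "0", "0", "0", "-9", a),
          collapse = " ")
  }, character(1L))
  writeLines(rows, ped_path)
  invisible(G)
}
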