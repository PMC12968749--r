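#' Construct a genotype matrix
#'
#' The central genotype container: an accessions x SNPs matrix of diploid
#' call codes together with the marker map and, optionally, the two observed
#' alleles at each locus. Call codes are `0` (homozygous for the first
#' allele), `1` (heterozygous), `2` (homozygous for the second allele) and
#' `NA` (missing call).
#'
#' @param calls Integer matrix, accessions in rows and SNPs in columns, with
#'   entries in `{0, 1, 2, NA}`.
#' @param accession_ids Character vector of unique accession identifiers
#'   (defaults to existing rownames).
#' @param snp_ids Character vector of unique SNP identifiers (defaults to
#'   existing colnames).
#' @param chromosome Per-SNP chromosome label (recycled if length 1).
#' @param position_bp Per-SNP physical position, integer >= 1.
#' @param alleles Two-column character matrix giving, per SNP, the allele
#'   coded 0 (first column) and the allele coded 2 (second column).
#'
#' @return An object of class `genotype_matrix`: the call matrix with the
#'   marker map attached as attributes.
#' @seealso [read_ped_map()], [read_bed()], [simulate_collection()]
#' @export
genotype_matrix <- function(calls, accession_ids = rownames(calls),
                            snp_ids = colnames(calls),
                            chromosome = "1",
                            position_bp = seq_len(ncol(calls)),
                            alleles = NULL) {
  if (!is.matrix(calls)) abort_fmt("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  n <- nrow(calls)
  m <- ncol(calls)
  if (is.null(accession_ids)) accession_ids <- sprintf("ACC%04d", seq_len(n))
  if (is.null(snp_ids)) snp_ids <- sprintf("SNP%05d", seq_len(m))
  accession_ids <- as.character(accession_ids)
  snp_ids <- as.character(snp_ids)
  if (length(accession_ids) != n) abort_fmt("accession_ids length != nrow(calls)")
  if (length(snp_ids) != m) abort_fmt("snp_ids length != ncol(calls)")
  if (anyDuplicated(accession_ids)) abort_fmt("duplicate accession id: %s",
    accession_ids[duplicated(accession_ids)][1L])
  if (anyDuplicated(snp_ids)) abort_fmt("duplicate SNP id: %s",
    snp_ids[duplicated(snp_ids)][1L])
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L))) {
    abort_fmt("non-missing calls must be coded 0, 1 or 2")
  }
  chromosome <- rep_len(as.character(chromosome), m)
  position_bp <- rep_len(as.integer(position_bp), m)
  if (m > 0 && any(position_bp < 1L, na.rm = TRUE)) {
    abort_fmt("position_bp must be >= 1")
  }
  if (is.null(alleles)) {
    alleles <- cbind(rep("A", m), rep("B", m))
  }
  alleles <- as.matrix(alleles)
  if (!identical(dim(alleles), c(m, 2L)) && m > 0) {
    abort_fmt("`alleles` must be an n_snps x 2 matrix")
  }
  dimnames(calls) <- list(accession_ids, snp_ids)
  structure(calls,
            chromosome = chromosome,
            position_bp = position_bp,
            alleles = alleles,
            class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d SNPs\n", nrow(x), ncol(x)))
  miss <- mean(is.na(x))
  het <- mean(x == 1L, na.rm = TRUE)
  cat(sprintf("  missing calls: %.2f%%   heterozygous calls: %.2f%%\n",
              100 * miss, 100 * het))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' Row/column subsetting keeps the marker map in step with the retained SNPs.
#'
#' @param x A `genotype_matrix`.
#' @param i Accession selector (ids, indices or logical).
#' @param j SNP selector.
#' @param ... Ignored.
#' @param drop Ignored; the result is always a `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass(x)
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  jj <- seq_len(ncol(m))
  names(jj) <- colnames(m)
  jidx <- unname(jj[j])
  out <- m[i, jidx, drop = FALSE]
  genotype_matrix(out,
                  accession_ids = rownames(out),
                  snp_ids = colnames(out),
                  chromosome = attr(x, "chromosome")[jidx],
                  position_bp = attr(x, "position_bp")[jidx],
                  alleles = attr(x, "alleles")[jidx, , drop = FALSE])
}

#' @export
as.matrix.genotype_matrix <- function(x, ...) {
  out <- unclass(x)
  attributes(out) <- attributes(out)[c("dim", "dimnames")]
  out
}

accession_ids <- function(G) rownames(G)
snp_ids <- function(G) colnames(G)
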