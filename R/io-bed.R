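#' Read PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' Decodes the SNP-major PLINK 1 binary dialect: a BED file opening with the
#' magic bytes `0x6c 0x1b`, a mode byte (`0x01` = SNP-major, the only mode
#' supported), then one 2-bit field per individual per SNP, packed four
#' individuals per byte from the least-significant bits up. The 2-bit codes
#' map to calls as `00` = homozygous A1 (call 0), `10` = heterozygous
#' (call 1), `11` = homozygous A2 (call 2), `01` = missing. BIM columns five
#' and six give the A1/A2 alleles, which anchor the call coding.
#'
#' @param bfile_prefix Path prefix; `<prefix>.bed`, `<prefix>.bim` and
#'   `<prefix>.fam` must all exist.
#' @return A [genotype_matrix()].
#' @export
read_bed <- function(bfile_prefix) {
  bed <- paste0(bfile_prefix, ".bed")
  bim <- paste0(bfile_prefix, ".bim")
  fam <- paste0(bfile_prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) abort_fmt("missing file: %s", f)
  }
  bimtab <- do.call(rbind, strsplit(trimws(readLines(bim)), "[ \t]+"))
  if (ncol(bimtab) != 6L) abort_fmt("BIM must have 6 columns")
  famtab <- do.call(rbind, strsplit(trimws(readLines(fam)), "[ \t]+"))
  if (ncol(famtab) < 2L) abort_fmt("FAM must have at least 2 columns")
  n <- nrow(famtab)
  m <- nrow(bimtab)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    abort_fmt("'%s' lacks the PLINK BED magic bytes", bed)
  }
  if (raw[3L] == as.raw(0x00)) {
    abort_fmt("individual-major BED files are not supported")
  }
  if (raw[3L] != as.raw(0x01)) abort_fmt("unknown BED mode byte")
  bps <- ceiling(n / 4)                 # bytes per SNP
  payload <- raw[-(1:3)]
  if (length(payload) != bps * m) {
    abort_fmt("BED payload has %d bytes; expected %d (%d accessions x %d SNPs)",
              length(payload), bps * m, n, m)
  }
  # unpack 2-bit fields: byte -> 4 codes, least-significant pair first
  v <- as.integer(payload)
  codes <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, v %/% 64L)
  codes <- matrix(codes, nrow = 4L * bps, ncol = m)[seq_len(n), , drop = FALSE]
  lut <- c(0L, NA_integer_, 1L, 2L)     # 00,01,10,11
  calls <- matrix(lut[codes + 1L], n, m)
  genotype_matrix(calls,
                  accession_ids = famtab[, 2L],
                  snp_ids = bimtab[, 2L],
                  chromosome = bimtab[, 1L],
                  position_bp = as.integer(bimtab[, 4L]),
                  alleles = cbind(bimtab[, 5L], bimtab[, 6L]))
}

#' Write PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' Inverse of [read_bed()]; always writes SNP-major files. The code-0 allele
#' goes to BIM column A1 and the code-2 allele to A2, so re-reading restores
#' the calls exactly.
#'
#' @param G A [genotype_matrix()].
#' @param bfile_prefix Output path prefix.
#' @return Invisibly, `G`.
#' @export
write_bed <- function(G, bfile_prefix) {
  n <- nrow(G)
  m <- ncol(G)
  al <- attr(G, "alleles")
  bim <- sprintf("%s\t%s\t0\t%d\t%s\t%s", attr(G, "chromosome"), colnames(G),
                 attr(G, "position_bp"), al[, 1L], al[, 2L])
  writeLines(bim, paste0(bfile_prefix, ".bim"))
  fam <- sprintf("%s\t%s\t0\t0\t0\t-9", rownames(G), rownames(G))
  writeLines(fam, paste0(bfile_prefix, ".fam"))
  enc <- c(0L, 2L, 3L)                  # call 0,1,2 -> 2-bit code
  bps <- ceiling(n / 4)
  X <- unclass(G)
  codes <- matrix(1L, nrow = 4L * bps, ncol = m)   # pad/missing = 01
  obs <- !is.na(X)
  tmp <- matrix(1L, n, m)
  tmp[obs] <- enc[X[obs] + 1L]
  codes[seq_len(n), ] <- tmp
  i1 <- seq(1L, 4L * bps, by = 4L)
  bytes <- codes[i1, , drop = FALSE] + 4L * codes[i1 + 1L, , drop = FALSE] +
    16L * codes[i1 + 2L, , drop = FALSE] + 64L * codes[i1 + 3L, , drop = FALSE]
  con <- file(paste0(bfile_prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(G)
}
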