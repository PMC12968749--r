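test_that("PED parsing anchors allele codes on first-seen alleles", {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(c("F1 S1 0 0 0 -9 A A A G",
               "F2 S2 0 0 0 -9 A A G G"), ped)
  writeLines(c("1 snp1 0 100", "1 snp2 0 200"), map)
  G <- read_ped_map(ped, map)
  expect_identical(unname(as.matrix(G)), rbind(c(0L, 1L), c(0L, 2L)))
  expect_identical(rownames(G), c("S1", "S2"))
  expect_identical(attr(G, "alleles")[2, ], c("A", "G"))
})

test_that("PED '0' alleles become missing calls", {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(c("F1 S1 0 0 0 -9 0 0 C C",
               "F2 S2 0 0 0 -9 T T C 0"), ped)
  writeLines(c("1 snp1 0 100", "1 snp2 0 200"), map)
  G <- read_ped_map(ped, map)
  expect_identical(unname(as.matrix(G)), rbind(c(NA_integer_, 0L), c(0L, NA_integer_)))
})

test_that("PED format errors are caught", {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(c("F1 S1 0 0 0 -9 A A"), ped)
  writeLines(c("1 snp1 0 100", "1 snp2 0 200"), map)
  expect_error(read_ped_map(ped, map), "expected")

  writeLines(c("F1 S1 0 0 0 -9 A A A G",
               "F2 S1 0 0 0 -9 A A G G"), ped)
  expect_error(read_ped_map(ped, map), "duplicate accession")

  writeLines(c("F1 S1 0 0 0 -9 A A A G",
               "F2 S2 0 0 0 -9 C T G G"), ped)
  expect_error(read_ped_map(ped, map), "distinct alleles")
})

test_that("PED round-trip restores calls exactly with allele anchoring, and up to relabelling without", {
  sim <- simulate_collection(n_accessions = 10, n_snps = 50,
                             duplicate_fraction = 0.2, seed = 11)
  G <- sim$genotypes
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  write_ped_map(G, ped, map)

  G2 <- read_ped_map(ped, map, alleles = attr(G, "alleles"))
  expect_identical(as.matrix(G2), as.matrix(G))

  # without the anchor, each locus is either preserved or 0<->2 swapped,
  # and the distances cannot tell the difference
  G3 <- read_ped_map(ped, map)
  for (j in seq_len(ncol(G))) {
    a <- as.matrix(G)[, j]
    b <- as.matrix(G3)[, j]
    expect_true(identical(a, b) || identical(a, 2L - b))
  }
  expect_equal(pairwise_distance(G3)$d, pairwise_distance(G)$d)
})

test_that("BED round-trip is exact, including missing calls", {
  X <- random_calls(13, 37, missing = 0.1, seed = 5)   # n %% 4 != 0 pads bytes
  G <- gm(X)
  prefix <- tempfile()
  write_bed(G, prefix)
  G2 <- read_bed(prefix)
  expect_identical(as.matrix(G2), as.matrix(G))
  expect_identical(attr(G2, "position_bp"), attr(G, "position_bp"))
})

test_that("single hom-A2 genotype decodes from its one payload byte", {
  G <- gm(matrix(2L, 1, 1))
  prefix <- tempfile()
  write_bed(G, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", 10)
  expect_identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01)))
  expect_identical(as.integer(raw[4]) %% 4L, 3L)       # 2-bit code 11
  expect_identical(unname(as.matrix(read_bed(prefix))), matrix(2L, 1, 1))
})

test_that("malformed BED files are rejected", {
  X <- random_calls(4, 6, seed = 2)
  prefix <- tempfile()
  write_bed(gm(X), prefix)

  bed <- paste0(prefix, ".bed")
  raw <- readBin(bed, "raw", file.size(bed))

  writeBin(raw[-length(raw)], bed)                      # truncated payload
  expect_error(read_bed(prefix), "payload")

  writeBin(c(as.raw(c(0x00, 0x00)), raw[-(1:2)]), bed)  # wrong magic
  expect_error(read_bed(prefix), "magic")

  raw[3] <- as.raw(0x00)                                # individual-major
  writeBin(raw, bed)
  expect_error(read_bed(prefix), "individual-major")
})

test_that("text and binary dialects yield the same matrix under one allele convention", {
  sim <- simulate_collection(n_accessions = 8, n_snps = 30, n_subpops = 3,
                             seed = 21)
  G <- sim$genotypes
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  prefix <- tempfile()
  write_ped_map(G, ped, map)
  write_bed(G, prefix)
  Gt <- read_ped_map(ped, map, alleles = attr(G, "alleles"))
  Gb <- read_bed(prefix)
  expect_identical(as.matrix(Gt), as.matrix(Gb))
})

test_that("cluster tables have the contracted shape and round-trip", {
  sim <- simulate_collection(n_accessions = 10, n_snps = 60, seed = 8)
  D <- pairwise_distance(sim$genotypes)
  asg <- list(all_k3 = kmeans_cluster(D, 3, seed = 1),
              all_k5 = kmeans_cluster(D, 5, seed = 1))
  path <- tempfile(fileext = ".csv")
  tab <- write_cluster_table(asg, sim$meta, path)
  expect_identical(dim(tab), c(10L, 5L))
  expect_identical(names(tab)[1:3], c("accession_id", "species", "maturity_group"))

  back <- read_cluster_table(path)
  expect_identical(back$all_k3, unname(asg$all_k3$labels[back$accession_id]))
  expect_identical(back$all_k5, unname(asg$all_k5$labels[back$accession_id]))

  # metadata-only degenerate case
  tab0 <- write_cluster_table(list(), sim$meta)
  expect_identical(dim(tab0), c(10L, 3L))

  # inconsistent accession sets
  D2 <- pairwise_distance(sim$genotypes[1:5, ])
  expect_error(write_cluster_table(list(kmeans_cluster(D, 2, 1),
                                        kmeans_cluster(D2, 2, 1))),
               "different accession sets")
})

test_that("accession metadata validates and round-trips through CSV", {
  meta <- accession_meta(c("a", "b"), species = c("max", "soja"),
                         maturity_group = c("IV", "UNDETERMINED"),
                         preferred = c(TRUE, FALSE),
                         seed_available = c(TRUE, FALSE))
  path <- tempfile(fileext = ".csv")
  write_accession_meta(meta, path)
  expect_identical(read_accession_meta(path), meta)

  expect_error(accession_meta(c("a", "a")), "duplicate")
  expect_error(accession_meta("a", maturity_group = "XI"), "maturity group")
  expect_error(accession_meta("a", species = "glycine"), "species")
})
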