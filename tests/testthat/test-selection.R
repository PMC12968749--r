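test_that("MG windows follow the adjacent-group rule with boundary clipping", {
  expect_identical(mg_window("00")$members, c("000", "00", "0"))
  expect_identical(mg_window("000")$members, c("000", "00"))
  expect_identical(mg_window("X")$members, c("IX", "X"))
  expect_identical(mg_window("IV")$members, c("III", "IV", "V"))
  # full sweep: target always inside, members always contiguous
  for (t in mg_levels) {
    w <- mg_window(t)
    expect_true(t %in% w$members)
    idx <- match(w$members, mg_levels)
    expect_identical(idx, seq(min(idx), max(idx)))
    expect_true(length(w$members) %in% 2:3)
  }
  expect_error(mg_window("UNDETERMINED"), "UNDETERMINED")
  expect_error(mg_window("XI"), "unknown")
})

make_assignment <- function(n = 20, k = 5, seed = 3) {
  sim <- simulate_collection(n_accessions = n, n_snps = 200,
                             duplicate_fraction = 0, seed = seed)
  list(A = kmeans_cluster(pairwise_distance(sim$genotypes), k, seed = 1),
       meta = sim$meta, G = sim$genotypes)
}

test_that("diverse sets take one accession per cluster and honour preference", {
  fx <- make_assignment()
  ds <- build_diverse_set(fx$A, meta = fx$meta, seed = 7)
  expect_identical(nrow(ds$picks), 5L)
  expect_identical(sort(ds$picks$cluster), 0:4)
  expect_length(ds$exhausted, 0)
  expect_true(all(ds$picks$mode == "random"))

  pref <- names(fx$A$labels)[fx$A$labels == 2L][1]
  ds2 <- build_diverse_set(fx$A, meta = fx$meta, preferred = pref, seed = 7)
  row <- ds2$picks[ds2$picks$cluster == 2L, ]
  expect_identical(row$accession_id, pref)
  expect_identical(row$mode, "preferred")

  # two preferred accessions in one cluster is a constraint error
  both <- names(fx$A$labels)[fx$A$labels == 2L][1:2]
  expect_error(build_diverse_set(fx$A, preferred = both), "cluster 2")
  expect_error(build_diverse_set(fx$A, preferred = "x", excluded = "x"),
               "both preferred and excluded")
})

test_that("clusters with no eligible member are reported exhausted, never back-filled", {
  fx <- make_assignment()
  singleton_like <- names(fx$A$labels)[fx$A$labels == 0L]
  ds <- build_diverse_set(fx$A, meta = fx$meta, excluded = singleton_like,
                          seed = 1)
  expect_identical(ds$exhausted, 0L)
  expect_identical(nrow(ds$picks), 4L)
  expect_false(any(ds$picks$accession_id %in% singleton_like))
  # |picks| + |exhausted| = k
  expect_identical(nrow(ds$picks) + length(ds$exhausted), fx$A$k)
})

test_that("unavailable seed blocks a random pick but exhausts honestly", {
  fx <- make_assignment()
  members <- names(fx$A$labels)[fx$A$labels == 1L]
  meta <- fx$meta
  meta$seed_available[meta$accession_id %in% members] <- FALSE
  ds <- build_diverse_set(fx$A, meta = meta, seed = 2)
  expect_true(1L %in% ds$exhausted)
  expect_false(any(ds$picks$accession_id %in% members))
})

test_that("replacement re-picks within the same cluster with mode replacement", {
  fx <- make_assignment()
  ds <- build_diverse_set(fx$A, meta = fx$meta, seed = 7)
  victim <- ds$picks$accession_id[ds$picks$cluster == 3L]
  ds2 <- replace_picks(ds, fx$A, meta = fx$meta, excluded = victim, seed = 9)
  row <- ds2$picks[ds2$picks$cluster == 3L, ]
  expect_identical(row$mode, "replacement")
  expect_false(row$accession_id == victim)
  expect_identical(fx$A$labels[[row$accession_id]], 3L)
  # untouched clusters keep their picks
  expect_identical(ds2$picks$accession_id[ds2$picks$cluster != 3L],
                   ds$picks$accession_id[ds$picks$cluster != 3L])
})

test_that("diverse sets from different seeds differ only within clusters", {
  fx <- make_assignment(n = 40, k = 8)
  ds1 <- build_diverse_set(fx$A, seed = 1)
  ds2 <- build_diverse_set(fx$A, seed = 2)
  expect_identical(ds1$picks$cluster, ds2$picks$cluster)
  for (i in seq_len(nrow(ds1$picks))) {
    expect_identical(fx$A$labels[[ds1$picks$accession_id[i]]],
                     fx$A$labels[[ds2$picks$accession_id[i]]])
  }
  # determinism
  expect_identical(build_diverse_set(fx$A, seed = 1)$picks, ds1$picks)
})

test_that("random sets are seeded uniform samples independent of id order", {
  ids <- sprintf("A%03d", 1:30)
  s1 <- build_random_set(ids, 10, seed = 5)
  s2 <- build_random_set(rev(ids), 10, seed = 5)
  expect_identical(s1, s2)
  expect_length(unique(s1), 10)
  expect_true(all(s1 %in% ids))
  expect_identical(sort(build_random_set(ids, 30, seed = 1)), ids)
  expect_length(build_random_set(ids, 1, seed = 1), 1)
  expect_error(build_random_set(ids, 0, seed = 1), "n")
  expect_error(build_random_set(ids, 31, seed = 1), "n")
})

test_that("selector tables emit one labelled column per scope and k", {
  sim <- simulate_collection(n_accessions = 60, n_snps = 200,
                             n_subpops = 5, seed = 31)
  tab <- export_selector_table(sim$genotypes, sim$meta, k_list = c(4, 8),
                               mg_targets = "II", seed = 1)
  expect_true(all(c("all_k4", "all_k8", "MG_II_k4", "MG_II_k8") %in% names(tab)))
  expect_identical(nrow(tab), 60L)
  expect_false(anyNA(tab$all_k4))

  w <- mg_window("II")$members
  inside <- tab$maturity_group %in% w
  expect_true(all(is.na(tab$MG_II_k4[!inside])))
  expect_false(anyNA(tab$MG_II_k4[inside]))

  # oversized k: that column is skipped with a warning, others still emitted
  expect_warning(
    tab2 <- export_selector_table(sim$genotypes, sim$meta, k_list = c(4, 1000),
                                  seed = 1),
    "exceeds")
  expect_true("all_k4" %in% names(tab2))
  expect_false("all_k1000" %in% names(tab2))
})

test_that("selector table CSV round-trips labels and blanks", {
  sim <- simulate_collection(n_accessions = 30, n_snps = 150,
                             n_subpops = 4, seed = 37)
  path <- tempfile(fileext = ".csv")
  tab <- export_selector_table(sim$genotypes, sim$meta, k_list = 3,
                               mg_targets = "V", seed = 2, path = path)
  back <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(accession_id = "character",
                                  maturity_group = "character"))
  expect_identical(back$all_k3, tab$all_k3)
  expect_identical(is.na(back$MG_V_k3), is.na(tab$MG_V_k3))
})
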