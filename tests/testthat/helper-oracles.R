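# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the package internals they check.

# per-locus double loop over the distance rules
naive_distance <- function(X, het_het = 1) {
  n <- nrow(X)
  d <- matrix(0, n, n)
  nl <- matrix(0L, n, n)
  per_locus_g <- function(a, b) {
    if (a == b) {
      if (a == 1) het_het else 0
    } else if (a == 1 || b == 1) 0.5 else 1
  }
  for (i in seq_len(n)) {
    nl[i, i] <- sum(!is.na(X[i, ]))
    for (j in seq_len(n)) {
      if (j <= i) next
      g <- 0
      N <- 0L
      for (l in seq_len(ncol(X))) {
        if (is.na(X[i, l]) || is.na(X[j, l])) next
        N <- N + 1L
        g <- g + per_locus_g(X[i, l], X[j, l])
      }
      d[i, j] <- d[j, i] <- g / N
      nl[i, j] <- nl[j, i] <- N
    }
  }
  list(d = d, n_loci = nl)
}

# per-SNP allele scan: retained iff >= 2 distinct alleles observed
naive_polymorphic_count <- function(X, rows) {
  sum(vapply(seq_len(ncol(X)), function(l) {
    alleles <- character(0)
    for (i in rows) {
      g <- X[i, l]
      if (is.na(g)) next
      alleles <- union(alleles, switch(as.character(g),
                                       "0" = "a", "1" = c("a", "b"), "2" = "b"))
    }
    length(alleles) >= 2
  }, logical(1)))
}

# BFS connected components of a logical adjacency matrix
naive_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# genotype matrix from an integer matrix in one call
gm <- function(calls, ids = NULL) {
  calls <- as.matrix(calls)
  if (is.null(ids)) ids <- sprintf("A%02d", seq_len(nrow(calls)))
  genotype_matrix(calls, accession_ids = ids)
}

# random call matrix with missingness, values 0/1/2/NA
random_calls <- function(n, m, missing = 0.05, het = 0.1, seed = 1) {
  set.seed(seed)
  x <- sample(c(0L, 1L, 2L), n * m, replace = TRUE,
              prob = c((1 - het) / 2, het, (1 - het) / 2))
  x[runif(n * m) < missing] <- NA_integer_
  matrix(x, n, m)
}
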