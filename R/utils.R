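# Internal helpers shared across modules.

# Deterministic sub-seed derivation (Lehmer step per offset). Keeps every
# derived seed in [0, 2^31 - 2] so set.seed() always accepts it, and lets
# each stochastic stage own an independent, reproducible stream.
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  x <- abs(as.double(seed)) %% 2147483647
  for (o in c(...)) {
    x <- (x * 48271 + abs(as.double(o)) + 1) %% 2147483647
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort_fmt("`%s` must be a single number in [%s, %s]", name,
              format(min), format(max))
  }
  invisible(x)
}
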