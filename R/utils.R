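# Internal helpers.

# Evaluate `code` under a local RNG seeded with `seed`, leaving the
# caller's RNG state untouched; with seed = NULL the global stream is used.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), code)
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x
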