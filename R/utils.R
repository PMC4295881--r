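# Internal helpers: seeded evaluation and seed streams.
#
# All user-facing stochastic operations take an explicit integer seed. Code
# that needs several independent streams (e.g. one per permutation replicate)
# derives sub-seeds from the master seed with `derive_seeds()` so replicates
# are reproducible individually, not just as a sequence.

# Evaluate `code` under `seed`, restoring R's RNG state afterwards.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# k sub-seeds deterministically derived from one master seed (all < 2^31).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k, replace = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)
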