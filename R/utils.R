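# Internal helpers.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards; with seed = NULL the current stream is used untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive `n` child seeds (< 2^31) from the current RNG stream.
spawn_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
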