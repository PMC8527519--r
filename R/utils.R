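# Internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed` (or the
# current stream when seed is NULL), restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive per-iteration substream seeds from one master seed, so that
# iterations can be computed in any order with identical results.
iteration_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_power_of_two <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
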