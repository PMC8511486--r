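# Internal helpers shared across modules.

# Round half away from zero (platform-stable edge-count rounding; base round()
# uses banker's rounding, which would make edge counts depend on parity).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Deterministic seed mixing: maps a (seed, index) pair into [1, 2^31 - 2] so
# independent streams (permutation i, rewiring j, pipeline stage k) can be
# re-run in isolation. Plain LCG-style mixing; all arithmetic kept in double
# well below 2^53 so the result is exact.
mix_seed <- function(seed, index) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  i <- (abs(as.numeric(index)) %% 2147483647) + 1
  as.integer((s * 48271 + i * 69621 + 7) %% 2147483629) + 1L
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards so
# seeded internals never disturb the user's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
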