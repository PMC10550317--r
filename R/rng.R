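# Seed handling.
#
# All stochastic entry points take an integer `seed` and are deterministic
# given it.  Internally a master seed is split into named sub-streams
# (founders / inheritance / noise / ...) so that, e.g., a truncation-selection
# run with one candidate per offspring reproduces the neutral run exactly
# under the same master seed.  Derived seeds stay below 2^31 - 1.

# Set the RNG locally; returns a restorer function for on.exit().
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

# Deterministic stream splitting: hash (seed, tag, indices) into [1, 2^31-2].
# Multiplicative hashing modulo the Mersenne prime 2^31 - 1, which keeps all
# arithmetic exact in doubles (products stay below 2^53).
derive_seed <- function(seed, tag, ...) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% m
  mix <- function(h, v) ((h * 48271) %% m + v) %% m
  for (ch in utf8ToInt(as.character(tag))) h <- mix(h, ch)
  for (v in c(...)) h <- mix(h, as.numeric(v) %% m)
  as.integer(h %% (m - 1)) + 1L
}
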