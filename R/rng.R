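# Deterministic randomness helpers.
#
# All stochastic steps in the package (codebook seeding, synthetic data,
# splits) run under an explicit integer seed and leave the caller's global
# RNG state untouched.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  code
}

# Counter-based per-item seed derivation: expands one master seed into
# independent per-item seeds so any subset of generated items is
# reproducible on its own. Kept below 2^31 - 1.
derive_seed <- function(master_seed, ...) {
  counters <- c(...)
  s <- as.double(master_seed) %% 2147483647
  for (k in counters) {
    s <- (s * 48271 + as.double(k) * 16807 + 1) %% 2147483647
  }
  as.integer(s)
}
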