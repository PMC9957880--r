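# Deterministic per-patient random streams.
#
# Every source of randomness is derived from a single root seed and the
# patient id through an integer mixing function, so that (i) runs are
# bit-reproducible, (ii) the draws of patient i do not depend on how many
# other patients are simulated, and (iii) both healthcare scenarios of the
# same patient can consume identical uniforms (common random numbers).

# Mix (root seed, patient id, block) into a seed in [1, 2^31 - 22].
# All arithmetic stays below 2^53 so it is exact in doubles.
.mix_seed <- function(root, id, block = 0) {
  m <- 2147483629
  x <- as.numeric(root) %% m
  x <- (x * 48271 + as.numeric(id)) %% m
  x <- (x * 69621 + as.numeric(block) + 1) %% m
  as.integer(x) + 1L
}

# A fixed-layout block of uniforms for one patient, shared by both
# scenarios. Callers are responsible for saving/restoring the global RNG
# state (see .with_preserved_rng); this function is used in hot loops.
# Layout:
#   death: 2  (year-of-death inversion, position within year)
#   fail : 48 (24 failure draws x 2: component choice, quantile)
#   dec  : 64 (treatment-selection draws)
#   per  : 6  (perioperative-death Bernoulli draws)
.patient_draws <- function(root, id) {
  set.seed(.mix_seed(root, id, 1))
  u <- stats::runif(120)
  list(
    death = u[1:2],
    fail  = u[3:50],
    dec   = u[51:114],
    per   = u[115:120],
    root  = root,
    id    = id
  )
}

# Extension draws for the (rare) trajectory that exhausts a block.
.extra_draws <- function(root, id, block, n = 64) {
  set.seed(.mix_seed(root, id, block))
  stats::runif(n)
}

# Run `expr` with the caller's RNG state preserved: the package's seeded
# draws never perturb (and are never perturbed by) the session RNG.
.with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(expr)
}
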