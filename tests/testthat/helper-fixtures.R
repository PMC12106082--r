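# Shared fixtures, built in code at test time.

# small deterministic response set: `conds` x `trials` x `units`
toy_set <- function(conds = c(0, 1), trials = 10, units = 3, phase = "pre",
                    shift = 0, seed = 101) {
  mats <- with_seed(seed, lapply(seq_along(conds), function(i) {
    matrix(rnorm(trials * units, mean = shift * (i - 1)), trials, units)
  }))
  names(mats) <- as.character(conds)
  response_set(mats, phase = phase)
}

with_seed <- neurogeom:::with_seed

# random well-conditioned geometry with n units
random_geometry <- function(n, seed, dtheta = 1) {
  with_seed(seed, {
    A <- matrix(rnorm(n * n), n)
    S1 <- crossprod(A) / n + diag(0.5, n)
    B <- matrix(rnorm(n * n), n)
    S2 <- crossprod(B) / n + diag(0.5, n)
    population_geometry(rnorm(n), rnorm(n), S1, S2, dtheta = dtheta)
  })
}

# the validation population: well-driven direction-tuned units around the
# trained direction (45 deg), 4-deg discrimination — the motion-task regime
validation_spec <- function(n_units = 20) {
  population_spec(n_units = n_units, period = 360, stimulus_pair = c(45, 49),
                  preferred_stimuli = seq(5, 85, length.out = n_units),
                  tuning_amplitude = 60, tuning_baseline = 5,
                  tuning_width = 20, fano = 1.5,
                  corr_strength = 0.2, corr_decay = 60)
}

# geometry with a well-separated geometric eigen-spectrum (ratio 2), for
# PC-direction recovery under sampling
ladder_geometry <- function(n = 8, top = 100, seed = 5, dtheta = 1) {
  lam <- top * 0.5^(seq_len(n) - 1)
  Q <- with_seed(seed, qr.Q(qr(matrix(rnorm(n * n), n))))
  S <- Q %*% (lam * t(Q))
  S <- (S + t(S)) / 2
  df <- with_seed(seed + 1, rnorm(n))
  population_geometry(-df / 2, df / 2, S, S, dtheta = dtheta)
}
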