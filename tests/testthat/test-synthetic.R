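# Synthetic population generator and mechanism injection.

test_that("make_population reproduces the stated mean/covariance structure", {
  # c0 = 0: diagonal covariance, entries fano * mean rate
  sp <- population_spec(n_units = 6, corr_strength = 0, fano = 1.5)
  g <- make_population(sp)
  f_bar <- (g$f1 + g$f2) / 2
  expect_equal(g$Sigma1, diag(1.5 * f_bar), tolerance = 1e-12)

  # flat tuning, fano 1, c0 = 0: Sigma = baseline * I
  sp2 <- population_spec(n_units = 4, tuning_amplitude = 0, tuning_baseline = 7,
                         fano = 1, corr_strength = 0)
  expect_equal(make_population(sp2)$Sigma1, diag(7, 4), tolerance = 1e-12)

  # element-wise correlation oracle: c0 = 0.2, tau = 30, 8 units
  sp3 <- population_spec(n_units = 8, corr_strength = 0.2, corr_decay = 30)
  g3 <- make_population(sp3)
  v <- diag(g3$Sigma1)
  for (i in 1:7) for (j in (i + 1):8) {
    dp <- neurogeom:::circ_dist(sp3$preferred_stimuli[i],
                                sp3$preferred_stimuli[j], 180)
    expect_equal(g3$Sigma1[i, j] / sqrt(v[i] * v[j]),
                 0.2 * exp(-dp / 30), tolerance = 1e-10)
  }
})

test_that("single mechanisms obey their analytic scaling laws", {
  g <- make_population(population_spec(n_units = 10))
  a0 <- alfi(g)

  shr <- apply_mechanism(g, mech_shrinkage(0.25))
  expect_equal(shr$truth$alfi_post, 4 * a0, tolerance = 1e-10)
  expect_equal(unname(shr$truth$gains["ms"]), 3 * a0, tolerance = 1e-10)
  expect_true(all(abs(shr$truth$gains[c("se", "sr", "mw")]) < 1e-12))

  enh <- apply_mechanism(g, mech_enhancement(2))
  expect_equal(enh$truth$alfi_post, 4 * a0, tolerance = 1e-10)
  expect_equal(unname(enh$truth$gains["se"]), 3 * a0, tolerance = 1e-10)
  # scaling acts through |df|^2 only: separation doubles, covariance fixed
  expect_equal(signal_separation(enh$post), 2 * signal_separation(g))
  expect_identical(enh$post$Sigma_bar, g$Sigma_bar)

  # warping by any orthogonal R on an isotropic covariance changes nothing
  iso <- population_geometry(rep(0, 5), rnorm(5), diag(2.5, 5))
  R <- qr.Q(qr(matrix(with_seed(3, rnorm(25)), 5)))
  wrp <- apply_mechanism(iso, mech_warping(R = R))
  expect_equal(wrp$truth$alfi_post, wrp$truth$alfi_pre, tolerance = 1e-10)
  expect_true(all(abs(wrp$truth$gains) < 1e-10))
})

test_that("rotation preserves signal length and realises the stated angle", {
  g <- make_population(population_spec(n_units = 8))
  rot <- apply_mechanism(g, mech_rotation(60, plane = "signal"))
  expect_equal(signal_separation(rot$post), signal_separation(g),
               tolerance = 1e-12)
  expect_equal(rot$truth$signal_rotation_angle, 60, tolerance = 1e-8)
  # covariance untouched: all gain attributed to the rotation step
  expect_identical(rot$post$Sigma_bar, g$Sigma_bar)
  expect_true(all(abs(rot$truth$gains[c("se", "ms", "mw")]) < 1e-10))
  expect_error(apply_mechanism(g, mech_rotation(30, plane = c(1, 99))),
               "out of range")
})

test_that("identity-parameter mechanisms leave the geometry unchanged", {
  g <- make_population(population_spec(n_units = 6))
  for (m in list(mech_enhancement(1), mech_shrinkage(1),
                 mech_rotation(0, plane = "signal"),
                 mech_warping(angle_deg = 0),
                 mech_warping(permute = 1:6))) {
    out <- apply_mechanism(g, m)
    expect_equal(out$post$f1, g$f1, tolerance = 1e-12)
    expect_equal(out$post$f2, g$f2, tolerance = 1e-12)
    expect_equal(out$post$Sigma_bar, g$Sigma_bar, tolerance = 1e-10)
    expect_true(all(abs(out$truth$gains) < 1e-8 * max(1, alfi(g))))
  }
})

test_that("warping preserves the trace and the eigenvalue multiset", {
  g <- make_population(population_spec(n_units = 7))
  wrp <- apply_mechanism(g, mech_warping(angle_deg = 40, plane = c(1, 3),
                                         permute = c(2, 1, 3:7)))
  expect_equal(sum(diag(wrp$post$Sigma_bar)), sum(diag(g$Sigma_bar)),
               tolerance = 1e-12 * sum(diag(g$Sigma_bar)))
  expect_equal(sort(eigen(wrp$post$Sigma_bar, symmetric = TRUE)$values),
               sort(eigen(g$Sigma_bar, symmetric = TRUE)$values),
               tolerance = 1e-8)
  expect_true(all(abs(wrp$truth$gains[c("se", "sr")]) < 1e-10))
  expect_lt(abs(wrp$truth$gains["ms"]), 1e-8 * alfi(g))
})

test_that("ground truth for single mechanisms has exactly one nonzero gain and closes", {
  g <- make_population(population_spec(n_units = 9))
  cases <- list(enhancement = mech_enhancement(1.7),
                shrinkage = mech_shrinkage(0.6),
                rotation = mech_rotation(25, plane = "signal"),
                warping = mech_warping(angle_deg = 35))
  key <- c(enhancement = "se", shrinkage = "ms", rotation = "sr",
           warping = "mw")
  for (nm in names(cases)) {
    tr <- apply_mechanism(g, cases[[nm]])$truth
    gains <- tr$gains
    expect_gt(abs(gains[key[nm]]), 1e-8)
    expect_true(all(abs(gains[setdiff(names(gains), key[nm])]) < 1e-10))
    expect_equal(sum(gains), tr$alfi_post - tr$alfi_pre, tolerance = 1e-10)
  }
})

test_that("sample_trials is seeded, reproducible and converges to the analytic mean", {
  g <- make_population(population_spec(n_units = 4))
  s1 <- sample_trials(g, 100, seed = 11)
  s2 <- sample_trials(g, 100, seed = 11)
  expect_identical(s1$responses, s2$responses)
  expect_false(identical(s1$responses,
                         sample_trials(g, 100, seed = 12)$responses))
  expect_error(sample_trials(g, 1, seed = 1), ">= 2")

  # Monte-Carlo concentration: T = 50,000, per-unit mean within 3 sd/sqrt(T)
  big <- sample_trials(g, 50000, seed = 21)
  for (k in 1:2) {
    mu_hat <- colMeans(big$responses[[k]])
    mu <- if (k == 1) g$f1 else g$f2
    tol <- 3 * sqrt(diag(g$Sigma_bar) / 50000)
    expect_true(all(abs(mu_hat - mu) < tol))
  }

  # degenerate covariance: every trial equals the mean
  g0 <- population_geometry(c(1, 2), c(3, 4), matrix(0, 2, 2))
  s0 <- sample_trials(g0, 5, seed = 1)
  expect_true(all(t(s0$responses[[1]]) == c(1, 2)))
})

test_that("sample_counts_pln matches Poisson and log-normal limits", {
  # Sigma_x = 0 reduces to Poisson: empirical Fano near 1
  y <- sample_counts_pln(log(c(5, 8)), matrix(0, 2, 2), trials = 20000,
                         window = 1, seed = 31)
  expect_true(all(y == floor(y)) && all(y >= 0))
  ff <- fano_factor(y)
  expect_true(all(abs(ff - 1) < 0.05))
  # determinism
  expect_identical(y, sample_counts_pln(log(c(5, 8)), matrix(0, 2, 2),
                                        trials = 20000, window = 1, seed = 31))
  # log-normal moment oracle: mu = 0, Sigma_x = 0.25 I -> E y = exp(0.125)
  y2 <- sample_counts_pln(c(0, 0), diag(0.25, 2), trials = 50000,
                          window = 1, seed = 32)
  m <- exp(0.125)
  se <- sqrt((m + m^2 * (exp(0.25) - 1)) / 50000)
  expect_true(all(abs(colMeans(y2) - m) < 3 * se))
  expect_error(sample_counts_pln(c(0, 0), diag(0.25, 2), 10, window = 0, seed = 1),
               "positive")
})

test_that("signal and noise correlations are positively related when c0 > 0", {
  sp <- population_spec(n_units = 20, corr_strength = 0.3, corr_decay = 30)
  g <- make_population(sp)
  # signal correlations from analytic tuning curves over a stimulus grid
  grid <- seq(0, 179, by = 3)
  tc <- vapply(grid, function(th) neurogeom:::tuning_value(sp, th),
               numeric(sp$n_units))
  sig <- stats::cor(t(tc))
  noise <- scale_correlation(g$Sigma_bar)$C
  lower <- lower.tri(sig)
  expect_gt(stats::cor(sig[lower], noise[lower], method = "spearman"), 0.5)
})
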