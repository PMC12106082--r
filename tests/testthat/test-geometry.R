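# Geometry estimation, aLFI, eigenform, decomposition and PC comparison.

test_that("estimate_geometry computes means, pooled covariance and signal vector", {
  # deterministic constants: df exact, covariance only the ridge
  m1 <- matrix(rep(c(1, 2), each = 4), 4, 2)
  m2 <- matrix(rep(c(3, 5), each = 4), 4, 2)
  s <- response_set(list(`0` = m1, `1` = m2))
  g <- estimate_geometry(s, dtheta = 1, ridge = 1e-4)
  expect_equal(g$df, c(2, 3))
  expect_equal(g$Sigma_bar, matrix(0, 2, 2))

  # swapping condition labels negates df, pooled covariance unchanged
  s2 <- response_set(list(`1` = m2, `0` = m1))
  g2 <- estimate_geometry(s2, conditions = c(1, 0), dtheta = 1)
  expect_equal(g2$df, -g$df)
  expect_equal(g2$Sigma_bar, g$Sigma_bar)
  expect_error(estimate_geometry(s, dtheta = 0), "positive")

  # Monte-Carlo recovery: T = 2,000 within 5% Frobenius of the truth
  gt <- random_geometry(5, seed = 40)
  set <- sample_trials(gt, 2000, seed = 41)
  ge <- estimate_geometry(set, ridge = 0)
  frob <- function(M) sqrt(sum(M^2))
  expect_lt(frob(ge$Sigma_bar - gt$Sigma_bar) / frob(gt$Sigma_bar), 0.05)
})

test_that("alfi matches hand-computed quadratic forms", {
  expect_equal(alfi(population_geometry(c(0, 0), c(1, 0), diag(2))), 0.5)
  expect_equal(alfi(population_geometry(c(1, 1), c(1, 1), diag(2))), 0)
  # (1/2) * (1/2 + 2) / 1 = 1.25
  expect_equal(alfi(population_geometry(c(0, 0), c(1, 1), diag(c(2, 0.5)))),
               1.25)
  # singular covariance without ridge names the condition number
  sing <- population_geometry(c(0, 0), c(1, 0), matrix(1, 2, 2), ridge = 0)
  expect_error(alfi(sing), "condition number|singular")
})

test_that("eigendecompose returns a sorted, reconstructing spectrum", {
  g <- population_geometry(c(0, 0), c(1, 1), diag(c(0.5, 2)))
  e <- eigendecompose(g)
  expect_equal(e$values, c(2, 0.5))
  expect_equal(e$lambda_bar, 1.25)
  expect_equal(e$lambda_hat, c(1.6, 0.4))
  expect_equal(mean(e$lambda_hat), 1, tolerance = 1e-10)
  expect_equal(sqrt(sum(e$df_hat^2)), 1, tolerance = 1e-12)

  # isotropic case
  iso <- eigendecompose(population_geometry(rep(0, 4), rep(1, 4), diag(3, 4)))
  expect_true(all(abs(iso$lambda_hat - 1) < 1e-12))

  # reconstruction oracle on random PSD matrices
  for (seed in 1:5) {
    g2 <- random_geometry(6, seed = seed)
    e2 <- eigendecompose(g2)
    rec <- e2$vectors %*% (e2$values * t(e2$vectors))
    S <- g2$Sigma_bar + diag(g2$ridge * mean(diag(g2$Sigma_bar)), 6)
    expect_lt(max(abs(rec - S)), 1e-8)
  }
})

test_that("eigenform evaluation equals the direct quadratic form", {
  g <- population_geometry(c(0, 0), c(1, 1), diag(c(2, 0.5)))
  expect_equal(alfi_eigenform(g), 1.25)
  expect_equal(alfi_eigenform(g), alfi(g), tolerance = 1e-12)

  # isotropic limit reduces to |df|^2 / (n lambda_bar dtheta^2)
  iso <- population_geometry(rep(0, 4), c(1, 2, 0, -1), diag(3, 4))
  expect_equal(alfi_eigenform(iso), (1 + 4 + 1) / (4 * 3), tolerance = 1e-12)

  # randomized equivalence across 200 geometries
  worst <- max(vapply(1:200, function(seed) {
    g <- random_geometry(10, seed = 1000 + seed)
    abs(alfi_eigenform(g) - alfi(g)) / alfi(g)
  }, 0))
  expect_lt(worst, 1e-8)
})

test_that("stepwise decomposition closes and matches analytic oracles", {
  g <- make_population(population_spec(n_units = 8))

  # identity: all five values equal, all gains zero
  d0 <- stepwise_decomposition(g, g)
  vals <- c(d0$alfi_pre, d0$alfi_se, d0$alfi_ms, d0$alfi_sr, d0$alfi_post)
  expect_true(all(abs(vals - d0$alfi_pre) < 1e-12))
  expect_true(all(abs(d0$contributions) < 1e-12))

  # pure shrinkage c = 0.25: ms carries 3x the pre information
  post <- apply_mechanism(g, mech_shrinkage(0.25))$post
  d1 <- stepwise_decomposition(g, post)
  expect_equal(unname(d1$contributions["ms"]), 3 * d1$alfi_pre,
               tolerance = 1e-10)
  expect_true(all(abs(d1$contributions[c("se", "sr", "mw")]) < 1e-12))

  # pure rotation with anisotropic fixed covariance: sr is the entire gain
  post2 <- apply_mechanism(g, mech_rotation(45, plane = c(1, 2)))$post
  d2 <- stepwise_decomposition(g, post2)
  expect_equal(unname(d2$contributions["sr"]), d2$alfi_post - d2$alfi_pre,
               tolerance = 1e-10)
  expect_lt(abs(d2$contributions["mw"]), 1e-12)

  # closure and post consistency hold for arbitrary geometry pairs
  for (seed in 1:20) {
    pre <- random_geometry(7, seed = 2000 + seed)
    pst <- random_geometry(7, seed = 3000 + seed)
    d <- stepwise_decomposition(pre, pst)
    expect_equal(sum(d$contributions), d$alfi_post - d$alfi_pre,
                 tolerance = 1e-12 * max(1, abs(d$alfi_post)))
    expect_equal(d$alfi_post, alfi(pst), tolerance = 1e-8)
    expect_equal(d$alfi_pre, alfi(pre), tolerance = 1e-8)
  }
})

test_that("signal rotation angle is the arc between unit signal vectors", {
  a <- population_geometry(c(0, 0), c(1, 0), diag(2))
  b <- population_geometry(c(0, 0), c(0, 2), diag(2))
  expect_equal(signal_rotation_angle(a, a), 0)
  expect_equal(signal_rotation_angle(a, b), 90)
  zero <- population_geometry(c(0, 0), c(0, 0), diag(2))
  expect_warning(ang <- signal_rotation_angle(a, zero), "undefined")
  expect_true(is.na(ang))
})

test_that("pc_comparison matches constructed rotations and honours coverage", {
  g <- ladder_geometry(6, seed = 8)
  expect_true(all(pc_comparison(g, g)$pc_angles < 1e-5))

  # post eigenvectors rotated 30 degrees in the top-2 eigen-plane
  post <- apply_mechanism(g, mech_warping(angle_deg = 30, plane = c(1, 2)))$post
  cmp <- pc_comparison(g, post, coverage = 0.99)
  expect_equal(cmp$pc_angles[1:2], c(30, 30), tolerance = 1e-6)

  # coverage 1 reports all components
  expect_equal(pc_comparison(g, post, coverage = 1)$n_components, 6)
  expect_error(pc_comparison(g, post, coverage = 0), "coverage")
})

test_that("orthogonal invariance and scaling laws hold", {
  g <- random_geometry(6, seed = 77)
  Q <- qr.Q(qr(matrix(with_seed(78, rnorm(36)), 6)))
  rot <- population_geometry(Q %*% g$f1, Q %*% g$f2,
                             Q %*% g$Sigma1 %*% t(Q), Q %*% g$Sigma2 %*% t(Q),
                             dtheta = g$dtheta, ridge = g$ridge)
  expect_equal(alfi(rot), alfi(g), tolerance = 1e-8)

  # transform both phases: every aLFI value and gain is invariant
  p2 <- random_geometry(6, seed = 79)
  rot2 <- population_geometry(Q %*% p2$f1, Q %*% p2$f2,
                              Q %*% p2$Sigma1 %*% t(Q), Q %*% p2$Sigma2 %*% t(Q),
                              dtheta = p2$dtheta, ridge = p2$ridge)
  d_orig <- stepwise_decomposition(g, p2)
  d_rot <- stepwise_decomposition(rot, rot2)
  for (f in c("alfi_pre", "alfi_se", "alfi_ms", "alfi_sr", "alfi_post"))
    expect_equal(d_rot[[f]], d_orig[[f]], tolerance = 1e-8)

  # Sigma -> c Sigma gives aLFI / c; df -> s df gives s^2 aLFI
  cs <- 0.3; ss <- 1.9
  scaled_S <- population_geometry(g$f1, g$f2, cs * g$Sigma1, cs * g$Sigma2,
                                  dtheta = g$dtheta)
  expect_equal(alfi(scaled_S), alfi(g) / cs, tolerance = 1e-10)
  mid <- (g$f1 + g$f2) / 2
  scaled_d <- population_geometry(mid - ss * g$df / 2, mid + ss * g$df / 2,
                                  g$Sigma1, g$Sigma2, dtheta = g$dtheta)
  expect_equal(alfi(scaled_d), ss^2 * alfi(g), tolerance = 1e-10)
})
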