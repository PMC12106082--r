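# Synthetic populations with known geometry.
#
# Generates populations with Gaussian tuning on a circular stimulus domain,
# Poisson-like variance (Var = fano * mean rate) and limited-range noise
# correlations that decay with preferred-stimulus distance — the standard
# structure that also reproduces the positive relationship between signal
# and noise correlations. Each of the four learning mechanisms can then be
# injected with an analytically known information gain, so the estimation
# and decomposition code can be validated against exact ground truth.

#' Specify a synthetic population
#'
#' @param n_units number of units (>= 2).
#' @param preferred_stimuli preferred stimuli in degrees; default evenly
#'   spaced over the domain.
#' @param tuning_amplitude,tuning_baseline Gaussian tuning amplitude and
#'   baseline, in response units (defaults 30 and 5 spk/s).
#' @param tuning_width Gaussian tuning width sigma in degrees (default 15).
#' @param fano target Fano factor: unit variance = `fano` * mean rate
#'   (default 1.5, typical of cortical spiking).
#' @param corr_strength peak noise-correlation coefficient c0 in \[0, 1)
#'   (default 0.2).
#' @param corr_decay decay constant tau of the correlation with circular
#'   preferred-stimulus distance, degrees (default 45).
#' @param stimulus_pair the two stimulus values (theta1, theta2), degrees;
#'   default `c(55, 56)` — a 1-degree discrimination about a 55-degree
#'   reference.
#' @param period stimulus domain period: 180 for orientation, 360 for
#'   direction (default 180).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_units = 50,
                            preferred_stimuli = NULL,
                            tuning_amplitude = 30, tuning_baseline = 5,
                            tuning_width = 15, fano = 1.5,
                            corr_strength = 0.2, corr_decay = 45,
                            stimulus_pair = c(55, 56), period = 180) {
  if (n_units < 2) stop("`n_units` must be >= 2", call. = FALSE)
  if (tuning_width <= 0) stop("`tuning_width` must be positive", call. = FALSE)
  if (corr_strength < 0 || corr_strength >= 1)
    stop("`corr_strength` must be in [0, 1)", call. = FALSE)
  if (length(stimulus_pair) != 2L || stimulus_pair[1L] == stimulus_pair[2L])
    stop("`stimulus_pair` must hold two distinct stimulus values", call. = FALSE)
  if (is.null(preferred_stimuli))
    preferred_stimuli <- seq(0, period, length.out = n_units + 1L)[seq_len(n_units)]
  if (length(preferred_stimuli) != n_units)
    stop("`preferred_stimuli` length must equal `n_units`", call. = FALSE)
  structure(list(n_units = as.integer(n_units),
                 preferred_stimuli = as.numeric(preferred_stimuli),
                 tuning_amplitude = tuning_amplitude,
                 tuning_baseline = tuning_baseline,
                 tuning_width = tuning_width, fano = fano,
                 corr_strength = corr_strength, corr_decay = corr_decay,
                 stimulus_pair = as.numeric(stimulus_pair), period = period),
            class = "population_spec")
}

# Gaussian tuning on the circular domain
tuning_value <- function(spec, theta) {
  d <- circ_dist(theta, spec$preferred_stimuli, spec$period)
  spec$tuning_baseline +
    spec$tuning_amplitude * exp(-d^2 / (2 * spec$tuning_width^2))
}

#' Analytic geometry of a synthetic population
#'
#' Builds the exact mean responses and covariance implied by a
#' [population_spec()]: mean `f(theta) = baseline + amplitude *
#' exp(-d(theta, pref)^2 / (2 width^2))` with circular distance `d`; unit
#' variance `v_i = fano * mean(f_i(theta1), f_i(theta2))`; off-diagonal
#' covariance `c0 * exp(-|pref_i - pref_j|_circ / tau) * sqrt(v_i v_j)`.
#' Both conditions share the covariance. The matrix is projected to the
#' nearest PSD matrix (eigenvalue flooring, flagged) if needed; flooring
#' beyond 1 percent of spectral mass is an error.
#'
#' @param spec a `population_spec`.
#' @return A `population_geometry` (dtheta = |theta2 - theta1|, ridge 0) with
#'   the spec attached as attribute `"spec"`.
#' @export
make_population <- function(spec) {
  if (!inherits(spec, "population_spec")) stop("not a population_spec", call. = FALSE)
  f1 <- tuning_value(spec, spec$stimulus_pair[1L])
  f2 <- tuning_value(spec, spec$stimulus_pair[2L])
  v <- spec$fano * (f1 + f2) / 2
  dpref <- outer(spec$preferred_stimuli, spec$preferred_stimuli,
                 function(a, b) circ_dist(a, b, spec$period))
  C <- spec$corr_strength * exp(-dpref / spec$corr_decay)
  diag(C) <- 1
  Sigma <- C * tcrossprod(sqrt(v))
  Sigma <- psd_floor(Sigma, max_distortion = 0.01, name = "population covariance")$mat
  geom <- population_geometry(f1, f2, Sigma, Sigma,
                              dtheta = abs(diff(spec$stimulus_pair)), ridge = 0)
  attr(geom, "spec") <- spec
  geom
}

plane_check <- function(plane, n) {
  if (length(plane) != 2L || any(plane < 1) || any(plane > n) ||
      plane[1L] == plane[2L])
    stop("rotation plane indices out of range", call. = FALSE)
  as.integer(plane)
}

#' Mechanism specifications
#'
#' Constructors for the four pre-to-post transformations injected by
#' [apply_mechanism()]:
#' * `mech_enhancement(scale)` — signal enhancement: the signal vector is
#'   scaled by `scale` about the midpoint of the two means; covariance
#'   unchanged.
#' * `mech_shrinkage(factor)` — manifold shrinkage: both covariances scaled
#'   by `factor`; means unchanged.
#' * `mech_rotation(angle_deg, plane)` — signal rotation: the signal vector
#'   is rotated by `angle_deg` with its length preserved. `plane` is either a
#'   pair of eigenvector ranks of the pre covariance (a Givens rotation in
#'   that eigen-plane; the realised angle between pre and post signal vectors
#'   then depends on how much of df lies in the plane) or `"signal"`, which
#'   rotates df by exactly `angle_deg` within the plane spanned by df and the
#'   leading eigenvector's component orthogonal to df.
#' * `mech_warping(angle_deg, plane, permute, R)` — manifold warping: the
#'   covariance eigenstructure changes at fixed total variance, via an
#'   orthogonal conjugation `R Sigma R'` (either an explicit orthogonal `R`
#'   or a rotation of `angle_deg` in the eigen-plane `plane`) and/or a
#'   permutation `permute` of the eigenvalues; means unchanged.
#'
#' @param scale signal-length scale factor s > 0.
#' @param factor covariance scale factor c > 0.
#' @param angle_deg rotation angle in degrees.
#' @param plane integer pair of eigenvector ranks, or `"signal"` (rotation
#'   only).
#' @param permute integer permutation of `1:n` applied to the eigenvalues.
#' @param R explicit orthogonal matrix (checked to 1e-10).
#' @return An object of class `mechanism`.
#' @name mechanisms
NULL

#' @rdname mechanisms
#' @export
mech_enhancement <- function(scale) {
  stopifnot_scalar(scale, "scale")
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  structure(list(kind = "enhancement", scale = scale), class = "mechanism")
}

#' @rdname mechanisms
#' @export
mech_shrinkage <- function(factor) {
  stopifnot_scalar(factor, "factor")
  if (factor <= 0) stop("`factor` must be positive", call. = FALSE)
  structure(list(kind = "shrinkage", factor = factor), class = "mechanism")
}

#' @rdname mechanisms
#' @export
mech_rotation <- function(angle_deg, plane = c(1, 2)) {
  stopifnot_scalar(angle_deg, "angle_deg")
  if (!identical(plane, "signal")) plane <- as.numeric(plane)
  structure(list(kind = "rotation", angle_deg = angle_deg, plane = plane),
            class = "mechanism")
}

#' @rdname mechanisms
#' @export
mech_warping <- function(angle_deg = NULL, plane = c(1, 2), permute = NULL,
                         R = NULL) {
  if (is.null(angle_deg) && is.null(permute) && is.null(R))
    stop("warping needs `angle_deg`, `permute` or `R`", call. = FALSE)
  if (!is.null(R)) {
    R <- as.matrix(R)
    if (max(abs(crossprod(R) - diag(nrow(R)))) > 1e-10)
      stop("`R` must be orthogonal to 1e-10", call. = FALSE)
  }
  structure(list(kind = "warping", angle_deg = angle_deg, plane = plane,
                 permute = permute, R = R), class = "mechanism")
}

# orthogonal rotation by angle (radians) in the plane spanned by
# orthonormal vectors u, v: identity elsewhere
span_rotation <- function(u, v, angle) {
  n <- length(u)
  diag(n) + sin(angle) * (tcrossprod(v, u) - tcrossprod(u, v)) +
    (cos(angle) - 1) * (tcrossprod(u) + tcrossprod(v))
}

#' Inject a learning mechanism into an analytic geometry
#'
#' Applies one mechanism (see [mechanisms]) to a pre-training geometry and
#' returns the post geometry together with analytic ground truth: the exact
#' pre/post aLFI, the per-mechanism information gains from the stepwise
#' decomposition of the analytic geometries, and the realised signal
#' rotation angle. For a single injected mechanism, only the matching gain
#' is nonzero.
#'
#' @param pre a `population_geometry` (analytic; exact means/covariances).
#' @param mech a `mechanism`, or a list of mechanisms applied in order.
#' @return A list with elements `post` (a `population_geometry`) and `truth`
#'   (class `ground_truth`: `alfi_pre`, `alfi_post`, `gains`,
#'   `signal_rotation_angle`, `mechanisms`).
#' @export
apply_mechanism <- function(pre, mech) {
  if (inherits(mech, "mechanism")) mech <- list(mech)
  post <- pre
  for (m in mech) post <- apply_one_mechanism(post, m)
  dec <- stepwise_decomposition(pre, post)
  truth <- structure(list(
    alfi_pre = alfi(pre), alfi_post = alfi(post),
    gains = dec$contributions,
    signal_rotation_angle = dec$signal_rotation_angle,
    mechanisms = vapply(mech, function(m) m$kind, "")),
    class = "ground_truth")
  list(post = post, truth = truth)
}

apply_one_mechanism <- function(geom, m) {
  if (!inherits(m, "mechanism")) stop("not a mechanism", call. = FALSE)
  mid <- (geom$f1 + geom$f2) / 2
  switch(m$kind,
    enhancement = {
      half <- m$scale * geom$df / 2
      population_geometry(mid - half, mid + half, geom$Sigma1, geom$Sigma2,
                          dtheta = geom$dtheta, ridge = geom$ridge)
    },
    shrinkage = {
      population_geometry(geom$f1, geom$f2,
                          m$factor * geom$Sigma1, m$factor * geom$Sigma2,
                          dtheta = geom$dtheta, ridge = geom$ridge)
    },
    rotation = {
      ang <- m$angle_deg * pi / 180
      e <- eigendecompose(geom)
      if (identical(m$plane, "signal")) {
        u <- e$df_hat
        lead <- e$vectors[, 1L]
        v <- lead - sum(lead * u) * u
        nv <- sqrt(sum(v^2))
        if (nv < 1e-12) {  # df parallel to the leading PC: use the next one
          lead <- e$vectors[, 2L]
          v <- lead - sum(lead * u) * u
          nv <- sqrt(sum(v^2))
        }
        R <- span_rotation(u, v / nv, ang)
      } else {
        pl <- plane_check(m$plane, geom$n)
        R <- span_rotation(e$vectors[, pl[1L]], e$vectors[, pl[2L]], ang)
      }
      df_new <- as.numeric(R %*% geom$df)
      population_geometry(mid - df_new / 2, mid + df_new / 2,
                          geom$Sigma1, geom$Sigma2,
                          dtheta = geom$dtheta, ridge = geom$ridge)
    },
    warping = {
      e <- eigendecompose(geom)
      lam <- e$values
      vec <- e$vectors
      if (!is.null(m$permute)) {
        p <- as.integer(m$permute)
        if (!identical(sort(p), seq_len(geom$n)))
          stop("`permute` must be a permutation of 1:n", call. = FALSE)
        lam <- lam[p]
      }
      S <- vec %*% (lam * t(vec))
      R <- m$R
      if (is.null(R) && !is.null(m$angle_deg)) {
        pl <- plane_check(m$plane, geom$n)
        R <- span_rotation(vec[, pl[1L]], vec[, pl[2L]], m$angle_deg * pi / 180)
      }
      if (!is.null(R)) S <- R %*% S %*% t(R)
      S <- (S + t(S)) / 2
      population_geometry(geom$f1, geom$f2, S, S,
                          dtheta = geom$dtheta, ridge = geom$ridge)
    },
    stop("unknown mechanism kind: ", m$kind, call. = FALSE))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %s; aLFI %.5g -> %.5g>\n",
              paste(x$mechanisms, collapse = "+"), x$alfi_pre, x$alfi_post))
  cat("  gains:", paste(sprintf("%s=%+.5g", names(x$gains), x$gains),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Sample trials from an analytic geometry
#'
#' Draws `trials` multivariate-Gaussian trials per condition from the
#' geometry's means and covariances, returning a [response_set()].
#' Reproducible for a fixed seed; the caller's RNG state is untouched.
#'
#' @param geom a `population_geometry`.
#' @param trials trials per condition (>= 2).
#' @param seed integer seed.
#' @param phase phase label for the resulting set.
#' @param conditions optional length-2 vector of condition labels; defaults
#'   to `0` and `dtheta`.
#' @param response_unit response-unit label.
#' @return A `response_set` with two conditions.
#' @export
sample_trials <- function(geom, trials, seed, phase = "pre",
                          conditions = NULL, response_unit = "spk/s") {
  if (trials < 2) stop("`trials` must be >= 2", call. = FALSE)
  if (is.null(conditions)) conditions <- c(0, geom$dtheta)
  draw <- function(mu, S) {
    S <- psd_floor(S, warn = FALSE)$mat
    m <- MASS::mvrnorm(trials, mu = mu, Sigma = S)
    if (trials == 1L) m <- matrix(m, nrow = 1L)
    m
  }
  mats <- with_seed(seed, list(draw(geom$f1, geom$Sigma1),
                               draw(geom$f2, geom$Sigma2)))
  names(mats) <- as.character(conditions)
  response_set(mats, phase = phase, response_unit = response_unit)
}

#' Sample spike counts from a Poisson log-normal model
#'
#' Per trial, draws a latent log-rate vector `x ~ N(mu, Sigma_x)` and then
#' independent counts `y_i ~ Poisson(exp(x_i) * window)`. The degenerate case
#' `Sigma_x = 0` reduces to plain Poisson counts.
#'
#' @param mu latent log-rate mean vector (log spk/s).
#' @param Sigma_x latent log-rate covariance (PSD).
#' @param trials number of trials.
#' @param window count window in seconds (> 0).
#' @param seed integer seed.
#' @return An integer matrix `trials x units` with attribute `"window"`.
#' @seealso [pln_forward()], [pln_fit_moments()]
#' @export
sample_counts_pln <- function(mu, Sigma_x, trials, window = 1, seed) {
  stopifnot_scalar(window, "window")
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  if (trials < 1) stop("`trials` must be >= 1", call. = FALSE)
  mu <- as.numeric(mu)
  Sigma_x <- psd_floor(as.matrix(Sigma_x), warn = FALSE, name = "Sigma_x")$mat
  n <- length(mu)
  counts <- with_seed(seed, {
    x <- MASS::mvrnorm(trials, mu = mu, Sigma = Sigma_x)
    if (trials == 1L) x <- matrix(x, nrow = 1L)
    matrix(stats::rpois(trials * n, lambda = exp(x) * window), trials, n)
  })
  colnames(counts) <- paste0("u", seq_len(n))
  storage.mode(counts) <- "integer"
  attr(counts, "window") <- window
  counts
}
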