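# Population geometry and averaged linear Fisher information (aLFI).
#
# Two stimulus conditions define two clouds ("manifolds") of trial responses
# in unit-indexed space. The geometry of the pair — mean vectors f1, f2,
# condition covariances Sigma1, Sigma2, pooled covariance
# Sigma_bar = (Sigma1 + Sigma2)/2, and the signal vector df = f2 - f1 —
# determines the linear Fisher information about the stimulus. The averaged
# LFI normalises by unit count and squared stimulus separation:
#
#   aLFI = (1/n) * df' Sigma_bar^{-1} df / dtheta^2
#
# and its eigendecomposition form separates the contributions of signal
# length, total variance, signal direction and covariance shape — the basis
# of the four-mechanism decomposition in stepwise_decomposition().

#' Construct a population geometry
#'
#' Low-level constructor from explicit moments. Most users will call
#' [estimate_geometry()] (from trial data) or [make_population()] (analytic).
#'
#' @param f1,f2 mean response vectors for the two conditions.
#' @param Sigma1,Sigma2 condition covariance matrices (symmetric).
#' @param dtheta stimulus separation between the two conditions, in native
#'   stimulus units (degrees, or decimal contrast).
#' @param ridge ridge fraction: `ridge * mean(diag(Sigma_bar))` is added to
#'   the diagonal before any inversion-dependent step. Recorded in the object.
#' @return An object of class `population_geometry` with fields `f1`, `f2`,
#'   `df`, `Sigma1`, `Sigma2`, `Sigma_bar`, `dtheta`, `n`, `ridge`.
#' @export
population_geometry <- function(f1, f2, Sigma1, Sigma2 = Sigma1, dtheta = 1,
                                ridge = 0) {
  f1 <- as.numeric(f1); f2 <- as.numeric(f2)
  n <- length(f1)
  if (length(f2) != n) stop("f1 and f2 differ in length", call. = FALSE)
  Sigma1 <- unname(check_symmetric(as.matrix(Sigma1), name = "Sigma1"))
  Sigma2 <- unname(check_symmetric(as.matrix(Sigma2), name = "Sigma2"))
  if (nrow(Sigma1) != n || nrow(Sigma2) != n)
    stop("covariance dimension disagrees with mean length", call. = FALSE)
  stopifnot_scalar(dtheta, "dtheta")
  if (dtheta <= 0) stop("`dtheta` must be positive", call. = FALSE)
  structure(list(f1 = f1, f2 = f2, df = f2 - f1,
                 Sigma1 = Sigma1, Sigma2 = Sigma2,
                 Sigma_bar = (Sigma1 + Sigma2) / 2,
                 dtheta = dtheta, n = n, ridge = ridge),
            class = "population_geometry")
}

#' @export
print.population_geometry <- function(x, ...) {
  cat(sprintf("<population_geometry: n=%d units, dtheta=%g, |df|=%.4g, ridge=%g>\n",
              x$n, x$dtheta, sqrt(sum(x$df^2)), x$ridge))
  invisible(x)
}

# pooled covariance with the recorded ridge applied
ridged_sigma <- function(geom) {
  S <- geom$Sigma_bar
  if (geom$ridge > 0) S <- S + diag(geom$ridge * mean(diag(S)), geom$n)
  S
}

#' Signal separation (length of the signal vector)
#' @param geom a `population_geometry`.
#' @return Euclidean norm of `df`, in response units.
#' @export
signal_separation <- function(geom) sqrt(sum(geom$df^2))

#' Decompose a condition covariance into scale and correlation
#'
#' Returns the diagonal standard-deviation matrix `V` and correlation matrix
#' `C` such that `Sigma = V %*% C %*% V` (V is symmetric so this equals
#' `t(V) C V`). Zero-variance units yield zero rows/columns in `C` off the
#' diagonal.
#'
#' @param Sigma covariance matrix.
#' @return list with `V`, `C`.
#' @export
scale_correlation <- function(Sigma) {
  Sigma <- check_symmetric(as.matrix(Sigma))
  s <- sqrt(pmax(diag(Sigma), 0))
  inv <- ifelse(s > 0, 1 / s, 0)
  C <- Sigma * tcrossprod(inv)
  diag(C) <- 1
  list(V = diag(s, nrow(Sigma)), C = C)
}

#' Estimate the pre/post manifold geometry from trials
#'
#' Computes sample means and unbiased (T-1) covariances for two stimulus
#' conditions of a response set, the pooled covariance (their exact average),
#' and the signal vector.
#'
#' @param set a `response_set`.
#' @param conditions length-2 vector naming the condition pair (numeric
#'   stimulus values); defaults to the first two conditions.
#' @param dtheta stimulus separation; defaults to the difference between the
#'   two condition values.
#' @param ridge ridge fraction used downstream (default `1e-6`), recorded in
#'   the geometry.
#' @return A `population_geometry`.
#' @export
estimate_geometry <- function(set, conditions = NULL, dtheta = NULL,
                              ridge = 1e-6) {
  validate_response_set(set)
  if (is.null(conditions)) conditions <- set$conditions[1:2]
  if (length(conditions) != 2L)
    stop("exactly two conditions must be selected", call. = FALSE)
  idx <- match(conditions, set$conditions)
  if (anyNA(idx)) stop("condition not present in set", call. = FALSE)
  m1 <- set$responses[[idx[1L]]]; m2 <- set$responses[[idx[2L]]]
  if (is.null(dtheta)) dtheta <- abs(diff(conditions))
  stopifnot_scalar(dtheta, "dtheta")
  if (dtheta <= 0) stop("`dtheta` must be positive", call. = FALSE)
  population_geometry(colMeans(m1), colMeans(m2),
                      stats::cov(m1), stats::cov(m2),
                      dtheta = dtheta, ridge = ridge)
}

#' Averaged linear Fisher information
#'
#' Computes `aLFI = (1/n) * df' Sigma_bar^{-1} df / dtheta^2`, the linear
#' Fisher information per unit and per squared stimulus separation. The
#' quadratic form is evaluated through a Cholesky linear solve on the ridged
#' pooled covariance, never an explicit inverse.
#'
#' @param geom a `population_geometry`.
#' @return Non-negative scalar, in 1/(unit * stimulus-unit squared).
#' @export
alfi <- function(geom) {
  S <- ridged_sigma(geom)
  R <- tryCatch(chol(S), error = function(e) e)
  if (inherits(R, "error")) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    kappa <- max(ev) / max(min(ev), .Machine$double.xmin)
    stop(sprintf(
      "pooled covariance is singular (condition number %.3g); increase `ridge`",
      kappa), call. = FALSE)
  }
  z <- backsolve(R, geom$df, transpose = TRUE)
  sum(z^2) / (geom$n * geom$dtheta^2)
}

#' Eigendecompose the pooled covariance
#'
#' Symmetric eigendecomposition of the (ridged) pooled covariance, with
#' eigenvalues sorted descending and each eigenvector's sign fixed so its
#' largest-magnitude entry is positive. Also returns the normalised
#' quantities used by the eigenform of the information: the mean variance
#' `lambda_bar`, relative eigenvalues `lambda_hat` (mean 1), and the unit
#' signal vector `df_hat`.
#'
#' @param geom a `population_geometry`.
#' @return An object of class `eigen_geometry` with fields `values`,
#'   `vectors`, `lambda_bar`, `lambda_hat`, `df_hat`, `n`, `dtheta`.
#' @export
eigendecompose <- function(geom) {
  S <- ridged_sigma(geom)
  e <- eigen(S, symmetric = TRUE)
  lmax <- max(abs(e$values))
  if (min(e$values) < -1e-10 * max(lmax, 1))
    stop("pooled covariance has a substantially negative eigenvalue", call. = FALSE)
  lam <- pmax(e$values, 0)
  vec <- e$vectors
  for (i in seq_len(ncol(vec))) {
    j <- which.max(abs(vec[, i]))
    if (vec[j, i] < 0) vec[, i] <- -vec[, i]
  }
  lb <- mean(lam)
  nd <- sqrt(sum(geom$df^2))
  structure(list(values = lam, vectors = vec,
                 lambda_bar = lb,
                 lambda_hat = lam / lb,
                 df_hat = if (nd > 0) geom$df / nd else geom$df,
                 signal_sep = nd,
                 n = geom$n, dtheta = geom$dtheta),
            class = "eigen_geometry")
}

# sum_i (u' xi_i)^2 / lambda_hat_i over non-degenerate components
eigenform_sum <- function(u, eig) {
  proj2 <- as.numeric(crossprod(eig$vectors, u))^2
  keep <- eig$lambda_hat > 0
  sum(proj2[keep] / eig$lambda_hat[keep])
}

#' aLFI in eigendecomposition form
#'
#' Evaluates the information through the spectrum of the pooled covariance:
#' `aLFI = (1/(n dtheta^2)) * (|df|^2 / lambda_bar) *
#' sum_i (df_hat' xi_i)^2 / lambda_hat_i`. Algebraically identical to
#' [alfi()]; exposed separately because the factorisation into signal length,
#' mean variance, signal direction and eigenstructure is what the stepwise
#' mechanism decomposition manipulates. Zero-eigenvalue components are
#' excluded (consistent with the ridge policy).
#'
#' @param geom a `population_geometry`.
#' @param eig its [eigendecompose()] result; recomputed if missing.
#' @return Scalar equal to `alfi(geom)` to relative 1e-8.
#' @export
alfi_eigenform <- function(geom, eig = eigendecompose(geom)) {
  if (eig$n != geom$n) stop("eigen geometry dimension mismatch", call. = FALSE)
  sep2 <- sum(geom$df^2)
  if (sep2 == 0) return(0)
  (sep2 / eig$lambda_bar) * eigenform_sum(eig$df_hat, eig) /
    (geom$n * geom$dtheta^2)
}

#' Stepwise four-mechanism decomposition of information gain
#'
#' Decomposes the pre-to-post change in aLFI into four geometric mechanisms
#' by switching the pre-test quantities to their post-test values one at a
#' time, in the fixed order signal enhancement (|df|^2), manifold shrinkage
#' (mean variance lambda_bar), signal rotation (signal direction df_hat) and
#' manifold warping (eigenvectors and relative eigenvalues):
#'
#'   aLFI_pre  : all pre
#'   aLFI_se   : post |df|^2,  pre lambda_bar, pre direction, pre spectrum
#'   aLFI_ms   : post |df|^2,  post lambda_bar, pre direction, pre spectrum
#'   aLFI_sr   : post |df|^2,  post lambda_bar, post direction, pre spectrum
#'   aLFI_post : all post (= aLFI_mw)
#'
#' Marginal contributions are the successive differences and sum exactly to
#' `alfi_post - alfi_pre`; `alfi_post` equals the direct quadratic-form
#' evaluation on the post geometry.
#'
#' @param pre,post `population_geometry` objects over the same units and the
#'   same stimulus separation.
#' @return An object of class `stepwise_decomposition`: the five aLFI values
#'   (`alfi_pre`, `alfi_se`, `alfi_ms`, `alfi_sr`, `alfi_post`), marginal
#'   `contributions` (named `se`, `ms`, `sr`, `mw`), `cumulative` gains vs
#'   pre, and the `signal_rotation_angle` in degrees.
#' @export
stepwise_decomposition <- function(pre, post) {
  if (pre$n != post$n)
    stop("pre and post unit counts differ", call. = FALSE)
  if (abs(pre$dtheta - post$dtheta) > 1e-12 * max(pre$dtheta, 1))
    stop("pre and post stimulus separations differ", call. = FALSE)
  e_pre <- eigendecompose(pre)
  e_post <- eigendecompose(post)
  k <- 1 / (pre$n * pre$dtheta^2)
  sep2_pre <- sum(pre$df^2)
  sep2_post <- sum(post$df^2)
  s_pre_pre <- eigenform_sum(e_pre$df_hat, e_pre)
  s_post_pre <- eigenform_sum(e_post$df_hat, e_pre)
  s_post_post <- eigenform_sum(e_post$df_hat, e_post)

  a_pre <- k * sep2_pre / e_pre$lambda_bar * s_pre_pre
  a_se <- k * sep2_post / e_pre$lambda_bar * s_pre_pre
  a_ms <- k * sep2_post / e_post$lambda_bar * s_pre_pre
  a_sr <- k * sep2_post / e_post$lambda_bar * s_post_pre
  a_post <- k * sep2_post / e_post$lambda_bar * s_post_post

  contrib <- c(se = a_se - a_pre, ms = a_ms - a_se,
               sr = a_sr - a_ms, mw = a_post - a_sr)
  structure(list(
    alfi_pre = a_pre, alfi_se = a_se, alfi_ms = a_ms,
    alfi_sr = a_sr, alfi_post = a_post,
    contributions = contrib,
    cumulative = c(se = a_se, ms = a_ms, sr = a_sr, mw = a_post) - a_pre,
    signal_rotation_angle = signal_rotation_angle(pre, post),
    n = pre$n, dtheta = pre$dtheta),
    class = "stepwise_decomposition")
}

#' @export
print.stepwise_decomposition <- function(x, ...) {
  cat(sprintf("<stepwise_decomposition: n=%d, dtheta=%g>\n", x$n, x$dtheta))
  cat(sprintf("  aLFI pre %.6g -> post %.6g (gain %.6g)\n",
              x$alfi_pre, x$alfi_post, x$alfi_post - x$alfi_pre))
  cat("  marginal contributions:\n")
  for (nm in names(x$contributions))
    cat(sprintf("    %-2s %+.6g\n", nm, x$contributions[[nm]]))
  if (is.finite(x$signal_rotation_angle))
    cat(sprintf("  signal rotation angle %.2f deg\n", x$signal_rotation_angle))
  invisible(x)
}

#' Signal rotation angle between phases
#'
#' Angle between the pre- and post-training signal vectors, in degrees,
#' from the arc-cosine of the (clipped) dot product of the unit signal
#' vectors. Range 0-180 degrees.
#'
#' @param pre,post `population_geometry` objects.
#' @return Angle in degrees, or `NA` (with a warning) if either signal
#'   vector is zero.
#' @export
signal_rotation_angle <- function(pre, post) {
  n1 <- sqrt(sum(pre$df^2)); n2 <- sqrt(sum(post$df^2))
  if (n1 == 0 || n2 == 0) {
    warning("signal rotation angle undefined for a zero signal vector",
            call. = FALSE)
    return(NA_real_)
  }
  d <- sum(pre$df * post$df) / (n1 * n2)
  acos(min(1, max(-1, d))) * 180 / pi
}

#' Compare principal-component geometry across phases
#'
#' Matches principal components of the pre and post pooled covariances by
#' variance rank, truncating at the smallest number of components whose
#' cumulative variance reaches `coverage` in either phase, and reports the
#' PC strengths (eigenvalue spectra) and per-component rotation angles
#' `acos(|xi_pre . xi_post|)` in 0-90 degrees. Components with (near-)tied
#' eigenvalues are flagged: their individual directions are not identifiable.
#'
#' @param pre,post `population_geometry` or `eigen_geometry` objects.
#' @param coverage cumulative-variance fraction in (0, 1]; default 0.99.
#' @param tie_tol relative eigen-gap below which a component is flagged
#'   non-identifiable.
#' @return An object of class `geometry_comparison`: `n_components`,
#'   `pc_angles` (degrees), `tied` (logical), eigenvalue spectra
#'   `values_pre`/`values_post`, total variances, and — when full geometries
#'   were supplied — signal separations and the signal rotation angle.
#' @export
pc_comparison <- function(pre, post, coverage = 0.99, tie_tol = 1e-6) {
  if (!(coverage > 0 && coverage <= 1))
    stop("`coverage` must be in (0, 1]", call. = FALSE)
  geoms <- NULL
  if (inherits(pre, "population_geometry")) {
    geoms <- list(pre = pre, post = post)
    pre <- eigendecompose(pre); post <- eigendecompose(post)
  }
  if (pre$n != post$n) stop("unit counts differ", call. = FALSE)
  m_for <- function(e) {
    cum <- cumsum(e$values) / sum(e$values)
    which(cum >= coverage - 1e-12)[1L]
  }
  m <- max(m_for(pre), m_for(post))
  ang <- acos(pmin(1, abs(colSums(pre$vectors[, seq_len(m), drop = FALSE] *
                                  post$vectors[, seq_len(m), drop = FALSE])))) * 180 / pi
  gap <- function(e, i) {
    lo <- if (i < e$n) abs(e$values[i] - e$values[i + 1L]) else Inf
    hi <- if (i > 1L) abs(e$values[i] - e$values[i - 1L]) else Inf
    min(lo, hi) / max(e$values[1L], .Machine$double.eps)
  }
  tied <- vapply(seq_len(m), function(i) gap(pre, i) < tie_tol || gap(post, i) < tie_tol,
                 logical(1L))
  out <- list(n_components = m, coverage = coverage,
              pc_angles = ang, tied = tied,
              values_pre = pre$values, values_post = post$values,
              total_variance_pre = sum(pre$values),
              total_variance_post = sum(post$values))
  if (!is.null(geoms)) {
    out$signal_separation_pre <- signal_separation(geoms$pre)
    out$signal_separation_post <- signal_separation(geoms$post)
    out$signal_rotation_angle <- signal_rotation_angle(geoms$pre, geoms$post)
  }
  structure(out, class = "geometry_comparison")
}

#' @export
print.geometry_comparison <- function(x, ...) {
  cat(sprintf("<geometry_comparison: %d matched PCs at %.0f%% coverage>\n",
              x$n_components, 100 * x$coverage))
  cat("  PC rotation angles (deg):",
      paste(sprintf("%.1f%s", x$pc_angles, ifelse(x$tied, "*", "")),
            collapse = ", "), "\n")
  if (any(x$tied)) cat("  (* tied eigenvalue: direction not identifiable)\n")
  cat(sprintf("  total variance pre %.4g -> post %.4g\n",
              x$total_variance_pre, x$total_variance_post))
  invisible(x)
}
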