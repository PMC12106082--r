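# Multivariate Poisson log-normal (PLN) moment relations.
#
# Spike counts y_i are Poisson around log-normally varying latent rates:
# x ~ N(mu, Sigma_x), y_i | x ~ Poisson(exp(x_i) * window). The count
# moments are available in closed form, and inverting them gives a simple
# moment-matching estimator of the latent rate mean and covariance — the
# route used here to recover trial-by-trial rate variability from spiking
# data before computing population-geometry metrics.

#' PLN count moments from latent log-rate moments
#'
#' Closed-form mean and covariance of PLN counts:
#' `m_i = w * exp(mu_i + Sigma_x_ii / 2)`;
#' `Cov_ii = m_i + m_i^2 (exp(Sigma_x_ii) - 1)`;
#' `Cov_ij = m_i m_j (exp(Sigma_x_ij) - 1)` for `i != j`.
#' The implied Fano factor is always >= 1 (PLN counts are over-dispersed).
#'
#' @param mu latent log-rate mean vector.
#' @param Sigma_x latent log-rate covariance (PSD; checked).
#' @param window count window in seconds.
#' @return A list with `mean` (count mean vector), `cov` (count covariance),
#'   `rate_mean` and `rate_cov` (the same moments on the rate scale, spk/s).
#' @export
pln_forward <- function(mu, Sigma_x, window = 1) {
  stopifnot_scalar(window, "window")
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  mu <- as.numeric(mu)
  Sigma_x <- check_symmetric(as.matrix(Sigma_x), name = "Sigma_x")
  ev <- eigen(Sigma_x, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("`Sigma_x` must be positive semi-definite", call. = FALSE)
  # rate moments: E r_i = exp(mu_i + s_ii/2); Cov(r)_ij = Er_i Er_j (e^{s_ij}-1)
  r <- exp(mu + diag(Sigma_x) / 2)
  rate_cov <- tcrossprod(r) * (exp(Sigma_x) - 1)
  m <- window * r
  cv <- window^2 * rate_cov
  diag(cv) <- diag(cv) + m          # Poisson noise adds the mean on the diagonal
  list(mean = m, cov = cv, rate_mean = r, rate_cov = rate_cov)
}

#' Moment-matching PLN estimator
#'
#' Inverts the [pln_forward()] relations at the sample count moments:
#' `Sigma_x_ij = log(1 + (Cov_ij - delta_ij m_i) / (m_i m_j))` and
#' `mu_i = log(m_i / w) - Sigma_x_ii / 2`. Sub-Poisson sample variances
#' (which would give a negative diagonal) are floored to 0 and flagged;
#' off-diagonal log arguments <= 0 are floored at 1e-8 and flagged. The
#' resulting latent covariance is PSD-repaired by eigenvalue flooring, with
#' a hard error if the repair distorts more than 5 percent of the trace
#' (data inconsistent with the model).
#'
#' @param counts integer matrix trials x units (>= 10 trials), e.g. from
#'   [sample_counts_pln()]; a `window` attribute, if present, supplies the
#'   default window.
#' @param window count window in seconds.
#' @return An object of class `pln_estimate`: `mu`, `Sigma_x`, `rate_mean`,
#'   `rate_cov`, `floored` (logical matrix of floored entries),
#'   `psd_distortion`.
#' @export
pln_fit_moments <- function(counts, window = attr(counts, "window") %||% 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 10L) stop("need >= 10 trials", call. = FALSE)
  if (any(counts < 0) || max(abs(counts - round(counts))) > 0)
    stop("`counts` must be non-negative integers", call. = FALSE)
  stopifnot_scalar(window, "window")
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  m <- colMeans(counts)
  if (any(m == 0)) {
    bad <- colnames(counts)[m == 0]
    if (is.null(bad)) bad <- which(m == 0)
    stop("unit(s) with zero mean count: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  S <- stats::cov(counts)
  arg <- 1 + (S - diag(m, length(m))) / tcrossprod(m)
  floored <- arg <= 0 | (row(arg) == col(arg) & arg < 1)
  arg[arg <= 0] <- 1e-8
  Sigma_x <- log(arg)
  diag(Sigma_x) <- pmax(diag(Sigma_x), 0)   # sub-Poisson variance -> 0
  Sigma_x <- (Sigma_x + t(Sigma_x)) / 2
  rep_ <- psd_floor(Sigma_x, max_distortion = 0.05, warn = FALSE,
                    name = "latent covariance")
  Sigma_x <- rep_$mat
  mu <- log(m / window) - diag(Sigma_x) / 2
  fwd <- pln_forward(mu, Sigma_x, window)
  structure(list(mu = mu, Sigma_x = Sigma_x,
                 rate_mean = fwd$rate_mean, rate_cov = fwd$rate_cov,
                 window = window, floored = floored,
                 psd_distortion = rep_$distortion),
            class = "pln_estimate")
}

#' @export
print.pln_estimate <- function(x, ...) {
  cat(sprintf("<pln_estimate: %d units, window %gs, mean rate %.3g spk/s>\n",
              length(x$mu), x$window, mean(x$rate_mean)))
  if (any(x$floored))
    cat(sprintf("  %d moment entr%s floored during inversion\n",
                sum(x$floored), if (sum(x$floored) == 1) "y" else "ies"))
  if (x$psd_distortion > 0)
    cat(sprintf("  PSD repair distorted %.3g%% of spectral mass\n",
                100 * x$psd_distortion))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
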