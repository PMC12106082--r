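# Single-unit response metrics: tuning curves, Fano factor, noise and signal
# correlations, and behavioural threshold-versus-noise (TvN) interpolation.

#' Estimate tuning curves from a stimulus sweep
#'
#' The raw curve is the per-stimulus trial mean; smoothing convolves it with
#' a circular (wrap-around) Gaussian kernel of the stated width on the
#' stimulus domain. The kernel is normalised, so a constant response is
#' conserved; `kernel_sigma = 0` disables smoothing.
#'
#' @param sweep either a list of trial x unit matrices (one per grid point)
#'   or a grid x unit matrix of trial-mean responses.
#' @param grid stimulus grid in degrees, strictly increasing; defaults to the
#'   list names of `sweep`.
#' @param kernel_sigma Gaussian kernel width in degrees (default 10).
#' @param period stimulus domain period: 180 (orientation) or 360
#'   (direction); default 180.
#' @return An object of class `tuning_curves` with fields `grid`, `raw` and
#'   `smoothed` (grid x unit matrices), `kernel_sigma`, `period`.
#' @export
tuning_curve <- function(sweep, grid = NULL, kernel_sigma = 10, period = 180) {
  if (kernel_sigma < 0) stop("`kernel_sigma` must be >= 0", call. = FALSE)
  if (is.list(sweep)) {
    if (is.null(grid)) grid <- as.numeric(names(sweep))
    raw <- do.call(rbind, lapply(sweep, function(m) colMeans(as.matrix(m))))
  } else {
    raw <- as.matrix(sweep)
  }
  if (is.null(grid) || anyNA(grid))
    stop("a numeric stimulus `grid` is required", call. = FALSE)
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop("empty stimulus grid", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("`grid` must be strictly increasing", call. = FALSE)
  if (nrow(raw) != length(grid))
    stop("`sweep` rows disagree with grid length", call. = FALSE)
  if (kernel_sigma == 0) {
    smoothed <- raw
  } else {
    d <- outer(grid, grid, function(a, b) circ_dist(a, b, period))
    W <- exp(-d^2 / (2 * kernel_sigma^2))
    W <- W / rowSums(W)
    smoothed <- W %*% raw
  }
  dimnames(smoothed) <- dimnames(raw)
  structure(list(grid = grid, raw = raw, smoothed = smoothed,
                 kernel_sigma = kernel_sigma, period = period),
            class = "tuning_curves")
}

# circular Gaussian tuning model
tuning_model <- function(par, grid, period) {
  d <- circ_dist(grid, par[3L], period)
  par[1L] + par[2L] * exp(-d^2 / (2 * par[4L]^2))
}

#' Fit Gaussian tuning functions
#'
#' Least-squares fit of `baseline + amplitude * exp(-d_circ(theta,
#' preferred)^2 / (2 sigma^2))` to each unit's smoothed tuning curve, with
#' circular distance on the stimulus domain. Initialised at the empirical
#' peak, refined from a small width grid. Curves whose amplitude is
#' indistinguishable from zero are flagged degenerate instead of fitted.
#' Each fitted curve is also rescaled so its fitted minimum maps to 0 and
#' maximum to 1.
#'
#' @param curves a [tuning_curve()] result.
#' @param flat_tol amplitude (relative to the response range tolerance)
#'   below which a curve counts as flat.
#' @return A data frame with one row per unit: `baseline`, `amplitude`,
#'   `preferred`, `width`, `sse`, `converged`, `degenerate`. The rescaled
#'   fitted curves (grid x unit) are attached as attribute `"rescaled"`.
#' @export
fit_tuning <- function(curves, flat_tol = 1e-8) {
  if (!inherits(curves, "tuning_curves")) stop("not a tuning_curves object", call. = FALSE)
  grid <- curves$grid; period <- curves$period
  nu <- ncol(curves$smoothed)
  out <- data.frame(baseline = rep(NA_real_, nu), amplitude = NA_real_,
                    preferred = NA_real_, width = NA_real_, sse = NA_real_,
                    converged = FALSE, degenerate = FALSE)
  rownames(out) <- colnames(curves$smoothed)
  rescaled <- matrix(NA_real_, length(grid), nu,
                     dimnames = dimnames(curves$smoothed))
  for (j in seq_len(nu)) {
    y <- curves$smoothed[, j]
    rng <- diff(range(y))
    if (rng <= flat_tol * max(1, max(abs(y)))) {
      out$degenerate[j] <- TRUE
      next
    }
    peak <- grid[which.max(y)]
    obj <- function(p) sum((y - tuning_model(p, grid, period))^2)
    best <- NULL
    for (w0 in c(period / 16, period / 8, period / 4)) {
      p0 <- c(min(y), rng, peak, w0)
      fit <- stats::nlminb(p0, obj,
                           lower = c(-Inf, 0, -Inf, period / 1000),
                           upper = c(Inf, Inf, Inf, period))
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    p <- best$par
    p[3L] <- p[3L] %% period
    out$baseline[j] <- p[1L]; out$amplitude[j] <- p[2L]
    out$preferred[j] <- p[3L]; out$width[j] <- p[4L]
    out$sse[j] <- best$objective
    out$converged[j] <- best$convergence == 0
    fitc <- tuning_model(p, grid, period)
    rescaled[, j] <- (fitc - p[1L]) / p[2L]
  }
  attr(out, "rescaled") <- rescaled
  out
}

#' Group-level tuning curve
#'
#' Normalises each unit's smoothed tuning curve by its maximum response and
#' averages across units, giving one group curve suitable for a group-level
#' Gaussian fit (the per-unit path is [fit_tuning()] directly).
#'
#' @param curves a [tuning_curve()] result.
#' @return A `tuning_curves` object with a single column `group`.
#' @export
group_tuning <- function(curves) {
  if (!inherits(curves, "tuning_curves")) stop("not a tuning_curves object", call. = FALSE)
  mx <- apply(curves$smoothed, 2L, max)
  ok <- mx > 0
  if (!any(ok)) stop("all units have non-positive maxima", call. = FALSE)
  g <- rowMeans(sweep(curves$smoothed[, ok, drop = FALSE], 2L, mx[ok], "/"))
  structure(list(grid = curves$grid,
                 raw = matrix(g, dimnames = list(NULL, "group")),
                 smoothed = matrix(g, dimnames = list(NULL, "group")),
                 kernel_sigma = curves$kernel_sigma, period = curves$period),
            class = "tuning_curves")
}

#' Fano factor per unit
#'
#' Trial-to-trial variance-to-mean ratio of each unit's response, using the
#' unbiased (T-1) variance. Zero-mean units return `NA` with a warning
#' rather than an infinite ratio.
#'
#' @param responses trial x unit numeric matrix (>= 2 trials).
#' @return Named numeric vector of Fano factors.
#' @export
fano_factor <- function(responses) {
  responses <- as.matrix(responses)
  if (nrow(responses) < 2L) stop("need >= 2 trials", call. = FALSE)
  m <- colMeans(responses)
  v <- apply(responses, 2L, stats::var)
  ff <- ifelse(m == 0, NA_real_, v / m)
  if (anyNA(ff))
    warning("Fano factor undefined for zero-mean unit(s): ",
            paste(colnames(responses)[is.na(ff)], collapse = ", "),
            call. = FALSE)
  names(ff) <- colnames(responses)
  ff
}

#' Noise correlations
#'
#' Pearson correlations of trial-by-trial responses computed within each
#' stimulus condition (so stimulus-driven covariation never inflates them),
#' then averaged across conditions. Zero-variance units are excluded with a
#' warning. The summary statistic is the median of the strictly lower
#' triangle.
#'
#' @param responses a `response_set`, or a named list of trial x unit
#'   matrices (one per condition; >= 3 trials each).
#' @return A list with `matrix` (unit x unit, diagonal 1), `median`, and
#'   `excluded` (ids of zero-variance units).
#' @export
noise_correlations <- function(responses) {
  if (inherits(responses, "response_set")) responses <- responses$responses
  responses <- lapply(responses, as.matrix)
  if (any(vapply(responses, nrow, 0L) < 3L))
    stop("need >= 3 trials per condition", call. = FALSE)
  sds <- lapply(responses, function(m) apply(m, 2L, stats::sd))
  ok <- Reduce(`&`, lapply(sds, function(s) s > 0))
  if (!any(ok)) stop("all units have zero variance", call. = FALSE)
  excluded <- colnames(responses[[1L]])[!ok]
  if (length(excluded))
    warning("zero-variance unit(s) excluded: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  mats <- lapply(responses, function(m) stats::cor(m[, ok, drop = FALSE]))
  R <- Reduce(`+`, mats) / length(mats)
  diag(R) <- 1
  list(matrix = R, median = stats::median(R[lower.tri(R)]),
       excluded = excluded)
}

#' Signal correlations
#'
#' Pearson correlation between units' mean tuning curves across the stimulus
#' grid: units with similar tuning have positive signal correlation. Flat
#' curves yield `NA` entries (flagged by a warning).
#'
#' @param curves a [tuning_curve()] result, or a grid x unit matrix of mean
#'   responses (>= 3 grid points).
#' @return Unit x unit correlation matrix.
#' @export
signal_correlations <- function(curves) {
  m <- if (inherits(curves, "tuning_curves")) curves$raw else as.matrix(curves)
  if (nrow(m) < 3L) stop("need >= 3 grid points", call. = FALSE)
  flat <- apply(m, 2L, stats::sd) == 0
  if (any(flat))
    warning("flat tuning curve(s) give undefined signal correlations: ",
            paste(colnames(m)[flat], collapse = ", "), call. = FALSE)
  suppressWarnings(stats::cor(m))
}

#' Contrast thresholds from a psychometric accuracy surface (TvN)
#'
#' For each external-noise level, interpolates the accuracy-versus-contrast
#' psychometric curve — in log10 contrast by default, the psychophysics
#' convention — and returns the contrast at the first upward crossing of the
#' criterion accuracy. Rows whose accuracy never reaches the criterion give
#' `NA`. Plotting threshold against noise level yields the TvN function;
#' training shifts it downward.
#'
#' @param accuracy matrix of proportions correct, noise levels x contrast
#'   levels, values in \[0, 1\].
#' @param contrasts strictly increasing contrast levels (decimal), >= 2.
#' @param noise_levels optional labels for the rows.
#' @param criterion criterion accuracy in (0.5, 1); the conventional values
#'   are 0.55 for pre-test and 0.70 for post-test.
#' @param log_contrast interpolate in log10 contrast (default) or linear
#'   contrast.
#' @return Named numeric vector of contrast thresholds, one per noise level.
#' @export
tvn_thresholds <- function(accuracy, contrasts, noise_levels = NULL,
                           criterion = 0.70, log_contrast = TRUE) {
  accuracy <- as.matrix(accuracy)
  if (length(contrasts) < 2L) stop("need >= 2 contrast levels", call. = FALSE)
  if (any(diff(contrasts) <= 0)) stop("`contrasts` must be strictly increasing", call. = FALSE)
  if (ncol(accuracy) != length(contrasts))
    stop("accuracy columns disagree with contrast levels", call. = FALSE)
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracies must lie in [0, 1]", call. = FALSE)
  if (!(criterion > 0.5 && criterion < 1))
    stop("`criterion` must be in (0.5, 1)", call. = FALSE)
  xs <- if (log_contrast) log10(contrasts) else contrasts
  thr <- apply(accuracy, 1L, function(acc) {
    hit <- which(acc >= criterion)
    if (!length(hit)) return(NA_real_)
    i <- hit[1L]
    if (acc[i] == criterion || i == 1L) {
      x <- xs[i]
    } else {
      # linear interpolation on the segment crossing upward
      x <- xs[i - 1L] + (criterion - acc[i - 1L]) / (acc[i] - acc[i - 1L]) *
        (xs[i] - xs[i - 1L])
    }
    if (log_contrast) 10^x else x
  })
  names(thr) <- if (!is.null(noise_levels)) as.character(noise_levels)
                else rownames(accuracy)
  thr
}
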