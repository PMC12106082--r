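# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so that seeded sampling inside
#' the package never perturbs (or depends on) the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# circular distance between angles on a domain of the given period
circ_dist <- function(a, b, period) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# symmetric check with tolerance
check_symmetric <- function(S, tol = 1e-10, name = "covariance") {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop(name, " must be a square matrix", call. = FALSE)
  if (max(abs(S - t(S))) > tol * max(1, max(abs(S))))
    stop(name, " is not symmetric within tolerance", call. = FALSE)
  (S + t(S)) / 2
}

# nearest-PSD projection by eigenvalue flooring at zero; errors if the
# flooring removes more than `max_distortion` of the trace
psd_floor <- function(S, max_distortion = 0.01, warn = TRUE, name = "covariance") {
  S <- check_symmetric(S, name = name)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= 0) return(list(mat = S, floored = FALSE, distortion = 0))
  lam <- pmax(e$values, 0)
  distortion <- sum(abs(pmin(e$values, 0))) / max(sum(abs(e$values)), .Machine$double.eps)
  if (distortion > max_distortion)
    stop(sprintf("%s is not positive semi-definite: flooring would distort %.2f%% of spectral mass (limit %.2f%%)",
                 name, 100 * distortion, 100 * max_distortion), call. = FALSE)
  if (warn)
    warning(sprintf("%s had negative eigenvalues floored to 0 (%.3g%% of spectral mass)",
                    name, 100 * distortion), call. = FALSE)
  list(mat = e$vectors %*% (lam * t(e$vectors)), floored = TRUE, distortion = distortion)
}

# full-precision numeric formatting so CSV round-trips are bit exact
fmt_full <- function(x) sprintf("%.17g", x)

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a single finite number", call. = FALSE)
  invisible(x)
}
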