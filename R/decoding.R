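# Cross-validated linear population decoding.
#
# The default readout is the Fisher linear discriminant (FLD): weights
# w = Sigma_bar^{-1} df fitted on training folds only, with the decision
# boundary at the projected midpoint of the two class means. A
# ridge-penalised logistic readout (glmnet, fixed small lambda) is the
# alternative for data where the population covariance is too ill-conditioned
# for the FLD.

#' Sigmoid choice probability
#'
#' Classification confidence of a two-alternative choice from the two scalar
#' readouts (target vs reference): `p = exp(h_t - h_r) / (1 + exp(h_t -
#' h_r))`. Numerically stable for arbitrarily large differences.
#'
#' @param h_t,h_r finite scalar (or vector) readouts.
#' @return Probability in \[0, 1\].
#' @export
sigmoid_choice <- function(h_t, h_r) {
  d <- h_t - h_r
  if (any(!is.finite(d))) stop("inputs must be finite", call. = FALSE)
  # stable two-branch logistic
  p <- ifelse(d >= 0, 1 / (1 + exp(-d)), exp(d) / (1 + exp(d)))
  as.numeric(p)
}

# stratified fold assignment for two classes
make_folds <- function(n1, n2, scheme, k, seed) {
  with_seed(seed, {
    f1 <- switch(scheme,
      half_split = sample(rep(1:2, length.out = n1)),
      kfold = sample(rep(seq_len(k), length.out = n1)),
      leave_one_trial_out = seq_len(n1))
    f2 <- switch(scheme,
      half_split = sample(rep(1:2, length.out = n2)),
      kfold = sample(rep(seq_len(k), length.out = n2)),
      leave_one_trial_out = seq_len(n2))
    list(f1 = f1, f2 = f2,
         nfold = switch(scheme, half_split = 2L, kfold = as.integer(k),
                        leave_one_trial_out = max(n1, n2)))
  })
}

fld_fit <- function(x1, x2, ridge) {
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  S <- (stats::cov(x1) + stats::cov(x2)) / 2
  S <- S + diag(max(ridge * mean(diag(S)), 1e-12), ncol(S))
  w <- solve(S, mu2 - mu1)
  list(w = w, b = sum(w * (mu1 + mu2) / 2))
}

#' Cross-validated linear decoding accuracy
#'
#' Trains a linear classifier to discriminate two stimulus conditions of a
#' response set and reports held-out accuracy under one of the
#' cross-validation schemes used across dataset types: a single stratified
#' half split (artificial units), leave-one-trial-out (fMRI), or stratified
#' k-fold (spiking data, k = 10).
#'
#' @param set a `response_set`.
#' @param conditions length-2 condition pair; defaults to the first two.
#' @param scheme `"half_split"`, `"kfold"` or `"leave_one_trial_out"`.
#' @param k folds for `"kfold"` (default 10).
#' @param classifier `"fld"` (default) or `"logistic"` (ridge-penalised,
#'   fixed small lambda).
#' @param seed integer seed for the fold assignment.
#' @param ridge ridge fraction for the FLD pooled covariance (default 1e-6).
#' @param repeats number of repeated random splits to average (half split
#'   and k-fold only; default 1).
#' @return An object of class `decoder_result`: `accuracy` (mean over
#'   folds), `fold_accuracy`, `weights` (from a fit on all trials),
#'   `scheme`, `classifier`, `seed`.
#' @export
decode_accuracy <- function(set, conditions = NULL,
                            scheme = c("half_split", "kfold", "leave_one_trial_out"),
                            k = 10, classifier = c("fld", "logistic"),
                            seed = 1, ridge = 1e-6, repeats = 1) {
  scheme <- match.arg(scheme)
  classifier <- match.arg(classifier)
  validate_response_set(set)
  if (is.null(conditions)) conditions <- set$conditions[1:2]
  idx <- match(conditions, set$conditions)
  if (anyNA(idx)) stop("condition not present in set", call. = FALSE)
  x1 <- set$responses[[idx[1L]]]; x2 <- set$responses[[idx[2L]]]
  if (nrow(x1) < 4L || nrow(x2) < 4L)
    stop("need >= 4 trials per condition", call. = FALSE)
  if (scheme == "leave_one_trial_out") repeats <- 1L

  run_once <- function(seed_r) {
    folds <- make_folds(nrow(x1), nrow(x2), scheme, k, seed_r)
    acc <- numeric(0)
    for (f in seq_len(folds$nfold)) {
      tr1 <- x1[folds$f1 != f, , drop = FALSE]
      tr2 <- x2[folds$f2 != f, , drop = FALSE]
      te1 <- x1[folds$f1 == f, , drop = FALSE]
      te2 <- x2[folds$f2 == f, , drop = FALSE]
      if (nrow(te1) + nrow(te2) == 0L) next
      if (nrow(tr1) < 2L || nrow(tr2) < 2L)
        stop("a training fold contains fewer than two trials of one class",
             call. = FALSE)
      pred <- if (classifier == "fld") {
        fit <- fld_fit(tr1, tr2, ridge)
        scores <- rbind(te1, te2) %*% fit$w - fit$b
        as.integer(scores > 0)
      } else {
        xtr <- rbind(tr1, tr2)
        ytr <- c(rep(0L, nrow(tr1)), rep(1L, nrow(tr2)))
        fit <- glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                              lambda = 1e-3, standardize = FALSE)
        as.integer(stats::predict(fit, rbind(te1, te2), type = "response") > 0.5)
      }
      truth <- c(rep(0L, nrow(te1)), rep(1L, nrow(te2)))
      acc <- c(acc, mean(pred == truth))
    }
    acc
  }

  fold_acc <- unlist(lapply(seq_len(repeats), function(r) run_once(seed + r - 1L)))
  full <- fld_fit(x1, x2, ridge)
  structure(list(accuracy = mean(fold_acc), fold_accuracy = fold_acc,
                 weights = full$w, scheme = scheme, classifier = classifier,
                 k = if (scheme == "kfold") k else NA_integer_,
                 seed = seed, repeats = repeats),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("<decoder_result: %s/%s, accuracy %.3f over %d fold(s)>\n",
              x$classifier, x$scheme, x$accuracy, length(x$fold_accuracy)))
  invisible(x)
}

#' Find the time window with the largest training effect on decoding
#'
#' Slides a fixed-length window over the time bins of pre- and post-training
#' time-resolved sets in single-bin steps, decodes the condition pair within
#' each window for both phases, and returns the window maximising the
#' post-minus-pre decoding accuracy. Ties are broken by the earliest onset
#' (and flagged). The full trace is returned for audit.
#'
#' @param pre,post `time_resolved_set` objects with identical bin edges.
#' @param window_ms window length in ms (must span >= 1 bin and <= the
#'   recorded span).
#' @param conditions,scheme,k,classifier,seed,ridge passed to
#'   [decode_accuracy()].
#' @return A list: `window` (start, end in ms), `delta` (accuracy change),
#'   `trace` (data frame of start, end, acc_pre, acc_post, delta), `tied`.
#' @export
best_time_window <- function(pre, post, window_ms, conditions = NULL,
                             scheme = "kfold", k = 10, classifier = "fld",
                             seed = 1, ridge = 1e-6) {
  if (!inherits(pre, "time_resolved_set") || !inherits(post, "time_resolved_set"))
    stop("`pre` and `post` must be time_resolved_set objects", call. = FALSE)
  if (!isTRUE(all.equal(pre$bin_edges, post$bin_edges)))
    stop("pre and post bin edges differ", call. = FALSE)
  edges <- pre$bin_edges
  widths <- diff(edges)
  if (max(abs(widths - widths[1L])) > 1e-9)
    stop("bins must be equally spaced", call. = FALSE)
  nb <- round(window_ms / widths[1L])
  if (nb < 1L || nb > length(widths))
    stop("window length must cover between 1 bin and the full span", call. = FALSE)
  starts <- seq_len(length(widths) - nb + 1L)
  rows <- lapply(starts, function(s) {
    w0 <- edges[s]; w1 <- edges[s + nb]
    a_pre <- decode_accuracy(collapse_window(pre, w0, w1), conditions,
                             scheme = scheme, k = k, classifier = classifier,
                             seed = seed, ridge = ridge)$accuracy
    a_post <- decode_accuracy(collapse_window(post, w0, w1), conditions,
                              scheme = scheme, k = k, classifier = classifier,
                              seed = seed, ridge = ridge)$accuracy
    data.frame(start = w0, end = w1, acc_pre = a_pre, acc_post = a_post,
               delta = a_post - a_pre)
  })
  trace <- do.call(rbind, rows)
  best <- which(trace$delta >= max(trace$delta) - 1e-12)
  tied <- length(best) > 1L
  if (tied)
    warning("multiple windows tie for the largest accuracy change; ",
            "returning the earliest", call. = FALSE)
  i <- best[1L]
  list(window = c(start = trace$start[i], end = trace$end[i]),
       delta = trace$delta[i], trace = trace, tied = tied)
}
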