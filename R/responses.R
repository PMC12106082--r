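# Conditioned population responses: data model, disk I/O, inclusion filters.
#
# A response set holds trial-by-trial population responses keyed by stimulus
# condition for one experimental phase (pre- or post-training). On disk it is
# one tidy delimited table (condition, trial, one column per unit) plus a JSON
# sidecar carrying the metadata, so a set round-trips losslessly.

#' Construct a conditioned response set
#'
#' Bundles trial-by-trial population responses for one phase (pre or post
#' training), keyed by stimulus condition. Each condition holds a numeric
#' matrix of trials x units; all conditions must share the same units in the
#' same column order.
#'
#' @param responses named list of numeric matrices (trials x units), one per
#'   stimulus condition. Names must parse as real stimulus values (degrees or
#'   decimal contrast).
#' @param phase `"pre"` or `"post"`.
#' @param unit_ids character vector of unit identifiers; defaults to the
#'   column names of the first matrix, or `u1, u2, ...`.
#' @param response_unit label for the response scale, e.g. `"spk/s"`,
#'   `"psc"` (percent signal change) or `"a.u."`.
#' @return An object of class `response_set`.
#' @examples
#' m <- matrix(rnorm(20), 10, 2)
#' s <- response_set(list(`55` = m, `56` = m + 1), phase = "pre")
#' n_units(s)
#' @export
response_set <- function(responses, phase = c("pre", "post"), unit_ids = NULL,
                         response_unit = "a.u.") {
  phase <- match.arg(phase)
  if (!is.list(responses) || length(responses) == 0L)
    stop("`responses` must be a non-empty named list of matrices", call. = FALSE)
  if (is.null(names(responses)) || anyNA(suppressWarnings(as.numeric(names(responses)))))
    stop("`responses` names must parse as numeric stimulus values", call. = FALSE)
  responses <- lapply(responses, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  nu <- ncol(responses[[1L]])
  if (is.null(unit_ids)) {
    unit_ids <- colnames(responses[[1L]])
    if (is.null(unit_ids)) unit_ids <- paste0("u", seq_len(nu))
  }
  responses <- lapply(responses, function(m) {
    if (ncol(m) == length(unit_ids)) colnames(m) <- unit_ids
    rownames(m) <- NULL
    m
  })
  obj <- structure(
    list(responses = responses,
         conditions = as.numeric(names(responses)),
         phase = phase,
         unit_ids = as.character(unit_ids),
         response_unit = response_unit),
    class = "response_set")
  validate_response_set(obj)
}

#' Validate a conditioned response set
#'
#' Checks the class invariants: consistent unit count and column order across
#' conditions, at least two trials per condition, and all values finite.
#'
#' @param x a `response_set`.
#' @return `x`, invisibly-validated (errors name the offending condition).
#' @export
validate_response_set <- function(x) {
  if (!inherits(x, "response_set")) stop("not a response_set", call. = FALSE)
  nu <- length(x$unit_ids)
  for (i in seq_along(x$responses)) {
    m <- x$responses[[i]]
    cond <- names(x$responses)[i]
    if (!is.matrix(m) || ncol(m) != nu)
      stop(sprintf("condition %s has %d units; expected %d", cond, ncol(m), nu),
           call. = FALSE)
    if (!identical(colnames(m), x$unit_ids))
      stop(sprintf("condition %s column order disagrees with unit_ids", cond),
           call. = FALSE)
    if (nrow(m) < 2L)
      stop(sprintf("condition %s has %d trial(s); need >= 2", cond, nrow(m)),
           call. = FALSE)
    if (!all(is.finite(m))) {
      bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-finite value in condition %s at trial %d, unit %s",
                   cond, bad[1L], x$unit_ids[bad[2L]]), call. = FALSE)
    }
  }
  x
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("<response_set: phase=%s, %d conditions, %d units, %s trials/condition, unit=%s>\n",
              x$phase, length(x$conditions), length(x$unit_ids),
              paste(unique(vapply(x$responses, nrow, 0L)), collapse = "/"),
              x$response_unit))
  invisible(x)
}

#' Number of units in a response set
#' @param x a `response_set`.
#' @return integer unit count.
#' @export
n_units <- function(x) length(x$unit_ids)

# grand mean response per unit over all conditions and trials
grand_means <- function(x) {
  tot <- Reduce(`+`, lapply(x$responses, colSums))
  tot / sum(vapply(x$responses, nrow, 0L))
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a response set to disk
#'
#' Writes one tidy CSV (columns: condition, trial, then one column per unit)
#' with full 17-digit precision, plus a JSON sidecar `<path>.json` holding
#' phase, response unit, condition list and unit ids. `read_responses()`
#' reproduces the numeric payload bit for bit.
#'
#' @param x a `response_set`.
#' @param path output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @seealso [read_responses()]
#' @export
write_responses <- function(x, path) {
  validate_response_set(x)
  rows <- lapply(seq_along(x$responses), function(i) {
    m <- x$responses[[i]]
    cbind(condition = rep(fmt_full(x$conditions[i]), nrow(m)),
          trial = as.character(seq_len(nrow(m))),
          matrix(fmt_full(m), nrow(m), ncol(m)))
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("condition", "trial", x$unit_ids)
  ok <- tryCatch({
    utils::write.table(tab, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write responses to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  meta <- list(phase = x$phase, response_unit = x$response_unit,
               conditions = x$conditions, unit_ids = x$unit_ids)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a response set from disk
#'
#' Expects the tidy CSV + JSON sidecar layout produced by
#' [write_responses()]. Values are validated on load: ragged condition
#' blocks, non-numeric cells or non-finite values are errors (no silent
#' imputation).
#'
#' @param path CSV path; the sidecar `<path>.json` must exist.
#' @return A validated `response_set`.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing metadata sidecar: ", sp, call. = FALSE)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in c("phase", "response_unit", "conditions", "unit_ids"))
    if (is.null(meta[[f]])) stop("sidecar missing field '", f, "'", call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("condition", "trial", meta$unit_ids)
  if (!identical(colnames(tab), need))
    stop("table header disagrees with sidecar unit_ids", call. = FALSE)
  cond_chr <- tab$condition
  vals <- as.matrix(tab[, meta$unit_ids, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row %d, unit %s", bad[1L],
                 meta$unit_ids[bad[2L]]), call. = FALSE)
  }
  cond_num <- as.numeric(cond_chr)
  responses <- lapply(meta$conditions, function(cv) {
    m <- num[abs(cond_num - cv) < 1e-12 | cond_chr == fmt_full(cv), , drop = FALSE]
    colnames(m) <- meta$unit_ids
    m
  })
  names(responses) <- as.character(meta$conditions)
  response_set(responses, phase = meta$phase, unit_ids = meta$unit_ids,
               response_unit = meta$response_unit)
}

keep_units <- function(x, idx) {
  x$responses <- lapply(x$responses, function(m) m[, idx, drop = FALSE])
  x$unit_ids <- x$unit_ids[idx]
  x
}

#' Drop units that are not driven by the stimulus
#'
#' Keeps exactly the units whose grand-mean response (over all conditions and
#' trials) exceeds `threshold` in *both* phases, mirroring the inclusion rule
#' used for artificial units (mean rate > 0.001 before and after training).
#' The same units are removed from both phases and column order is preserved.
#'
#' @param pre,post `response_set` objects sharing `unit_ids`.
#' @param threshold response-unit threshold; default 0.001.
#' @return A list with elements `pre` and `post`.
#' @export
filter_active_units <- function(pre, post, threshold = 0.001) {
  validate_response_set(pre); validate_response_set(post)
  if (!identical(pre$unit_ids, post$unit_ids))
    stop("pre and post unit_ids differ", call. = FALSE)
  keep <- which(grand_means(pre) > threshold & grand_means(post) > threshold)
  list(pre = keep_units(pre, keep), post = keep_units(post, keep))
}

#' Select the most responsive units
#'
#' Ranks units by their grand-mean response in the `reference` set (typically
#' the pre-test phase, as when picking the 60 most responsive voxels per ROI)
#' and keeps the top `k` in `x`. Ties are broken by ascending unit id, and
#' the surviving columns keep their original order.
#'
#' @param x `response_set` to subset.
#' @param k number of units to keep.
#' @param reference `response_set` whose grand means define responsiveness;
#'   defaults to `x` itself.
#' @return A `response_set` with `k` units.
#' @export
select_top_units <- function(x, k, reference = x) {
  validate_response_set(x); validate_response_set(reference)
  if (!identical(x$unit_ids, reference$unit_ids))
    stop("`x` and `reference` unit_ids differ", call. = FALSE)
  if (k > n_units(x)) stop("k exceeds the number of units", call. = FALSE)
  gm <- grand_means(reference)
  ord <- order(-gm, x$unit_ids)          # ties: ascending unit id
  keep <- sort(ord[seq_len(k)])          # preserve original column order
  keep_units(x, keep)
}

#' Construct a time-resolved response set
#'
#' As [response_set()] but each condition holds a 3-D array of
#' trials x units x time bins, with bin edges in ms relative to stimulus
#' onset. Used for the sliding time-window decoding search.
#'
#' @param responses named list of 3-D numeric arrays.
#' @param bin_edges numeric vector of bin edges (ms), strictly increasing,
#'   length = bins + 1.
#' @param phase,unit_ids,response_unit as in [response_set()].
#' @return An object of class `time_resolved_set`.
#' @export
time_resolved_set <- function(responses, bin_edges, phase = c("pre", "post"),
                              unit_ids = NULL, response_unit = "spk/s") {
  phase <- match.arg(phase)
  if (!is.list(responses) || length(responses) == 0L || is.null(names(responses)))
    stop("`responses` must be a non-empty named list of 3-D arrays", call. = FALSE)
  dims <- dim(responses[[1L]])
  if (length(dims) != 3L) stop("each condition must be trials x units x bins", call. = FALSE)
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing", call. = FALSE)
  if (length(bin_edges) != dims[3L] + 1L)
    stop("need length(bin_edges) == bins + 1", call. = FALSE)
  for (i in seq_along(responses)) {
    d <- dim(responses[[i]])
    if (length(d) != 3L || any(d[2:3] != dims[2:3]))
      stop("condition ", names(responses)[i], " has inconsistent unit/bin count",
           call. = FALSE)
    if (!all(is.finite(responses[[i]])))
      stop("non-finite value in condition ", names(responses)[i], call. = FALSE)
  }
  if (is.null(unit_ids)) unit_ids <- paste0("u", seq_len(dims[2L]))
  structure(list(responses = responses,
                 conditions = as.numeric(names(responses)),
                 bin_edges = as.numeric(bin_edges),
                 phase = phase, unit_ids = as.character(unit_ids),
                 response_unit = response_unit),
            class = "time_resolved_set")
}

#' Collapse a time window of a time-resolved set
#'
#' Averages responses over the bins whose span lies inside `[start, end]` ms,
#' yielding an ordinary `response_set`.
#'
#' @param x a `time_resolved_set`.
#' @param start,end window bounds in ms (must align with bin edges' span).
#' @return A `response_set`.
#' @export
collapse_window <- function(x, start, end) {
  lo <- which(x$bin_edges >= start - 1e-9)[1L]
  hi <- utils::tail(which(x$bin_edges <= end + 1e-9), 1L)
  if (is.na(lo) || is.na(hi) || hi - lo < 1L)
    stop("window does not cover at least one bin", call. = FALSE)
  bins <- lo:(hi - 1L)
  resp <- lapply(x$responses, function(a) {
    m <- apply(a[, , bins, drop = FALSE], c(1L, 2L), mean)
    colnames(m) <- x$unit_ids
    m
  })
  response_set(resp, phase = x$phase, unit_ids = x$unit_ids,
               response_unit = x$response_unit)
}
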