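# Pipeline orchestration: chain simulate -> filter/select -> metrics ->
# decompose -> decode from a single declarative config, writing JSON results
# plus a manifest (seeds, package version, parameters) sufficient to
# re-create every output.

#' Build a pipeline run configuration
#'
#' Either `pre`/`post` name response CSV files on disk (the tidy table +
#' sidecar layout of [write_responses()]), or `simulate` describes a
#' synthetic scenario: a [population_spec()] plus a list of [mechanisms] and
#' a trial count.
#'
#' @param pre,post paths to pre/post response tables (data mode).
#' @param simulate list with elements `spec` (a `population_spec`),
#'   `mechanisms` (list of `mechanism` objects) and `trials` (simulation
#'   mode).
#' @param dtheta stimulus separation; required in data mode, taken from the
#'   spec in simulation mode.
#' @param ridge ridge fraction for covariance inversion (default 1e-6).
#' @param unit_threshold inclusion threshold on the grand-mean response
#'   (default 0.001).
#' @param top_k keep only the `top_k` most responsive units at pre-test
#'   (default `NULL`: keep all).
#' @param cv_scheme,cv_k decoding cross-validation scheme and fold count.
#' @param coverage PC variance coverage for [pc_comparison()] (default 0.99).
#' @param seed integer master seed; every stochastic stage derives its seed
#'   from it and records it in the manifest.
#' @param out_dir output directory (created); `NULL` to skip writing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(pre = NULL, post = NULL, simulate = NULL,
                       dtheta = NULL, ridge = 1e-6, unit_threshold = 0.001,
                       top_k = NULL, cv_scheme = "half_split", cv_k = 10,
                       coverage = 0.99, seed = 1, out_dir = NULL) {
  if (is.null(simulate)) {
    if (is.null(pre) || is.null(post))
      stop("either `simulate` or both `pre` and `post` paths are required",
           call. = FALSE)
    if (is.null(dtheta))
      stop("`dtheta` is required when decoding from files", call. = FALSE)
  } else {
    for (f in c("spec", "mechanisms", "trials"))
      if (is.null(simulate[[f]]))
        stop("`simulate` needs fields spec, mechanisms, trials", call. = FALSE)
    if (is.null(dtheta)) dtheta <- abs(diff(simulate$spec$stimulus_pair))
  }
  structure(list(pre = pre, post = post, simulate = simulate, dtheta = dtheta,
                 ridge = ridge, unit_threshold = unit_threshold, top_k = top_k,
                 cv_scheme = cv_scheme, cv_k = cv_k, coverage = coverage,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

with_ridge <- function(geom, ridge) { geom$ridge <- ridge; geom }

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: load or simulate the pre/post response
#' sets; filter inactive units and (optionally) select the most responsive
#' units at pre-test; estimate both geometries; compute single-unit metrics
#' (Fano factors, noise correlations), the stepwise four-mechanism
#' decomposition, the PC comparison, and cross-validated decoding accuracy
#' for both phases. Identical config and seed give byte-identical numeric
#' results.
#'
#' @param config a [run_config()].
#' @return A list with elements `decomposition`, `comparison`, `decoding`
#'   (pre/post `decoder_result`s), `metrics` (per-phase Fano medians and
#'   noise-correlation medians), `truth` (simulation mode only), `manifest`.
#'   If `config$out_dir` is set, `results.json` and `manifest.json` are
#'   written there.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("not a run_config", call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    pre_geom <- stage("simulate", make_population(sim$spec))
    inj <- stage("simulate", apply_mechanism(pre_geom, sim$mechanisms))
    truth <- inj$truth
    pre_set <- stage("simulate",
                     sample_trials(pre_geom, sim$trials, seed = config$seed,
                                   phase = "pre"))
    post_set <- stage("simulate",
                      sample_trials(inj$post, sim$trials, seed = config$seed + 1L,
                                    phase = "post"))
  } else {
    pre_set <- stage("load", read_responses(config$pre))
    post_set <- stage("load", read_responses(config$post))
  }
  flt <- stage("filter",
               filter_active_units(pre_set, post_set, config$unit_threshold))
  pre_set <- flt$pre; post_set <- flt$post
  if (!is.null(config$top_k)) {
    pre_ref <- pre_set
    pre_set <- stage("select", select_top_units(pre_set, config$top_k, pre_ref))
    post_set <- stage("select", select_top_units(post_set, config$top_k, pre_ref))
  }
  g_pre <- stage("geometry",
                 estimate_geometry(pre_set, dtheta = config$dtheta,
                                   ridge = config$ridge))
  g_post <- stage("geometry",
                  estimate_geometry(post_set, dtheta = config$dtheta,
                                    ridge = config$ridge))
  dec <- stage("decompose", stepwise_decomposition(g_pre, g_post))
  cmp <- stage("compare", pc_comparison(g_pre, g_post, config$coverage))
  metrics <- stage("metrics", list(
    fano_median_pre = stats::median(
      fano_factor(pre_set$responses[[1L]]), na.rm = TRUE),
    fano_median_post = stats::median(
      fano_factor(post_set$responses[[1L]]), na.rm = TRUE),
    noise_corr_median_pre = noise_correlations(pre_set)$median,
    noise_corr_median_post = noise_correlations(post_set)$median))
  decoding <- stage("decode", list(
    pre = decode_accuracy(pre_set, scheme = config$cv_scheme, k = config$cv_k,
                          seed = config$seed + 2L, ridge = config$ridge),
    post = decode_accuracy(post_set, scheme = config$cv_scheme, k = config$cv_k,
                           seed = config$seed + 2L, ridge = config$ridge)))
  manifest <- list(
    package = "neurogeom",
    version = as.character(utils::packageVersion("neurogeom")),
    seed = config$seed,
    stage_seeds = list(sample_pre = config$seed, sample_post = config$seed + 1L,
                       decode = config$seed + 2L),
    dtheta = config$dtheta, ridge = config$ridge,
    unit_threshold = config$unit_threshold, top_k = config$top_k,
    cv_scheme = config$cv_scheme, cv_k = config$cv_k,
    coverage = config$coverage,
    mode = if (is.null(config$simulate)) "data" else "simulation",
    inputs = if (is.null(config$simulate)) list(pre = config$pre,
                                                post = config$post)
             else list(mechanisms = truth$mechanisms,
                       trials = config$simulate$trials,
                       n_units = config$simulate$spec$n_units))
  result <- list(decomposition = dec, comparison = cmp, decoding = decoding,
                 metrics = metrics, truth = truth, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    payload <- list(
      alfi = list(pre = dec$alfi_pre, se = dec$alfi_se, ms = dec$alfi_ms,
                  sr = dec$alfi_sr, post = dec$alfi_post),
      contributions = as.list(dec$contributions),
      signal_rotation_angle = dec$signal_rotation_angle,
      pc_angles = cmp$pc_angles,
      total_variance = list(pre = cmp$total_variance_pre,
                            post = cmp$total_variance_post),
      decoding_accuracy = list(pre = decoding$pre$accuracy,
                               post = decoding$post$accuracy),
      metrics = metrics)
    if (!is.null(truth))
      payload$truth <- list(alfi_pre = truth$alfi_pre,
                            alfi_post = truth$alfi_post,
                            gains = as.list(truth$gains),
                            signal_rotation_angle = truth$signal_rotation_angle)
    jsonlite::write_json(payload, file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
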