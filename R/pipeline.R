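#' Pipeline configuration
#'
#' Bundles every stage choice with its default. Defaults mirror the
#' deployed detector: wavelet preprocessing on, 11-band PSD features with
#' per-fold SWLDA selection, dual KSS thresholds 3 and 7, robust scaling on
#' the (0.35, 0.65) quantiles, and a nested 10x10-fold cross-validated
#' RBF-SVM over the full exponent grid.
#'
#' @param sim A [sim_config()] used when `input_dir` is `NULL`.
#' @param input_dir,manifest_path Read recordings (one delimited-text file
#'   per `recording_id`, named `<recording_id>.txt`) and the manifest from
#'   disk instead of simulating.
#' @param preprocess Apply [preprocess_recording()] to every recording.
#' @param wavelet A [wavelet_config()].
#' @param feature `"psd"`, `"ar"` or `"mse"`.
#' @param band_set Band set name for PSD features (see [eeg_bands()]).
#' @param thresholds KSS labeling thresholds (see [labeling_scheme()]).
#' @param select Run SWLDA selection inside each outer fold.
#' @param grid A [grid_spec()].
#' @param fold_by,outer_k,inner_k Cross-validation layout (see
#'   [nested_cv()]).
#' @param seed Master seed for the run.
#' @param out_dir If non-`NULL`, artifacts (manifest, feature table, metric
#'   report, run manifest) are written there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            input_dir = NULL, manifest_path = NULL,
                            preprocess = TRUE, wavelet = wavelet_config(),
                            feature = "psd", band_set = "full",
                            thresholds = c(3, 7), select = TRUE,
                            grid = grid_spec(),
                            fold_by = "window", outer_k = 10, inner_k = 10,
                            seed = 1L, out_dir = NULL) {
  structure(
    list(sim = sim, input_dir = input_dir, manifest_path = manifest_path,
         preprocess = preprocess, wavelet = wavelet, feature = feature,
         band_set = band_set, thresholds = thresholds, select = select,
         grid = grid, fold_by = fold_by, outer_k = outer_k,
         inner_k = inner_k, seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

load_or_simulate <- function(config) {
  if (is.null(config$input_dir)) {
    sim <- config$sim
    sim$seed <- config$seed
    simulate_dataset(sim)
  } else {
    manifest <- read_manifest(config$manifest_path %||%
                                file.path(config$input_dir, "manifest.csv"))
    recordings <- purrr::pmap(
      manifest[, c("recording_id", "subject_id", "session", "kss")],
      function(recording_id, subject_id, session, kss) {
        read_recording(file.path(config$input_dir,
                                 paste0(recording_id, ".txt")),
                       fs = config$sim$fs, recording_id = recording_id,
                       subject_id = subject_id, session = session, kss = kss)
      }
    )
    list(recordings = recordings, manifest = manifest)
  }
}

#' Run the full drowsiness-detection pipeline
#'
#' Executes simulate (or load) -> preprocess -> extract -> label -> nested
#' cross-validation with per-fold selection and scaling, logging row counts
#' per stage to stderr. The run is reproducible from the config and seed.
#'
#' @param config A [pipeline_config()].
#' @return The `drowsy_cv` result, with the labelled feature table attached
#'   as `attr(, "features")`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(...) inform(sprintf(...))
  dataset <- load_or_simulate(config)
  stage("simulate/load: %d recordings", length(dataset$recordings))
  recs <- dataset$recordings
  if (config$preprocess) {
    recs <- lapply(recs, preprocess_recording, config = config$wavelet)
    stage("preprocess: wavelet denoise + artifact removal (%s, %d levels)",
          config$wavelet$wavelet_name, config$wavelet$n_levels)
  }
  features <- extract_features(recs, feature = config$feature,
                               bands = eeg_bands(config$band_set))
  stage("extract: %d windows x %d features (%s)", nrow(features),
        length(feature_names(features)), config$feature)
  scheme <- labeling_scheme(config$thresholds)
  features <- label_windows(features, scheme)
  stage("label: %d alert, %d drowsy, %d excluded",
        sum(features$label == "alert"), sum(features$label == "drowsy"),
        sum(features$label == "excluded"))
  cv <- nested_cv(features, grid = config$grid, outer_k = config$outer_k,
                  inner_k = config$inner_k, seed = config$seed,
                  scale = TRUE, select = config$select,
                  fold_by = config$fold_by)
  stage("cv: pooled accuracy %.1f%%, AUC %.3f",
        cv$metrics$accuracy, cv$metrics$auc)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_manifest(dataset$manifest,
                   file.path(config$out_dir, "manifest.csv"))
    write.table(features, file.path(config$out_dir, "features.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
    write_metrics(cv$metrics, file.path(config$out_dir, "metrics.json"))
    jsonlite::write_json(
      list(seed = config$seed, feature = config$feature,
           band_set = config$band_set, thresholds = config$thresholds,
           select = config$select, fold_by = config$fold_by,
           outer_k = config$outer_k, inner_k = config$inner_k,
           n_recordings = length(recs), n_windows = nrow(features)),
      file.path(config$out_dir, "run.json"), auto_unbox = TRUE)
    stage("artifacts written to %s", config$out_dir)
  }
  attr(cv, "features") <- features
  cv
}
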