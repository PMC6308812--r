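#' Cut a recording into fixed-length windows
#'
#' Time-averaging of features is done over 10 s windows with a 10 s shift,
#' so a 60 s recording is compressed into six window-level samples and a
#' 300 s task recording into thirty. Each window inherits the recording's
#' metadata and KSS score and carries its zero-based `window_index`.
#'
#' @param rec An [eeg_recording].
#' @param window_s Window length, seconds.
#' @param shift_s Shift between window starts, seconds.
#' @return A list of [eeg_recording] segments; the count is
#'   `floor((duration - window_s) / shift_s) + 1`.
#' @export
window_segment <- function(rec, window_s = 10, shift_s = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  dur <- duration(rec)
  if (window_s > dur) {
    abort("Window is longer than the recording.", class = "drowsy_error")
  }
  if (shift_s <= 0) abort("`shift_s` must be positive.", class = "drowsy_error")
  n_win <- floor((dur - window_s) / shift_s) + 1
  wlen <- round(window_s * rec$fs)
  step <- round(shift_s * rec$fs)
  lapply(seq_len(n_win), function(i) {
    start <- (i - 1L) * step + 1L
    seg <- rec
    seg$samples <- rec$samples[start:(start + wlen - 1L)]
    seg$window_index <- i - 1L
    seg
  })
}

#' KSS labeling scheme
#'
#' Two ways of turning a KSS score into a binary alert/drowsy label:
#'
#' * single threshold `A`: alert when `KSS < A`, drowsy when `KSS > A`,
#'   excluded when `KSS == A`;
#' * dual thresholds `A < B`: alert when `KSS < A`, drowsy when `KSS > B`,
#'   excluded for `A <= KSS <= B`.
#'
#' The inequalities are strict, so scores equal to a threshold are excluded.
#'
#' @param thresholds One integer (single mode) or two increasing integers
#'   (dual mode), each in 1..9.
#' @return A list of class `labeling_scheme`.
#' @export
#'
#' @examples
#' label_from_kss(8, labeling_scheme(c(3, 7)))
labeling_scheme <- function(thresholds = c(3, 7)) {
  thresholds <- as.integer(thresholds)
  if (!length(thresholds) %in% 1:2 || anyNA(thresholds) ||
      any(thresholds < 1L) || any(thresholds > 9L)) {
    abort("`thresholds` must be one or two integers in 1..9.",
          class = "drowsy_error")
  }
  if (length(thresholds) == 2L && thresholds[1] >= thresholds[2]) {
    abort("Dual thresholds need A < B.", class = "drowsy_error")
  }
  structure(list(mode = if (length(thresholds) == 1L) "single" else "dual",
                 thresholds = thresholds),
            class = "labeling_scheme")
}

#' Label a KSS score as alert, drowsy or excluded
#'
#' @param kss Integer KSS score(s) in 1..9 (NA allowed, labelled excluded).
#' @param scheme A [labeling_scheme()].
#' @return Factor with levels `alert`, `drowsy`, `excluded`.
#' @export
label_from_kss <- function(kss, scheme = labeling_scheme(c(3, 7))) {
  stopifnot(inherits(scheme, "labeling_scheme"))
  kss <- as.integer(kss)
  if (any(!is.na(kss) & (kss < 1L | kss > 9L))) {
    abort("KSS scores must lie in 1..9.", class = "drowsy_error")
  }
  a <- scheme$thresholds[1]
  b <- if (scheme$mode == "dual") scheme$thresholds[2] else a
  out <- rep("excluded", length(kss))
  out[!is.na(kss) & kss < a] <- "alert"
  out[!is.na(kss) & kss > b] <- "drowsy"
  factor(out, levels = c("alert", "drowsy", "excluded"))
}

#' Attach alert/drowsy labels to a feature table
#'
#' @param features A feature tibble from [extract_features()] with a `kss`
#'   column.
#' @param scheme A [labeling_scheme()].
#' @param drop_excluded Drop rows labelled `excluded` (default keeps them).
#' @return The tibble with a `label` column.
#' @export
label_windows <- function(features, scheme = labeling_scheme(c(3, 7)),
                          drop_excluded = FALSE) {
  features$label <- label_from_kss(features$kss, scheme)
  if (drop_excluded) {
    features <- dplyr::filter(features, .data$label != "excluded")
    features$label <- droplevels(features$label)
  }
  features
}

#' Fit the quantile-based robust scaler
#'
#' For every feature column, computes the median and the normalised
#' interquantile range `NIQR = (q_hi - q_lo) * 0.7413` on the training rows
#' only. The default quantile pair is (0.35, 0.65) - narrower than the
#' classical quartiles to blunt the influence of the heavy-tailed outliers
#' that dry-electrode EEG produces - while the 0.7413 normal-consistency
#' constant is retained as conventionally printed. Quantiles use linear
#' interpolation of order statistics (R's type 7).
#'
#' Features with zero spread are flagged (`zero_spread = TRUE`) and must be
#' dropped before scaling; [apply_robust_scaler()] refuses them.
#'
#' @param train_features Feature tibble (training rows only).
#' @param q_lo,q_hi Quantile pair.
#' @param niqr_constant Multiplier turning the interquantile range into a
#'   normal-consistent spread estimate.
#' @return A tibble of class `robust_scaler` with columns `feature`,
#'   `median`, `niqr`, `zero_spread`.
#' @export
fit_robust_scaler <- function(train_features, q_lo = 0.35, q_hi = 0.65,
                              niqr_constant = 0.7413) {
  feats <- feature_names(train_features)
  if (nrow(train_features) < 3) {
    abort("Need at least 3 training rows to fit the scaler.",
          class = "drowsy_error")
  }
  params <- purrr::map_dfr(feats, function(f) {
    x <- train_features[[f]]
    qs <- quantile(x, c(q_lo, q_hi), names = FALSE, type = 7)
    niqr <- (qs[2] - qs[1]) * niqr_constant
    tibble::tibble(feature = f, median = median(x), niqr = niqr,
                   zero_spread = niqr <= 0)
  })
  if (any(params$zero_spread)) {
    warn(sprintf("Zero-spread feature(s) flagged: %s",
                 paste(params$feature[params$zero_spread], collapse = ", ")))
  }
  structure(params, class = c("robust_scaler", class(params)),
            q_lo = q_lo, q_hi = q_hi, niqr_constant = niqr_constant)
}

#' Apply a fitted robust scaler
#'
#' Scales each feature to `z = (x - median) / NIQR` using parameters learned
#' on training data; applying train-fitted parameters to the training rows
#' gives per-feature median zero. Zero-spread features are dropped with a
#' warning.
#'
#' @param features Feature tibble to scale.
#' @param params A `robust_scaler` from [fit_robust_scaler()].
#' @return The tibble with scaled feature columns.
#' @export
apply_robust_scaler <- function(features, params) {
  stopifnot(inherits(params, "robust_scaler"))
  missing <- setdiff(params$feature, names(features))
  if (length(missing) > 0) {
    abort(sprintf("Features absent from the table: %s",
                  paste(missing, collapse = ", ")), class = "drowsy_error")
  }
  usable <- params[!params$zero_spread, ]
  dropped <- params$feature[params$zero_spread]
  if (length(dropped) > 0) {
    warn(sprintf("Dropping zero-spread feature(s): %s",
                 paste(dropped, collapse = ", ")))
    features <- dplyr::select(features, -dplyr::all_of(dropped))
  }
  for (i in seq_len(nrow(usable))) {
    f <- usable$feature[i]
    features[[f]] <- (features[[f]] - usable$median[i]) / usable$niqr[i]
  }
  features
}

#' Serialise scaler parameters to JSON (and back)
#'
#' The scaler learned during model development is reused at prediction time;
#' these helpers round-trip its parameters through a JSON file.
#'
#' @param params A `robust_scaler`.
#' @param path JSON file path.
#' @return `path` / the restored `robust_scaler`.
#' @export
write_scaler <- function(params, path) {
  stopifnot(inherits(params, "robust_scaler"))
  payload <- list(q_lo = attr(params, "q_lo"), q_hi = attr(params, "q_hi"),
                  niqr_constant = attr(params, "niqr_constant"),
                  params = tibble::as_tibble(unclass(params)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- tibble::as_tibble(payload$params)
  structure(params, class = c("robust_scaler", class(params)),
            q_lo = payload$q_lo, q_hi = payload$q_hi,
            niqr_constant = payload$niqr_constant)
}

#' @export
tidy.robust_scaler <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
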