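#' Frequency-band definitions
#'
#' Band edges follow the half-open convention `[low, high)`; a set of bands
#' is valid only if it is non-overlapping under that convention. Three named
#' sets are provided:
#'
#' * `"full"` - the 11-band layout used for SWLDA-based selection: 1-4, 4-8,
#'   8-10, 10-12, 12-14, 14-26, 26-40, 40-49, 51-65, 65-80 and 80-100 Hz.
#'   The 49-51 Hz gap is deliberate: it is the mains-notch region of the
#'   acquisition device and carries no usable signal.
#' * `"theta_alpha"` - the two bands classically associated with sleepiness:
#'   theta 4-8 Hz and alpha 8-12 Hz.
#' * `"practical"` - the four bands retained for the deployed detector:
#'   1-4, 4-8, 10-12 and 12-14 Hz.
#'
#' @param set One of `"full"`, `"theta_alpha"`, `"practical"`.
#' @return A tibble with columns `band`, `low`, `high`.
#' @export
eeg_bands <- function(set = c("full", "theta_alpha", "practical")) {
  set <- match.arg(set)
  edges <- switch(set,
    full = list(low = c(1, 4, 8, 10, 12, 14, 26, 40, 51, 65, 80),
                high = c(4, 8, 10, 12, 14, 26, 40, 49, 65, 80, 100)),
    theta_alpha = list(low = c(4, 8), high = c(8, 12)),
    practical = list(low = c(1, 4, 10, 12), high = c(4, 8, 12, 14))
  )
  tibble::tibble(
    band = sprintf("psd_%g_%g", edges$low, edges$high),
    low = edges$low, high = edges$high
  )
}

validate_bands <- function(bands) {
  stopifnot(all(c("band", "low", "high") %in% names(bands)))
  if (any(bands$low < 0) || any(bands$low >= bands$high)) {
    abort("Each band needs 0 <= low < high.", class = "drowsy_error")
  }
  b <- bands[order(bands$low), ]
  if (nrow(b) > 1 && any(b$low[-1] < b$high[-nrow(b)])) {
    abort("Bands overlap under the half-open [low, high) convention.",
          class = "drowsy_error")
  }
  bands
}

#' Band power from a Blackman-tapered periodogram
#'
#' The power spectral density of the (demeaned) segment is estimated by a
#' single periodogram with a Blackman taper, normalised by the taper power
#' so that band powers integrate the one-sided PSD over each half-open
#' interval `[low, high)` in Hz. One segment, one periodogram: no Welch
#' sub-segmentation.
#'
#' @param window An [eeg_recording] (typically a 10 s window).
#' @param bands A band tibble, e.g. from [eeg_bands()].
#' @return A named numeric vector of band powers (signal-units squared).
#' @export
#'
#' @examples
#' seg <- eeg_recording(sin(2 * pi * 10 * (0:5119) / 512), fs = 512)
#' compute_psd_bands(seg, eeg_bands("theta_alpha"))
compute_psd_bands <- function(window, bands = eeg_bands("full")) {
  stopifnot(inherits(window, "eeg_recording"))
  validate_bands(bands)
  x <- window$samples
  fs <- window$fs
  n <- length(x)
  if (n < 2 * fs) {
    abort("Segment must be at least 2 s long for band-power estimation.",
          class = "drowsy_error")
  }
  w <- signal::blackman(n)
  xw <- (x - mean(x)) * w
  spec <- abs(fft(xw))^2 / (fs * sum(w^2))
  n_half <- floor(n / 2)
  freq <- (0:n_half) * fs / n
  psd <- spec[1:(n_half + 1)]
  psd[2:(n_half + 1)] <- 2 * psd[2:(n_half + 1)]
  if (n %% 2 == 0) psd[n_half + 1] <- psd[n_half + 1] / 2
  df <- fs / n
  powers <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- freq >= bands$low[i] & freq < bands$high[i]
    sum(psd[sel]) * df
  }, numeric(1))
  setNames(powers, bands$band)
}

#' Autoregressive coefficients by the Yule-Walker method
#'
#' Fits `x_t = a_1 x_{t-1} + ... + a_p x_{t-p} + e_t` by solving the
#' Yule-Walker (Toeplitz autocovariance) system built from biased sample
#' autocovariances of the demeaned segment. Order 5 is the default feature
#' set.
#'
#' @param window An [eeg_recording] segment.
#' @param order Model order `p`.
#' @return Named numeric vector `ar1..ar<p>`.
#' @export
compute_ar_coeffs <- function(window, order = 5) {
  stopifnot(inherits(window, "eeg_recording"))
  x <- window$samples
  if (length(x) <= order) {
    abort("Segment must be longer than the AR order.", class = "drowsy_error")
  }
  acov <- as.numeric(stats::acf(x, lag.max = order, type = "covariance",
                                demean = TRUE, plot = FALSE)$acf)
  if (acov[1] <= 0) {
    abort("Constant (zero-variance) segment: Yule-Walker system is singular.",
          class = "drowsy_error")
  }
  R <- stats::toeplitz(acov[seq_len(order)])
  a <- solve(R, acov[2:(order + 1)])
  setNames(a, paste0("ar", seq_len(order)))
}

#' Coarse-grain a series for multiscale entropy
#'
#' Replaces the series by the means of consecutive non-overlapping blocks of
#' length `scale`; trailing samples that do not fill a block are dropped.
#'
#' @param series Numeric vector.
#' @param scale Block length (scale factor), `>= 1`.
#' @return Numeric vector of length `floor(length(series) / scale)`.
#' @export
coarse_grain <- function(series, scale) {
  scale <- as.integer(scale)
  if (scale < 1L || length(series) < scale) {
    abort("`scale` must be >= 1 and no longer than the series.",
          class = "drowsy_error")
  }
  if (scale == 1L) return(as.double(series))
  n_blocks <- length(series) %/% scale
  colMeans(matrix(series[seq_len(n_blocks * scale)], nrow = scale))
}

#' Sample entropy
#'
#' `SampEn(m, r) = -log(A / B)` where `B` counts template pairs (`i != j`)
#' whose length-`m` subsequences match under Chebyshev distance `<= r` and
#' `A` counts the same pairs still matching at length `m + 1`. Returns `NA`
#' (flagged undefined) when no pair matches at either length or the series
#' has zero variance.
#'
#' @param series Numeric vector (`length >= m + 2`).
#' @param m Template length (default 2).
#' @param r Match tolerance; default `0.15 * sd(series)`.
#' @return Sample entropy in nats, or `NA_real_` when undefined.
#' @export
sample_entropy <- function(series, m = 2, r = 0.15 * sd(series)) {
  if (length(series) < m + 2) {
    abort("Series too short for the template length.", class = "drowsy_error")
  }
  if (!is.finite(r) || r <= 0) return(NA_real_)
  counts <- .sampen_counts(as.double(series), as.integer(m), r)
  if (counts[1] == 0 || counts[2] == 0) return(NA_real_)
  -log(counts[2] / counts[1])
}

#' Multiscale entropy
#'
#' Sample entropy of the coarse-grained series at scales `1..n_scales`. The
#' tolerance `r` is computed once from the standard deviation of the
#' original (scale-1) series and held fixed across scales (set
#' `r_mode = "per_scale"` to recompute it at each scale).
#'
#' @param window An [eeg_recording] segment.
#' @param m Template length.
#' @param r_factor Tolerance as a fraction of the series SD.
#' @param n_scales Number of scales (default 20).
#' @param r_mode `"fixed"` (default) or `"per_scale"`.
#' @return Named numeric vector `mse_s1..mse_s<n>` (entries may be `NA` when
#'   undefined, e.g. for constant input).
#' @export
compute_mse <- function(window, m = 2, r_factor = 0.15, n_scales = 20,
                        r_mode = c("fixed", "per_scale")) {
  stopifnot(inherits(window, "eeg_recording"))
  r_mode <- match.arg(r_mode)
  x <- window$samples
  if (length(x) %/% n_scales < 10 * (m + 1)) {
    abort(sprintf(
      "Window too short: coarsest scale keeps %d points, need >= %d.",
      length(x) %/% n_scales, 10 * (m + 1)), class = "drowsy_error")
  }
  r_fixed <- r_factor * sd(x)
  ent <- vapply(seq_len(n_scales), function(tau) {
    cg <- coarse_grain(x, tau)
    r <- if (r_mode == "fixed") r_fixed else r_factor * sd(cg)
    if (!is.finite(r) || r <= 0) return(NA_real_)
    sample_entropy(cg, m = m, r = r)
  }, numeric(1))
  setNames(ent, paste0("mse_s", seq_len(n_scales)))
}

#' Columns of a feature table that are metadata, not features
#' @keywords internal
feature_meta_cols <- function() {
  c("recording_id", "subject_id", "session", "window_index", "kss", "label",
    "condition", "latent")
}

#' Names of the feature columns of a feature table
#'
#' @param features A feature tibble from [extract_features()].
#' @return Character vector of feature column names.
#' @export
feature_names <- function(features) {
  setdiff(names(features), feature_meta_cols())
}

#' Extract a window-level feature table from recordings
#'
#' Cuts each recording into 10 s windows (10 s shift by default) and computes
#' one feature vector per window: band powers (`feature = "psd"`, with a
#' choice of band set), order-5 Yule-Walker AR coefficients (`"ar"`), or
#' multiscale entropy (`"mse"`). The result is a tidy tibble: one row per
#' window with recording/subject provenance, the window's KSS score, and one
#' column per named feature.
#'
#' @param recordings A list of [eeg_recording] objects (or a single one).
#' @param feature `"psd"`, `"ar"` or `"mse"`.
#' @param bands Band set for PSD features (tibble from [eeg_bands()]).
#' @param window_s,shift_s Window length and shift in seconds.
#' @param ... Passed to the per-window extractor ([compute_ar_coeffs()] /
#'   [compute_mse()]).
#' @return A feature tibble.
#' @export
extract_features <- function(recordings, feature = c("psd", "ar", "mse"),
                             bands = eeg_bands("full"),
                             window_s = 10, shift_s = 10, ...) {
  feature <- match.arg(feature)
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  extractor <- switch(feature,
    psd = function(seg) compute_psd_bands(seg, bands = bands),
    ar = function(seg) compute_ar_coeffs(seg, ...),
    mse = function(seg) compute_mse(seg, ...)
  )
  rows <- purrr::map_dfr(recordings, function(rec) {
    segs <- window_segment(rec, window_s = window_s, shift_s = shift_s)
    purrr::map_dfr(seq_along(segs), function(i) {
      vals <- extractor(segs[[i]])
      tibble::tibble(
        recording_id = rec$recording_id, subject_id = rec$subject_id,
        session = rec$session, window_index = i - 1L, kss = rec$kss,
        !!!as.list(vals)
      )
    })
  })
  rows
}
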