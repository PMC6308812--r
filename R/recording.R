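#' Construct an EEG recording
#'
#' An `eeg_recording` is one continuous single-channel voltage trace together
#' with its sampling rate and study metadata: the subject it came from, the
#' session type, and (optionally) the Karolinska Sleepiness Scale (KSS) score
#' the subject reported immediately after the recording. KSS is a 9-point
#' ordinal scale, 1 = very alert, 9 = very sleepy.
#'
#' @param samples Numeric vector of voltage samples (arbitrary linear units,
#'   typically microvolts).
#' @param fs Sampling rate in Hz. Defaults to 512, the rate of the portable
#'   prefrontal device the pipeline targets.
#' @param recording_id Identifier for this recording.
#' @param subject_id Identifier for the subject.
#' @param session One of `"morning"`, `"daytime"`, `"night"`, `"task"`.
#' @param kss Optional integer KSS score in 1..9, or `NA`.
#'
#' @return An object of class `eeg_recording`.
#' @export
#'
#' @examples
#' rec <- eeg_recording(sin(2 * pi * 10 * seq(0, 1, by = 1 / 512)), fs = 512)
#' duration(rec)
eeg_recording <- function(samples, fs = 512, recording_id = "rec",
                          subject_id = "subject", session = "daytime",
                          kss = NA_integer_) {
  samples <- as.double(samples)
  if (length(samples) == 0L) {
    abort("`samples` must contain at least one value.", class = "drowsy_error")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    abort("`samples` must be finite and non-missing.", class = "drowsy_error")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive sampling rate in Hz.",
          class = "drowsy_error")
  }
  session <- match.arg(session, c("morning", "daytime", "night", "task"))
  if (!is.na(kss)) {
    kss <- as.integer(kss)
    if (kss < 1L || kss > 9L) {
      abort("`kss` must be an integer in 1..9 (or NA).", class = "drowsy_error")
    }
  }
  structure(
    list(samples = samples, fs = as.double(fs),
         recording_id = as.character(recording_id),
         subject_id = as.character(subject_id),
         session = session, kss = kss),
    class = "eeg_recording"
  )
}

#' Duration of a recording in seconds
#'
#' Exactly `length(samples) / fs`; the recording is never silently padded or
#' truncated.
#'
#' @param rec An [eeg_recording].
#' @return Duration in seconds.
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  length(rec$samples) / rec$fs
}

#' @export
print.eeg_recording <- function(x, ...) {
  kss <- if (is.na(x$kss)) "unrated" else paste0("KSS ", x$kss)
  cat(sprintf("<eeg_recording %s> subject %s, %s session, %.6g s at %g Hz, %s\n",
              x$recording_id, x$subject_id, x$session,
              duration(x), x$fs, kss))
  invisible(x)
}

#' Read a single-channel EEG recording from delimited text
#'
#' Reads one voltage sample per row. An optional single header line is
#' skipped; comma or whitespace delimiters are accepted (only the first field
#' per row is used). The file must hold exactly one channel.
#'
#' @param path Path to the file.
#' @param fs Sampling rate in Hz the file was recorded at.
#' @param recording_id,subject_id,session,kss Metadata passed to
#'   [eeg_recording()]; defaults derive `recording_id` from the file name.
#'
#' @return An [eeg_recording].
#' @export
read_recording <- function(path, fs = 512,
                           recording_id = NULL, subject_id = "subject",
                           session = "daytime", kss = NA_integer_) {
  if (!file.exists(path)) {
    abort(sprintf("Recording file not found: %s", path), class = "drowsy_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("Recording file is empty: %s", path), class = "drowsy_error")
  }
  first_field <- function(l) strsplit(trimws(l), "[,[:space:]]+")[[1]][1]
  fields <- vapply(lines, first_field, character(1), USE.NAMES = FALSE)
  start <- 1L
  suppressWarnings(v1 <- as.numeric(fields[1]))
  if (is.na(v1)) start <- 2L   # header line
  if (start > length(fields)) {
    abort(sprintf("Recording file holds no samples: %s", path),
          class = "drowsy_error")
  }
  body <- fields[start:length(fields)]
  suppressWarnings(vals <- as.numeric(body))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1] + start - 1L
    abort(sprintf("Malformed numeric value at row %d of %s: '%s'",
                  bad, path, lines[bad]),
          class = "drowsy_parse_error")
  }
  eeg_recording(vals, fs = fs,
                recording_id = recording_id %||%
                  sub("\\.[^.]*$", "", basename(path)),
                subject_id = subject_id, session = session, kss = kss)
}

#' Write a recording as delimited text (one sample per row)
#'
#' @param rec An [eeg_recording].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  writeLines(format(rec$samples, digits = 17, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

#' Read or write a recording manifest
#'
#' The manifest is a comma-separated table pairing each recording with its
#' subject, session and KSS score: columns `recording_id`, `subject_id`,
#' `session`, `kss` (extra columns such as `condition` or `latent` are kept).
#'
#' @param path Manifest file path.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Manifest not found: %s", path), class = "drowsy_error")
  }
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("recording_id", "subject_id", "session", "kss")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Manifest lacks required column(s): %s",
                  paste(missing, collapse = ", ")), class = "drowsy_error")
  }
  tibble::as_tibble(df)
}

#' @rdname read_manifest
#' @param manifest A data frame with the manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Confusion counts for a binary alert/drowsy classifier
#'
#' Drowsy is the positive class: `tp` counts drowsy windows classified drowsy,
#' `tn` alert windows classified alert, `fp` alert windows called drowsy, and
#' `fn` drowsy windows called alert.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.",
          class = "drowsy_error")
  }
  counts <- as.list(setNames(as.integer(round(counts)), names(counts)))
  structure(counts, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d, FP %d, FN %d, TN %d (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Write a metrics report to JSON
#'
#' Serialises the confusion counts and the five derived metrics (plus AUC if
#' present) so that [read_metrics()] restores an identical report.
#'
#' @param report A `metrics_report` from [compute_metrics()].
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  counts <- attr(report, "counts")
  payload <- list(
    counts = list(tp = counts$tp, fp = counts$fp, fn = counts$fn,
                  tn = counts$tn),
    metrics = as.list(tibble::as_tibble(report))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Metrics file not found: %s", path), class = "drowsy_error")
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- confusion_counts(payload$counts$tp, payload$counts$fp,
                             payload$counts$fn, payload$counts$tn)
  auc <- payload$metrics$auc
  compute_metrics(counts, auc = if (is.null(auc)) NA_real_ else auc)
}
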