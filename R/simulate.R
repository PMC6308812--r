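#' Configuration for the synthetic-EEG generator
#'
#' The generator emulates the statistical structure the detection pipeline
#' relies on: 60 s prefrontal recordings at 512 Hz whose theta (4-8 Hz) and
#' alpha (8-12 Hz) band power rises with a latent drowsiness level, a
#' residual 50 Hz mains component, and sporadic eye-blink transients. It does
#' not attempt biophysical realism (no cortical dipole model, no EOG/EMG
#' channels).
#'
#' `band_power_profile` is a data frame with columns `band`, `low`, `high`,
#' `baseline`, `slope`: each band contributes zero-phase band-pass-filtered
#' Gaussian noise with variance `baseline + slope * effect_size * latent`
#' (signal-units squared). The defaults put the drowsiness signal in the
#' delta, theta and alpha bands, matching the frequency ranges known to track
#' sleepiness ratings, with theta/alpha carrying most of it.
#'
#' @param n_subjects Number of subjects.
#' @param recordings_per_subject Recordings per subject (the reference study
#'   schedule is three a day over five analysed days, i.e. 15).
#' @param fs Sampling rate, Hz.
#' @param duration Recording length, seconds.
#' @param band_power_profile Data frame as described above; `NULL` for the
#'   default profile.
#' @param line_noise_amp Amplitude of the residual 50 Hz sinusoid (the
#'   acquisition device applies a notch filter, so the default is small).
#' @param blink_rate Eye-blink events per minute (Poisson).
#' @param effect_size Dimensionless multiplier on all band slopes; 0 removes
#'   every association between the signal and the latent level.
#' @param seed Integer seed giving bit-reproducible datasets.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 29, recordings_per_subject = 15,
                       fs = 512, duration = 60,
                       band_power_profile = NULL,
                       line_noise_amp = 2, blink_rate = 10,
                       effect_size = 1, seed = 1L) {
  if (is.null(band_power_profile)) {
    band_power_profile <- tibble::tribble(
      ~band,    ~low, ~high, ~baseline, ~slope,
      "delta",     1,     4,        60,     15,
      "theta",     4,     8,        30,     35,
      "alpha",     8,    12,        25,     40,
      "beta",     12,    26,        15,      0,
      "gamma",    26,    45,         5,      0
    )
  }
  band_power_profile <- tibble::as_tibble(band_power_profile)
  stopifnot(all(c("band", "low", "high", "baseline", "slope") %in%
                  names(band_power_profile)))
  if (n_subjects <= 0 || recordings_per_subject <= 0 || fs <= 0 ||
      duration <= 0 || effect_size < 0 || blink_rate < 0 ||
      line_noise_amp < 0) {
    abort("Invalid simulation configuration (counts/rates must be positive).",
          class = "drowsy_error")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         recordings_per_subject = as.integer(recordings_per_subject),
         fs = fs, duration = duration,
         band_power_profile = band_power_profile,
         line_noise_amp = line_noise_amp, blink_rate = blink_rate,
         effect_size = effect_size, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Zero-phase band-limited Gaussian noise with a target variance.
band_limited_noise <- function(n, fs, low, high, variance) {
  x <- rnorm(n)
  nyq <- fs / 2
  hi <- min(high, nyq * 0.99)
  bf <- signal::butter(4, c(low, hi) / nyq, type = "pass")
  y <- signal::filtfilt(bf, x)
  s <- sd(y)
  if (s == 0) return(rep(0, n))
  y * sqrt(variance) / s
}

# Smooth biphasic blink pulse (~0.5 s), energy concentrated below 8 Hz:
# a first-derivative-of-Gaussian waveform.
blink_pulse <- function(fs, width_s = 0.5, amplitude = 80) {
  t <- seq(-width_s / 2, width_s / 2, by = 1 / fs)
  sigma <- width_s / 6
  p <- -t * exp(-t^2 / (2 * sigma^2))
  amplitude * p / max(abs(p))
}

#' Simulate one synthetic EEG recording
#'
#' Produces a single-channel trace as the sum of per-band filtered Gaussian
#' noise (variances set by the config's `band_power_profile` and the latent
#' drowsiness level), a 50 Hz sinusoid, and Poisson-distributed biphasic
#' blink transients. Deterministic given `seed`.
#'
#' @param latent_drowsiness Latent drowsiness level in `[0, 1]`.
#' @param config A [sim_config()].
#' @param seed Integer seed for this recording.
#' @param duration Optional override of `config$duration` (seconds).
#' @param recording_id,subject_id,session,kss Metadata for the returned
#'   [eeg_recording].
#'
#' @return An [eeg_recording].
#' @export
#'
#' @examples
#' cfg <- sim_config(seed = 7)
#' rec <- simulate_recording(0.8, cfg, seed = 7, duration = 10)
simulate_recording <- function(latent_drowsiness, config = sim_config(),
                               seed = config$seed, duration = config$duration,
                               recording_id = "sim", subject_id = "subject",
                               session = "daytime", kss = NA_integer_) {
  if (!is.numeric(latent_drowsiness) || length(latent_drowsiness) != 1L ||
      is.na(latent_drowsiness) || latent_drowsiness < 0 ||
      latent_drowsiness > 1) {
    abort("`latent_drowsiness` must be a single value in [0, 1].",
          class = "drowsy_error")
  }
  fs <- config$fs
  n <- round(duration * fs)
  prof <- config$band_power_profile
  samples <- withr::with_seed(as.integer(seed), {
    x <- rep(0, n)
    for (i in seq_len(nrow(prof))) {
      v <- prof$baseline[i] +
        prof$slope[i] * config$effect_size * latent_drowsiness
      if (v > 0) {
        x <- x + band_limited_noise(n, fs, prof$low[i], prof$high[i], v)
      }
    }
    if (config$line_noise_amp > 0) {
      t <- (seq_len(n) - 1) / fs
      x <- x + config$line_noise_amp * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
    }
    if (config$blink_rate > 0) {
      n_blinks <- rpois(1, config$blink_rate * duration / 60)
      if (n_blinks > 0) {
        pulse <- blink_pulse(fs)
        for (pos in sort(runif(n_blinks, 0, max(duration - 0.5, 0)))) {
          i0 <- round(pos * fs) + 1
          idx <- i0:min(i0 + length(pulse) - 1, n)
          x[idx] <- x[idx] + pulse[seq_along(idx)]
        }
      }
    }
    x
  })
  eeg_recording(samples, fs = fs, recording_id = recording_id,
                subject_id = subject_id, session = session, kss = kss)
}

# Ordinal KSS from latent drowsiness: eight equally spaced thresholds on
# [0, 1] plus logistic jitter, so KSS tracks (but does not determine) latent.
kss_from_latent <- function(latent, noise_scale = 0.06) {
  u <- latent + rlogis(length(latent), 0, noise_scale)
  thresholds <- (1:8) / 9
  1L + vapply(u, function(ui) sum(ui > thresholds), integer(1))
}

# Session-conditional latent drowsiness: morning and night recordings skew
# drowsy, daytime is a mixture of alert and drowsy states.
draw_latent <- function(session) {
  switch(session,
    morning = stats::rbeta(1, 4, 2),
    night   = stats::rbeta(1, 5, 1.5),
    daytime = if (runif(1) < 0.6) stats::rbeta(1, 1.5, 5)
              else stats::rbeta(1, 4, 2),
    task    = runif(1)
  )
}

#' Simulate a full study dataset
#'
#' Draws, for every subject and session slot (cycling morning, daytime,
#' night), a latent drowsiness level, maps it to a KSS score through eight
#' equally spaced thresholds with logistic jitter, and synthesises the
#' recording with [simulate_recording()]. Per-recording seeds are derived
#' deterministically from `config$seed`, so the whole dataset is
#' bit-reproducible.
#'
#' @param config A [sim_config()].
#' @return A list with elements `recordings` (list of [eeg_recording]) and
#'   `manifest` (tibble with `recording_id`, `subject_id`, `session`, `kss`,
#'   `latent`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  sessions <- c("morning", "daytime", "night")
  plan <- tidyr::expand_grid(
    subject = seq_len(config$n_subjects),
    slot = seq_len(config$recordings_per_subject)
  )
  plan$session <- sessions[(plan$slot - 1L) %% 3L + 1L]
  meta <- withr::with_seed(config$seed, {
    latent <- vapply(plan$session, draw_latent, numeric(1))
    kss <- kss_from_latent(latent)
    tibble::tibble(
      recording_id = sprintf("S%02d_R%02d", plan$subject, plan$slot),
      subject_id = sprintf("S%02d", plan$subject),
      session = plan$session, kss = kss, latent = latent
    )
  })
  recordings <- purrr::pmap(
    list(meta$latent, meta$recording_id, meta$subject_id, meta$session,
         meta$kss, seq_len(nrow(meta))),
    function(latent, rid, sid, sess, kss, i) {
      simulate_recording(latent, config,
                         seed = (config$seed %% 100000L) * 10000L + i,
                         recording_id = rid, subject_id = sid,
                         session = sess, kss = kss)
    }
  )
  list(recordings = recordings, manifest = meta)
}

#' Simulate a two-condition practical experiment
#'
#' Every subject contributes one recording per condition (within-subject
#' design): condition A emulates a drowsiness-evoking task and condition B an
#' attention-demanding one, via distinct latent drowsiness means. Recordings
#' default to 300 s, the task length of the practical protocol, so each
#' yields 30 ten-second windows.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param latent_a,latent_b Mean latent drowsiness of conditions A and B.
#' @param latent_sd Between-subject spread of the latent level (truncated to
#'   `[0, 1]`).
#' @param duration Recording length in seconds.
#' @param config A [sim_config()]; its seed drives all draws.
#' @return A list with `recordings` and a `manifest` that includes a
#'   `condition` column.
#' @export
simulate_task_experiment <- function(n_subjects = 20, latent_a = 0.8,
                                     latent_b = 0.25, latent_sd = 0.08,
                                     duration = 300, config = sim_config()) {
  meta <- withr::with_seed(config$seed, {
    tibble::tibble(
      subject_id = rep(sprintf("P%02d", seq_len(n_subjects)), each = 2),
      condition = rep(c("A", "B"), times = n_subjects),
      latent = pmin(1, pmax(0, rnorm(2 * n_subjects,
                                     mean = rep(c(latent_a, latent_b),
                                                times = n_subjects),
                                     sd = latent_sd)))
    )
  })
  meta$recording_id <- paste0(meta$subject_id, "_", meta$condition)
  meta$session <- "task"
  meta$kss <- NA_integer_
  recordings <- purrr::pmap(
    list(meta$latent, meta$recording_id, meta$subject_id,
         seq_len(nrow(meta))),
    function(latent, rid, sid, i) {
      simulate_recording(latent, config,
                         seed = (config$seed %% 100000L) * 10000L + 5000L + i,
                         duration = duration, recording_id = rid,
                         subject_id = sid, session = "task")
    }
  )
  list(recordings = recordings,
       manifest = meta[, c("recording_id", "subject_id", "session", "kss",
                           "condition", "latent")])
}
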