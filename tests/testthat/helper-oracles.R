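# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive O(n^2) template-pair counter for sample entropy.
sampen_oracle <- function(x, m = 2, r = 0.15 * sd(x)) {
  n <- length(x)
  nt <- n - m
  B <- 0L; A <- 0L
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

# AUC as the exhaustive pairwise ranking probability (ties count 1/2).
auc_pairwise_oracle <- function(scores, y01) {
  pos <- scores[y01 == 1]
  neg <- scores[y01 == 0]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# Band power by a plain rectangular-window periodogram (relative use only).
band_power_raw <- function(x, fs, low, high) {
  n <- length(x)
  spec <- abs(fft(x - mean(x)))^2 / n
  freq <- (0:(n - 1)) * fs / n
  sel <- freq >= low & freq < high
  sum(spec[sel])
}

# AR(1) realisation with unit-variance innovations.
ar1_series <- function(n, a1, seed) {
  withr::with_seed(seed, as.numeric(stats::filter(rnorm(n), a1, "recursive")))
}

# Two-class Gaussian feature table: one informative feature (mean shift
# `sep`) and `n_noise` pure-noise features.
make_blob_features <- function(n_per_class = 100, n_noise = 10, sep = 2,
                               seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    tbl <- tibble::tibble(
      signal = c(rnorm(n_per_class, 0), rnorm(n_per_class, sep))
    )
    for (i in seq_len(n_noise)) {
      tbl[[sprintf("noise%02d", i)]] <- rnorm(n)
    }
    tbl$label <- factor(rep(c("alert", "drowsy"), each = n_per_class),
                        levels = c("alert", "drowsy"))
    tbl
  })
}

# Small labelled synthetic feature dataset run through the real generator +
# extractor; cached per session to keep the suite fast.
synthetic_psd_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_subjects = 8, recordings_per_subject = 9,
                        duration = 30, effect_size = 3, seed = 2024)
      ds <- simulate_dataset(cfg)
      fx <- extract_features(ds$recordings, "psd", bands = eeg_bands("full"))
      cache <<- label_windows(fx, labeling_scheme(c(3, 7)))
    }
    cache
  }
})
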