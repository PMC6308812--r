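Package: drowsyEEG
Title: Drowsiness Detection from Prefrontal Single-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for detecting drowsiness from 60-second
    prefrontal (Fp1-A1) single-channel EEG recordings scored with the
    Karolinska Sleepiness Scale (KSS). Provides wavelet soft-threshold
    denoising and artifact-frame removal, three window-level feature
    extractors (Blackman-window band power spectral density, order-5
    Yule-Walker autoregressive coefficients, and multiscale sample
    entropy), stepwise linear discriminant feature selection (SWLDA),
    quantile-based robust scaling, and alert-versus-drowsy classification
    with a nested cross-validated radial-basis-function support vector
    machine, reported through a full confusion-matrix metric suite with
    ROC/AUC and per-recording drowsiness probabilities. A seeded
    synthetic-EEG generator emulates recordings whose theta and alpha
    band power track a latent drowsiness level mapped to KSS scores, so
    every stage is testable without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
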