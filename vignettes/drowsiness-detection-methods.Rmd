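---
title: "Methods: single-channel EEG drowsiness detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-channel EEG drowsiness detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the signal model and
processing chain, the parameters that matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, the
numerical decisions taken where the method description left room, and the
limitations a user should keep in mind.

## The problem and the data model

A single prefrontal EEG channel (Fp1 referenced to the earlobe, dry
electrodes, 512 Hz) is recorded for 60 s while the wearer sits still with
eyes open; immediately afterwards the wearer rates their sleepiness on the
Karolinska Sleepiness Scale (KSS), a 9-point ordinal scale from 1 (very
alert) to 9 (very sleepy). The modelling target is binary: is a 10-second
stretch of signal "alert" or "drowsy"? KSS supplies the labels through
threshold rules; increased theta (4–8 Hz) and alpha (8–12 Hz) band power
with eyes open is the physiological signature the features are designed to
pick up.

An `eeg_recording` is a plain numeric trace plus sampling rate, subject,
session and KSS score. Voltage units are taken as given — the device's
dynamic range is unspecified and every downstream feature is either
scale-covariant (band powers scale with the square of the signal) or
explicitly rescaled (robust scaler), so absolute calibration is never
needed.

## Preprocessing: wavelet shrinkage and artifact frames

Denoising uses a periodised orthogonal discrete wavelet transform (pyramid
algorithm, implemented in the package) with soft thresholding of all detail
coefficients, `sign(c)·max(|c|−λ, 0)`, followed by inverse reconstruction.

Decisions and defaults:

* **Wavelet family: db4** (8-tap Daubechies), configurable (`db2`, `haar`).
  db4 is the conventional compromise for EEG between time localisation and
  smoothness.
* **Depth: 6 levels.** At 512 Hz the detail levels then cover 128–256,
  64–128, 32–64, 16–32, 8–16 and 4–8 Hz, so the transform resolves both
  the mains region (level 3) and the physiological bands.
* **Threshold: universal rule** `λ = σ·sqrt(2 ln N)` with
  `σ = MAD(finest detail)/0.6745`. This is the standard choice when only
  "soft thresholding" is specified; a `fixed` rule with user-supplied λ is
  available (λ = 0 is an exact identity, used as a test).
* **Level indexing: level 1 = finest detail.** The alternative (counting
  from the coarse end) exists in the literature; the finest-first convention
  is documented here because the artifact stage depends on it.
* **Artifact frames.** Muscular and eye-blink artifacts appear as isolated
  high-amplitude coefficients. After decomposition, coefficients at levels
  2 and 4 whose magnitude exceeds `k = 3` times that level's
  normal-consistent MAD are zeroed ("frames" are read as individual
  coefficients, equivalently their support intervals — no frame length is
  specified anywhere, and single coefficients are the minimal faithful
  reading). Both the level set and `k` are configuration.

Length is always preserved: signals whose length is not divisible by
`2^levels` are reflection-padded internally and truncated after
reconstruction, which keeps decompose→reconstruct exact to floating-point
precision (the suite checks ≤ 1e−8 relative error; in practice it is
~1e−13).

A note on expectations: zeroing levels 2 and 4 removes energy in the
64–128 Hz and 16–32 Hz ranges at 512 Hz. A smooth half-second blink
transient keeps most of its energy below 8 Hz, in the approximation band,
so artifact removal reduces the transient's energy — the tests measure this
in the bands the levels actually cover — but does not flatten the blink
completely. Full blink cancellation would need regression-based EOG
correction, which is out of scope.

## Features per 10-second window

Recordings are cut into 10 s windows with a 10 s shift (six windows per
60 s recording, thirty per 300 s task recording); each window inherits the
recording's KSS score. Three extractors are provided:

**Band power (PSD).** One Blackman-tapered periodogram per window — no
Welch sub-segmentation, since a single window function is all that is
specified and 10 s at 512 Hz gives 0.1 Hz resolution. The periodogram is
normalised by the taper power so band powers are integrals of a one-sided
PSD in signal-units²/Hz × Hz. Band edges are half-open `[low, high)`; the
11-band layout spans 1–100 Hz and deliberately omits 49–51 Hz (the
acquisition device notches mains there, so that region is dead). Two
reduced sets are provided: `theta_alpha` (4–8, 8–12 Hz) and `practical`
(1–4, 4–8, 10–12, 12–14 Hz). Band powers are used on a linear scale —
whether a log transform was intended is unknowable from the method
description, so linear is the default and any transform is left to the
caller.

One verified subtlety: a sinusoid sitting exactly on a band edge (e.g.
10 Hz) does **not** put ~all its power into `[10, 12)`. Taper leakage is
symmetric about the tone, so roughly a fifth of its power lands in
`[8, 10)` while the peak bin itself belongs to `[10, 12)` under the
half-open rule. The tests assert the edge-assignment and the ≥95%
concentration for an interior tone; claiming 95% for an edge tone would be
wrong for any taper.

**Autoregressive coefficients.** Order-5 Yule–Walker fit: the Toeplitz
system of biased sample autocovariances is solved directly (`solve()` on
the 5×5 system). Biased autocovariances guarantee positive-definiteness.
A constant window raises a singularity error rather than returning NaNs.
The suite cross-checks the solver against `stats::ar.yw` and against a
generic linear solve of the same system, and verifies recovery of a planted
AR(1) coefficient (a₁ = 0.5 ± 0.05 at n = 30720 averaged over 20 seeds).

**Multiscale entropy.** Sample entropy `SampEn(m, r) = −ln(A/B)` with
`m = 2`, `r = 0.15·SD`, where B counts template pairs (i ≠ j) matching at
length m under Chebyshev distance ≤ r and A the same pairs at length m+1.
The pair counting is O(n²) and implemented in C++; an independent pure-R
brute-force counter is the test oracle (exact equality on windows up to 200
points over 100 seeds). The tolerance r is computed once from the scale-1
window SD and held fixed across scales — the standard multiscale-entropy
definition — with a per-scale mode available. Scales default to 1..20; a
10 s window at 512 Hz leaves 256 points at the coarsest scale, above the
10·(m+1) floor the implementation enforces. Undefined values (no matches,
or zero variance) are flagged `NA`, never silently zero.

## Labeling, selection, scaling

**KSS thresholds.** Single-threshold mode A labels `KSS < A` alert and
`KSS > A` drowsy; dual mode (A, B) labels `KSS < A` alert and `KSS > B`
drowsy. Inequalities are strict as stated, so scores equal to a threshold
are excluded — every KSS value maps to exactly one of
{alert, drowsy, excluded}, which the suite checks for all schemes.

**SWLDA.** Step-wise linear discriminant analysis in its stepwise-regression
form (the formulation standard in the BCI literature): ordinary least
squares of the 0/1 label on the features, forward entry of the smallest
partial-F p-value below `p_enter = 0.1`, backward removal of any included
feature whose partial-F p-value exceeds `p_remove = 0.15`. The F statistic
for a candidate against a k-feature model is referred to `F(1, n−k−2)`.
Determinism: ties on p-values break by feature-name order, so results are
independent of row and column order. Termination: a repeated-model-state
guard plus a `2 × n_features` step cap. Collinear candidates (no rank
increase) are logged as `skip` and passed over — duplicated informative
features therefore yield exactly one survivor. Null calibration is tested:
with all-noise features the expected number selected is close to
`p_enter × n_features`, and the entry p-value is uniform under the null
(KS test).

**Robust scaler.** `z = (x − median)/NIQR` with
`NIQR = (q65 − q35) × 0.7413`, quantiles by linear interpolation of order
statistics (R type 7 — the convention must be pinned because small-sample
quantiles differ across rules). The 0.7413 constant is the
normal-consistency factor for the classical 25–75 interquartile range; the
method as printed pairs it with the narrower 35–65 quantiles, and that
pairing is kept verbatim as the default. The absolute scale of z is
irrelevant downstream (the SVM grid spans 13 octaves of γ), so consistency
of the constant matters less than fidelity; callers can pass the
35/65-consistent constant (≈ 2.5942, i.e. 1/(qnorm(0.65)−qnorm(0.35)))
through `niqr_constant` if they want unit-variance z under normality.
Zero-spread features are flagged at fit time and refused at apply time.
Parameters are fitted on training rows only and serialise to JSON for reuse
at prediction time.

## Classification and evaluation

The classifier is a soft-margin SVM with RBF kernel
`K(x, x′) = exp(−γ‖x−x′‖²)` (via `e1071`, the standard libsvm binding;
features arrive already scaled, so internal scaling is off). Hyperparameters
come from a grid search, `C ∈ 2^−2..2^11` and `γ ∈ 2^−10..2^3` in steps of
one exponent, evaluated by **nested cross-validation**: outer folds estimate
generalisation; inner folds on the outer-training rows alone pick (C, γ) by
pooled inner-fold accuracy. Robust scaling and (optionally) SWLDA selection
are refit inside every outer fold, so held-out rows never influence
scaling, selection or the hyperparameter choice — the suite verifies this
with a label-permutation control (pooled accuracy falls to the
majority-class rate) and a subject-offset fixture where window-level CV
overestimates while leave-one-subject-out stays at chance.

Decisions:

* **Stratified fold draws, fixed seed.** Nothing is said about fold
  construction; stratification guarantees both classes in every fold and the
  seed makes runs bit-reproducible.
* **Window-level folding is the default** (it replicates the development
  analysis); recording-grouped and subject-grouped (`losocv()`) modes exist
  because windows from one recording are not independent and window-level
  CV is optimistic in exactly the way the fixture demonstrates.
* **Argmax tie-break: smallest C, then smallest γ** — deterministic and
  biased towards the smoother model.
* **Per-outer-fold SWLDA** is the default (no leakage); a global-selection
  mode can be had by selecting before calling `nested_cv()`, which mirrors
  the original workflow where selection ran once on all data.

Metrics treat drowsy as the positive class: precision, sensitivity,
specificity, accuracy and F-measure in percent, each flagged `NA` on a zero
denominator. The ROC curve sweeps thresholds over decision scores
(`score ≥ t` ⇒ drowsy) and the AUC is the trapezoid integral; it equals the
exhaustive pairwise-ranking probability, which the suite checks directly
and against `pROC`. Per-recording **drowsiness probability** is the mean of
binary window outputs (0 and 1 attainable); two task conditions are
compared with a paired t-test because each subject completes both
conditions. Exactly identical paired samples return t = 0, p = 1 rather
than an error.

## The synthetic-data generator

`simulate_recording()` builds a trace as a sum of per-band zero-phase
band-pass-filtered Gaussian noise (4th-order Butterworth, forward-backward)
whose variance is `baseline + slope × effect_size × latent`, plus a 50 Hz
sinusoid (default amplitude 2, the residue left after the device notch) and
Poisson blink transients (10/min), smooth biphasic derivative-of-Gaussian
pulses of ~0.5 s with energy concentrated below 8 Hz. Default band profile
(signal-units², chosen as plausible resting prefrontal values with the
drowsiness signal in delta/theta/alpha, strongest in theta and alpha):
delta 60 + 15·e·latent, theta 30 + 35·e·latent, alpha 25 + 40·e·latent,
beta 15, gamma 5, with `e = effect_size`. How far band power actually moves
between alert and drowsy states is not quantified anywhere, so
`effect_size` is an explicit free parameter: 1 by default (overlapping but
separable classes), 0 removes the signal entirely, 3 is the "high effect"
setting used where the tests need near-separable data.

`simulate_dataset()` draws a latent drowsiness level per session slot
(morning and night skew drowsy — Beta(4,2) and Beta(5,1.5); daytime is a
60/40 mixture of alert-ish Beta(1.5,5) and drowsy Beta(4,2)) and maps
latent to KSS through eight equally spaced thresholds on [0,1] with
logistic jitter (scale 0.06), so KSS tracks but does not determine the
latent state. Per-recording seeds derive arithmetically from the config
seed: identical configs give bit-identical datasets.

What the generator does **not** emulate: cortical dipole geometry, 1/f
spectral slope, non-stationarity within a recording, EOG/EMG channels,
electrode pops, or any coupling between artifacts and drowsiness. Passing
tests on this generator therefore demonstrate the pipeline's statistical
machinery — leakage-free selection and scaling, calibrated tests, correct
formulas, monotone feature responses — not field performance on real
recordings, which depends on signal properties the generator deliberately
leaves out.

## Problem sizes and numerical tolerances

The suite and the acceptance script run at deliberately modest scale: the
cached property dataset is 8 subjects × 9 recordings of 30 s (216 windows)
at `effect_size = 3`; grid searches in tests use 2×2 to 3×3 sub-grids of
the full 14×14 default; Monte-Carlo loops use 20–200 seeds depending on the
variance of the statistic. The full-schedule bookkeeping check (29 subjects
× 15 recordings of 60 s → 435 recordings → 2610 windows) runs at full size
since it is linear-time. Key tolerances: perfect reconstruction ≤ 1e−8
relative (observed ~1e−13); sample entropy equals its oracle exactly; AR(1)
recovery ±0.05; scaler identities ≤ 1e−12; AUC vs pairwise oracle ≤ 1e−10.

## Known limitations

* The exclusion bookkeeping of the original study (which windows were
  dropped for missing KSS or recording errors) is not reconstructible from
  published information; class counts on real data are therefore not a
  target this package can reproduce.
* Window-level cross-validation — the replication default — overstates
  deployment performance whenever windows of one recording share state;
  use `losocv()` for honest subject-level numbers.
* SWLDA's OLS-on-labels formulation tests linear separability per feature;
  features informative only through interactions will be missed.
* The EDF container is not read; recordings enter as one-sample-per-row
  delimited text (the format the CLI writes).
* The SVM decision threshold is libsvm's default (0); cost-sensitive
  thresholding for the heavy class imbalance that KSS labelling produces is
  left to the caller via the ROC curve.
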