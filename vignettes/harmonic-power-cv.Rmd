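---
title: "Harmonic power features and exhaustive cross-validation for HVAD thrombosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonic power features and exhaustive cross-validation for HVAD thrombosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pumpharmonics)
```

## The problem

A centrifugal ventricular assist device (here the HeartWare HVAD) emits a
line spectrum: a fundamental at the rotor speed, FF = rpm/60 Hz (42–47 Hz
for clinical speeds of 2540–2800 rpm), and integer harmonics 2H, 3H, ...
The four-blade impeller accents multiples of the 4th harmonic. Thrombus on
the rotor changes how power is distributed across these lines, which is why
harmonic power is a candidate acoustic marker of pump thrombosis — a
complication whose standard clinical marker (LDH elevation) tends to move
late.

This package implements the full chain from an accelerometer recording to a
cross-validated thrombosis classifier, together with the embedded
11-recording clinical cohort it was designed around (3 thrombosis YES, 8
NO; two patients contribute two recordings each). With 11 recordings one
cannot build a predictive model for new data; the goal of the protocol is
to rank feature subsets and algorithms by exhaustive cross-validation on
the cohort itself.

## Spectral features

`extract_profile()` maps a recording to twelve harmonic power values:

1. **PSD estimation.** The default estimator is the full-record
   periodogram (`compute_periodogram()`, rectangular window, mean removal
   only): for a 60 s record its 1/60 Hz grid places every harmonic of
   rpm/60 exactly on a bin, and its fine resolution is what a narrow
   harmonic integration window wants. `compute_welch()` (1 s Hann
   segments, 50 % overlap) is provided for visualization — averaging
   trades resolution for variance. Both satisfy Parseval's relation (PSD
   integrates to the signal's mean square), which the test suite checks at
   1–2 %.
2. **Harmonic power.** `harmonic_power()` integrates the PSD by the
   trapezoid rule over bins in the closed 1 Hz window centered on n·FF.
   On the 1/60 Hz periodogram grid the choice of quadrature matters only
   at the 0.01 dB level. FF is taken from the pump speed when known
   (`fundamental_from_rpm()`); `detect_fundamental()` (peak search in
   35–55 Hz with parabolic refinement, low-confidence flag when the peak
   is under 3x the band median) is the fallback. Harmonic centers are
   exact multiples of FF; no per-harmonic peak re-snapping is done, since
   a healthy rotor is speed-locked.
3. **Normalization.** `normalize_profile()` shifts the dB vector so the
   twelve linear powers sum to 1 (0 dB total). This removes the unknown
   amplitude calibration of the recording chain entirely — the tests
   assert gain invariance to one microdB — at the cost of making the
   features compositional (only relative power survives). Linear powers
   are clipped at 1e-12 before the log so silent windows produce a finite
   floor instead of `-Inf`.

## The cross-validation protocol

`run_cv()` implements exhaustive leave-two-out cross-validation: all
C(11,2) = 55 validation pairs, 9 training rows per split, 110 pooled
predictions collected into one confusion matrix with thrombosis YES as the
positive class. Leave-one-out (11 splits) is the `scheme = "loocv"`
variant. The baseline is the ZeroR rule — predict the training majority,
always NO on this cohort — giving 80/110 = 8/11 = 72.7 % under both
schemes.

When `pca = "2d"`, a 2-component PCA is fitted **on the 9 training rows
only** in every split (centering, unit-variance scaling, scores whitened
to unit training variance) and both sides are projected through it before
the classifier sees them. Fitting on all 11 rows first would leak the
held-out pair's position into the features; a test verifies the engine
uses the training-only fit.

Repeat recordings (HW-D1/D2, HW-F1/F2) are treated as independent items,
exactly as the original protocol did. This is a known leakage caveat: a
split can train on HW-D1 and validate on HW-D2. The package reproduces
the protocol rather than "fixing" it; a patient-grouped variant would be a
different study.

## The frozen KNN configuration

The cohort analyses were originally produced with a commercial AutoML
classifier that selects K-nearest-neighbor hyperparameters internally per
training set; those selections are not published and are out of scope to
emulate. The package instead pins, per model family, the effective
settings that reproduce the published pooled confusion matrices, frozen in
`knn_reproduction_defaults()`:

* **LTOCV on raw harmonic powers:** k = 2, features min-max rescaled to
  [0, 1] on training statistics, vote ties broken toward the training
  majority class. On a 9-row training set with at most 3 positive cases, a
  two-of-two-neighbors rule is the prior-calibrated behavior: a single
  close thrombotic neighbor is not enough evidence against a 2:1 negative
  prior. This configuration yields the published 91.8 % on (P_FF, P_2H)
  and 87.3 % with confusion (tp 18, fp 2, fn 12, tn 78) on
  (P_FF, P_2H, P_3H), with both false positives arising from the
  [HW-B, HW-G] validation pair.
* **Runs on 2D PCA scores, and LOOCV:** k = 1 (no further rescaling for
  PCA scores — they are already whitened). This yields 98.2 % with
  confusion (tp 30, fp 2, fn 0, tn 78) for PCA on (P_FF, P_2H, P_3H) —
  precision 93.8 %, recall 100 %, F1 96.8 % — and 100 % LOOCV accuracy for
  the (P_FF, P_2H) and (P_FF, P_2H, P_3H) models, plain and PCA.

No single k can reproduce both families: with a strict two-vote rule, the
split holding out both thrombotic HW-D recordings leaves only one YES row
in training, so zero false negatives is unreachable; with k = 1 the plain
LTOCV accuracies land near 97 % instead of the published 87.3 %. The
per-family pinning mirrors the per-model hyperparameter selection of the
original tooling and is recorded in every run manifest. Within each family
the configuration is fixed before the run and shared across all variable
sets; it is not re-tuned per cell. Remaining cells of the published grids
(and all non-KNN algorithms, which here run with frozen library defaults:
`glm`, `randomForest` with 200 trees, `xgboost` with 30 rounds at depth 3,
`e1071::svm` RBF, `e1071::naiveBayes`) agree directionally but not to the
decimal, for the same reason.

Other numerical conventions: distance ties are broken by training row
order (stable sort); accuracies are reported as percentages to one decimal
computed from exact integer counts, rounding half away from zero;
stochastic classifiers run 25 repeats from seed 20250502 and report the
modal confusion matrix with the dispersion retained.

## Synthetic data

`generate_recording()` builds a pump-like signal — sinusoids at n·FF with
linear powers proportional to a prescribed normalized dB profile, seeded
uniform phases, plus white Gaussian noise at a chosen level below the
total harmonic power. Defaults (6 kHz, 12 s, FF = 2560/60 Hz, noise
−30 dB) are sized so the full test battery runs in seconds; the duration
is a multiple of 3 s so every harmonic of 2560/60 Hz completes an integer
number of cycles and sits exactly on a periodogram bin, the same
self-consistency a 60 s clinical record has at rpm/60 Hz. An off-grid
fundamental adds rectangular-window leakage from the strong fundamental
into the weak harmonic windows, which is worth knowing about when
analyzing free-running recordings.

What the generator does *not* emulate: the 1/f-like decay of the real
broadband floor (noise here is white), heart sounds, respiration and
motion artifacts, or amplitude/speed modulation of the pump. Passing
recovery tests therefore show the spectral chain is correct, not that the
features are robust to physiological confounders. `generate_cohort()`
draws labeled Gaussian feature tables for engine tests, and
`paperlike_cohort()` builds an 11-row cohort with the published class
geometry — a thrombosis cluster plus two adjacent non-thrombotic
"confusers" — so the [HW-B, HW-G]-style failure mode is reproducible on
synthetic data.

## Problem sizes used by the tests

The test suite runs entirely on synthetic signals (6 kHz, 4–12 s), the
embedded 11-row cohort, and small Gaussian cohorts; profile-recovery and
estimator-variance properties use 20 seeds, and the label-permutation
check uses 100 permutations. These sizes keep the default suite under a
minute on one CPU while leaving every assertion at its stated tolerance.

## Known limitations

* Eleven recordings cannot support a deployable classifier; everything
  here quantifies in-cohort separability under exhaustive CV.
* The recording-to-feature stage and the published feature table are
  linked only qualitatively: the exact estimator settings behind the
  printed dB values are not recoverable, so the embedded Table of
  harmonic powers is treated as ground truth rather than re-derived from
  audio.
* Per-recording (not per-patient) cross-validation overstates
  generalization for the two twice-recorded patients.
* Absolute acoustic power is undefined after 0 dB-sum normalization; any
  marker that lives in overall loudness is invisible to these features.
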