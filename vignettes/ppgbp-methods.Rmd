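---
title: "Cuffless blood-pressure estimation from PPG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuffless blood-pressure estimation from PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ppgbp` implements a calibration-free, beat-level pipeline that estimates
systolic and diastolic blood pressure (SBP/DBP) from a single-channel
finger photoplethysmogram (PPG) sampled at 50 Hz, together with subject
biometrics. This vignette explains the models, the tunable parameters and
their units, the design decisions taken where the method left choices open,
and what the synthetic cohort generator does and does not emulate.

## The estimation model

Each 60 s recording is segmented into foot-to-foot cardiac cycles. After
quality control, the 30 beats most similar to the measurement's median
template are kept, and every beat is summarised by 19 features:

* **P1–P4** — coefficients of the 32-point, min-max-normalised beat shape
  on a 4-component SVD basis fitted to all training beats;
* **S1–S8** — the same construction on the second-derivative waveform
  (SDPTG), with 8 components;
* **heart rate** (bpm) from the beat duration;
* **b/a, c/a, d/a, e/a** — signed amplitude ratios of the SDPTG systolic
  waves, indices of vascular tone and aging;
* **SI** — stiffness index: subject height divided by the
  systolic-peak-to-dicrotic-notch time lapse (m/s);
* **BMI** (kg/m²).

Two bootstrap-aggregated regression-tree ensembles (one per pressure) map
the features to pressure. Because a measurement has one cuff reference but
30 beat rows, each row's training target is the reference plus an
independent uniform perturbation on ±0.5 mmHg. The per-measurement estimate
is the **median** of the 30 per-beat predictions; the method itself does
not state an aggregator, and the median matches its robust style elsewhere
(median template, median calibration factor).

Validation is leave-one-subject-out (LOSO): all measurements of the
held-out subject are removed, the SVD bases and both ensembles are refitted
on the remainder, and the held-out measurements are predicted. Personal
calibration subtracts from each new estimate the subject's calibration
factor, defined as the median of their previous fitting errors; by
construction this zeroes the subject's median error on the data the factor
was computed from.

## Quality control

Per beat, five hemodynamic features are computed: perfusion index
(peak-to-trough over mean, dimensionless), stiffness index (m/s), heart
rate (bpm), and the trapezoidal areas under the baseline-shifted waveform
from foot to notch and notch to beat end (sample-unit·s). The rules:

* a beat is **abnormal** when any feature deviates from the measurement
  median by more than 3 scaled median absolute deviations (scale 1.4826),
  or when a fiducial flag is set (boundary peak, missing notch, incomplete
  SDPTG). The outlier criterion itself is a design choice — the method only
  says "considered an outlier" — and the robust median/MAD form tolerates
  exactly the ≤20% contamination the next rule permits. On quantized
  features the MAD can degenerate to zero, so a scaled-IQR fallback is
  used, and the threshold never drops below 5% of the feature median —
  genuine artifacts move these features by far more; sub-percent
  variation on very clean signal is physiology, not artifact;
* the **SDPTG noise test** fails a beat when the standard deviation of the
  SDPTG over the dicrotic-notch-to-beat-end segment strictly exceeds 15% of
  |b|; a segment exactly at the threshold passes ("exceeded" is read
  strictly);
* a **measurement** is excluded when abnormal beats strictly exceed 20% of
  all beats, or when fewer than 30 good cycles survive. Exactly 20%
  abnormal is kept.

## Signal-processing choices

The detection algorithms are not specified by the method and are standard
practice at 50 Hz:

* **Feet**: zero-phase 0.5–10 Hz Butterworth band-pass, upstrokes as
  first-derivative maxima above a relative threshold (scale- and
  offset-invariant), each foot the preceding local minimum. Inter-foot
  intervals outside 0.3–2.0 s (30–200 bpm) invalidate their bounding feet.
* **Beats** are foot-to-foot and closed on both ends: consecutive beats
  share the boundary sample, so each holds one complete cycle.
* **Systolic peak**: global maximum in the first 60% of the beat; a maximum
  on the window edge flags the beat unusable.
* **Dicrotic notch**: most prominent local minimum (≥1% of beat amplitude)
  in (peak, 0.9·n]; failing that, the upward zero-crossing of the smoothed
  second derivative (an inflection, the damped-notch case); failing that,
  the beat is "notchless" and excluded from SI and the noise test.
* **SDPTG**: quadratic Savitzky–Golay smoothing before each of two central
  differentiations. The window is 7 samples (140 ms): at 50 Hz raw double
  differencing is noise-dominated, and 7 is the widest window that keeps
  zero-noise fiducials within one sample of ground truth. The a wave is the
  SDPTG maximum before the systolic peak (the first two samples are skipped
  — one-sided difference ends distort them); b, c, d, e are the subsequent
  alternating extrema.
* **Sub-sample refinement**: peak and notch positions used for the
  stiffness index are refined by parabolic interpolation. At 50 Hz the raw
  peak-to-notch lapse is an integer number of 20 ms samples; without
  refinement its within-measurement MAD is frequently zero and the outlier
  rule misfires.

## Feature-extraction choices

* The SVD basis is fitted **once per training fold** on all training beats
  and reused to project test beats. A per-measurement basis would make
  coefficients incomparable across subjects; whether the original analysis
  fitted one global basis is not documented.
* Beats are min-max normalised (baseline to 0, peak to 1) before the SVD so
  the coefficients encode shape, not perfusion amplitude — perfusion enters
  separately through QC and stratification. A `normalize = "none"` knob
  disables this.
* Component counts are fixed at 4 (PPG) and 8 (SDPTG); the fractions of
  variance they explain are logged diagnostics, not selection criteria.
  Component signs follow the largest-magnitude-element-positive convention.
* Template similarity is Euclidean distance on the normalised 32-point
  beats; ties at the selection boundary go to the earlier beat.

## Model choices

* `min_leaf = 30` is the stated minimum leaf size; `n_trees = 100` is a
  default (the method names no ensemble size).
* `mtry` defaults to one third of the 19 features — the regression default
  of the tree-bagging implementation the method was developed with. Pure
  bagging (`mtry = 19`) is available; at desk-scale cohorts the decorrelated
  ensemble generalises across subjects noticeably better.
* One master seed drives everything; every fold, measurement and
  perturbation derives a deterministic sub-seed (a counter/label hash), so
  runs are bit-reproducible and insensitive to processing order. Training
  rows are canonically sorted before bootstrap draws for the same reason.
* The dual-cuff disqualification rule (reference readings differing by more
  than 5 mmHg) is represented as an input-table flag filtered on load, since
  raw dual readings are usually absent from exported data.

## The synthetic cohort generator

No recordings ship with the package; `synth_config()` +
`simulate_cohort()` generate a cohort whose biometric marginals emulate a
mixed community/in-hospital adult population: a young arm (≤50 y) centred
at 36.0 ± 8.4 y with SBP 118.7 ± 17.0 mmHg, an older arm at 69.3 ± 11.6 y
with SBP 130.5 ± 18.6 mmHg, height 163 ± 8 cm, BMI 24.4 ± 3.8 kg/m², and
mild positive BMI→SBP (1.2 mmHg per kg/m²) and heart-rate→SBP
(0.15 mmHg per bpm) couplings, as seen in adult cohorts.

Each beat is a **two-lobe pulse**: a skewed (two-sided) Gaussian systolic
lobe plus a symmetric diastolic lobe,

$$s(t) = \exp\!\Big(-\tfrac{(t-t_1)^2}{2\,\sigma_{L/R}^2}\Big)
       + a_2 \exp\!\Big(-\tfrac{(t-t_2)^2}{2\,\sigma_2^2}\Big),$$

with $\sigma_L$ on the upstroke side and $\sigma_R$ on the decay side.
Lobe timings are in **absolute seconds**, not cycle fractions, because
pulse-reflection timing does not scale with heart period; this is what
makes the stiffness index track pressure rather than heart rate. The
couplings, all linear in the morphology-effective pressure:

* decay width $\sigma_R = 0.050 - 3.5\times10^{-4}(SBP-120)$ s — a stiffer
  system decays faster, which pulls the dicrotic valley earlier (higher SI)
  and deepens the central SDPTG b wave relative to a (more negative b/a);
* diastolic lobe centre $t_2 = t_1 + 0.31 - 2.5\times10^{-3}(SBP-120)$ s;
* diastolic amplitude $a_2 = 0.32 + 4.0\times10^{-3}(DBP-75)$, damped with
  age above 60 y to exercise the damped-notch detection path.

The morphology-effective pressure is the subject's true pressure plus a
per-subject bias (SD 3 mmHg by default; 8 mmHg in calibration scenarios),
minus a fixed 15 mmHg penalty when the perfusion index is below 0.01
(weak pulses read low), plus 2 mmHg per-measurement jitter. The cuff
reference is the true pressure plus irreducible N(0, 5 mmHg) noise for SBP
(3 mmHg for DBP) — the floor no waveform-based estimator can beat. AC/DC
is set per subject from a log-normal perfusion level centred at 0.012,
additive white noise defaults to 1% of AC (2% for poorly perfused
subjects), with a slow sinusoidal baseline drift of 0.3 AC and 2%
beat-to-beat period variability.

Ground truth (beat boundaries, fiducials, SDPTG wave indices and ratios)
is computed from the analytic derivatives of the lobe model on a fine
grid, independently of the detection path, which closes the loop in tests:
on zero-noise output every detected fiducial must sit within one sample of
truth.

**Planted effects are exaggerated on purpose.** The low-perfusion penalty
(15 mmHg) and the calibration-scenario subject bias (8 mmHg) are larger
than the corresponding effects reported for real cohorts of thousands of
measurements, because a desk-scale cohort of 120 measurements must detect
them with a two-sample or paired t-test at 5% significance and power above
0.8. Passing tests therefore demonstrate that the pipeline detects and
corrects such effects in the planted *direction*, not that real effects
have these magnitudes.

What the generator does **not** emulate: motion artifacts with physiologic
structure, respiratory modulation, arrhythmia, multi-wavelength or contact
pressure effects, or any hemodynamic (Windkessel-type) mechanism. The
waveform family is the simplest one exhibiting a foot, systolic peak,
dicrotic notch and five SDPTG waves; conclusions about real recordings
require real recordings.

## Numerical and degenerate-input conventions

* Beat resampling is linear interpolation onto 32 equally spaced points,
  endpoints preserved.
* Areas use the trapezoidal rule scaled by 1/fs; zero-amplitude beats give
  zero areas.
* A constant record, a record with no upstrokes, or fewer than two
  physiological feet raise a "no pulsatile activity" error; measurements
  shorter than 10 s are refused.
* Constant training targets (possible only when the ±0.5 mmHg perturbation
  is disabled) produce a constant predictor and a warning.
* A correlation against a constant reference is reported as `NA`, not an
  error; empty strata appear in reports with `n = 0` and no statistics.
* Test-of-improvement with identical error vectors returns p = 0.5 (no
  effect) rather than failing on zero variance.

## Problem sizes used by the test-suite

The package's own checks run the full pipeline on a 60-subject × 2
measurement cohort (the default study conditions) for recovery, determinism
and stratification properties, a 25-subject × 4-measurement cohort for the
calibration properties, and smaller cohorts (1–15 subjects, 15–60 s
records) for unit-level properties. These sizes keep a complete run on one
CPU in the minutes range while leaving the statistical criteria
well-powered; they are package choices, not method constants.

## Known limitations

* At 50 Hz the d and e waves are shallow; under realistic noise their
  detected locations scatter by several samples even though a–c remain
  stable. The ratios still carry signal, but d/a and e/a are the noisiest
  features.
* The stiffness index depends on notch detectability; heavily damped
  (older-arm) waveforms fall back to inflection-based notches, which are
  systematically earlier than valley notches.
* LOSO with tree ensembles degrades sharply when biometric features are
  pure subject identifiers (each tree can isolate subjects); real cohorts
  where biometrics correlate with pressure — and the generator's couplings
  — avoid this failure mode, but it is worth knowing when applying the
  model to data where they do not.
* The calibration factor is assumed stable over the follow-up horizon; no
  drift model is provided.
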