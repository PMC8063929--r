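---
title: "EMD-based ERP features for infant risk classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMD-based ERP features for infant risk classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`erpemd` implements an end-to-end analysis chain for classifying infants by
familial autism risk (control vs high-risk) and by diagnostic outcome
(HR-ASD vs HR-noASD) from visual event-related potentials (ERPs): empirical
mode decomposition (EMD) of condition-averaged ERPs, a six-feature battery
per intrinsic mode function (IMF) and channel, reduction by the maximum
across channels, weight-correlation feature ranking, and nested
cross-validated k-NN / SVM classification. Because no infant EEG recordings
ship with the package, a synthetic-cohort generator reproduces the
statistical structure the analysis assumes; it is first-class, tested code.

## The processing model

Epoched EEG (trials × channels × samples; 128 channels at 500 Hz, epochs
covering [−200, 800) ms around stimulus onset) is processed per subject and
stimulus condition:

1. **Exclusion** — a subject is dropped if any condition retains fewer than
   10 trials. Reading the rule as *any*-condition violation is the stricter
   of the two possible readings and the common one for complete-design
   classification; `min_trials` is a parameter.
2. **Average re-reference** — at every sample the mean across channels is
   subtracted.
3. **Baseline correction** — per trial and channel, the mean over
   [−200, 0) ms is subtracted. Baseline correction and trial averaging
   commute (both are linear); the per-trial order is kept because it is the
   standard ERP convention, and the equivalence is verified by a test.
4. **Trial averaging** — the pointwise mean across trials gives the ERP,
   one channels × samples matrix per subject × condition.

Sample conventions: half-open windows, so a [−200, 800) ms epoch at 500 Hz
is exactly 500 samples with stimulus onset at (1-based) index 101, and the
baseline holds exactly 100 samples.

## Empirical mode decomposition

Each channel's ERP `erp(t)` is decomposed by sifting. One sift iteration:
find local extrema; interpolate maxima and minima separately with cubic
splines into upper/lower envelopes `e_max(t)`, `e_min(t)`; form the
envelope mean `m(t) = (e_min + e_max)/2`; update the candidate
`d <- d − m(d)`. Sifting stops when either

* `d` satisfies the two IMF criteria — the numbers of extrema and zero
  crossings differ by at most one, and `max |m(t)|` is at most
  `envelope_tolerance` × the candidate's peak-to-peak range — or
* the Cauchy criterion `Σ(d_prev − d)² / Σ d_prev² < sd_threshold` fires, or
* `max_sift_iters` is reached.

The IMF is subtracted and sifting repeats on the residual; extraction stops
at `n_imfs` or when a residual is monotone (fewer than two maxima or
minima). By construction `erp(t) = Σ imf_i(t) + r(t)` holds to
floating-point accuracy, which the tests assert at 1e−9 relative on random
signals.

Numerical choices, all in `sift_config()`:

* `n_imfs = 3`. Higher-order modes of a 1-s epoch carry only slow trends
  and contribute nothing to classification; IMFs 1–3 also cover the beta
  and gamma bands that carry the hypothesized group differences.
* `sd_threshold = 0.2`, the standard Cauchy setting; the literal criterion
  "envelope mean zero at every point" is unattainable in finite precision,
  so the envelope test uses `envelope_tolerance = 0.05` of the peak-to-peak
  range.
* `max_sift_iters = 50` as a hard cap; in practice ERP channels sift in
  1–5 iterations.
* Envelope interpolation uses cubic splines (`stats::spline`, FMM end
  conditions), the canonical EMD choice.
* **Boundary handling** dominates error for 500-sample epochs: the two
  extrema nearest each edge are mirrored about the signal boundary before
  spline fitting, which keeps envelopes from diverging at the ends. Tests
  that compare against closed forms trim 5% per edge.
* **Plateaus** count as a single extremum at the midpoint of the flat run;
  an exactly-zero sample counts once as a zero crossing. Both conventions
  matter only for degenerate inputs but make the counts deterministic.

A fixed two-tone battery decomposed by an independently written reference
implementation (different language, spline code and extrema handling) is
frozen as a text fixture; per-IMF correlations must exceed 0.95.

## Feature battery

Per IMF (3), condition (6) and channel: energy `Σ x²`; Shannon entropy
`−Σ x² log x²` with `0·log 0 = 0`; mean; standard deviation (n−1); skewness
(population estimator `m₃/m₂^{3/2}`, 0 when the signal is constant); and
*moment*, implemented as the fourth central moment — mean, std and skewness
already cover orders 1–3, so order 4 is the informative next choice. The
entropy uses the natural log and applies the formula directly to squared
amplitudes without normalising them into probabilities; the log base only
rescales the feature and cannot change a rank-based selection.

Features assemble into a channels × 108 matrix (condition-major, then IMF,
then feature) and reduce to 1 × 108 by the **signed** maximum across
channels (the alternative, maximum absolute value, is not used; the signed
max follows the plain reading of "maximum across channels" and keeps
negative-valued features comparable). The attaining channel index is kept
for inspection.

## Feature selection and classification

The per-feature weight is the absolute Pearson correlation between the
feature column and the 0/1 class label (point-biserial correlation) — the
standard correlation filter; a constant feature gets weight 0, ties break
by ascending column index. Selection happens strictly inside training
folds.

Nested cross-validation: outer folds (10 for the risk problem, 5 for the
outcome problem) estimate performance; inner folds (9 and 4 respectively)
on each outer-training fold pick hyperparameters by best mean inner
accuracy, ties to the simpler model (smaller k, then smaller C, then
simpler kernel). Per outer fold, z-score standardisation statistics, the
feature ranking and the hyperparameter choice are all computed from the
outer-training rows only; a perturbation test asserts that mutating
outer-test rows changes nothing fitted in that fold. Standardisation before
distance-based classification is necessary because the features mix units
(energy in µV² against unitless skewness) across several orders of
magnitude.

Classifiers: k-NN with Euclidean distance, k ∈ {1, 3, …, 21}, vote ties
broken by the nearest member of the tied classes; SVM (via `e1071`) with
linear, quadratic, cubic and Gaussian kernels, C ∈ {0.01, 0.1, 1, 10, 100},
and Gaussian width presets expressed as gamma = {0.25, 1, 4}/p for p
features (coarse/medium/fine).

The outcome problem (17 HR-ASD vs 33 HR-noASD) first balances classes:
each of 5 resamples keeps all 17 minority subjects and draws 17 majority
subjects without replacement. Metrics are reported per resample and as the
unweighted mean — the aggregation had to be chosen, and the mean is the
least optimistic simple choice. Accuracy, sensitivity and specificity come
from pooled outer-test confusion counts; a metric with a zero denominator
is reported `NA` rather than thrown.

Folds split by subject; the 6 condition-level waveforms of a subject
(94 × 6 = 564 "observations" in the full design) always travel together,
so no within-subject leakage is possible.

## The synthetic cohort

`generate_cohort()` / `run_cohort_pipeline()` emulate the study design:
44 control, 33 HR-noASD, 17 HR-ASD subjects; six stimulus conditions
(dynamic direct/averted gaze, static direct/averted gaze, face, and a
no-face noise control); 128 channels at 500 Hz (tests use fewer channels —
see below). Per subject × condition, the trial count is Poisson with mean
30 (floored at 1), a realistic retained-trial count for infant paradigms;
`p_low_trials`, `n_low_trial` and `n_missing_outcome` inject the exclusion
cases (the study's 104 → 94 attrition: 6 low-trial, 4 unknown-outcome
subjects).

One trial is the sum of:

* **Components** — Gaussian-shaped P100 (100 ms, +6 µV, σ 25 ms), N290
  (290 ms, −8 µV, σ 40 ms) and P400 (400 ms, +10 µV, σ 60 ms) bumps, each
  spread over channels by a smooth occipitally-peaked profile. Any smooth
  unimodal kernel would do; Gaussians give analytic control of peak
  location and width. The no-face noise condition omits them; other
  conditions apply small fixed gains (0.9–1.1).
* **Evoked oscillations** — one Hann-windowed burst per band (beta
  ~21.5 Hz, gamma ~45 Hz; 150 ms long, centred 250 ms post-stimulus) whose
  carrier is phase-locked to stimulus onset with small frequency (±2 Hz),
  phase (SD 0.2 rad) and envelope-latency (SD 10 ms) jitter. Phase-locking
  is essential: a burst with trial-random phase cancels under trial
  averaging and could carry no group information into ERP features.
* **Background noise** — 1/f-amplitude-weighted noise at `noise_sd` (5 µV)
  plus white noise at half that, independent across channels and trials.
  Residual post-preprocessing noise is not characterised in infant ERP
  work; 1/f-plus-white is the generic EEG background assumption.

Group effects: high-risk subjects have N290/P400 latencies delayed by
40 ms, component amplitudes scaled (control 1.0, HR-noASD 0.6, HR-ASD
0.45), and much stronger evoked beta/gamma bursts (e.g. gamma 0.3 µV
control vs 4.5/6.0 µV). The `"strong"` preset was calibrated once so that
the groups are cleanly separable after feature extraction — its purpose is
to verify that the pipeline can recover a real signal — and the `"null"`
preset switches every group effect off so that any classifier must perform
at chance; both behaviours are asserted end-to-end. The strong effects are
deliberately larger than anything plausible in real infant EEG.

What the generator does **not** model: eye/muscle/line-noise artifacts,
channel bridging, electrode geometry (the topography is a profile over
channel index, not a head model), volume conduction, between-subject
morphology variability beyond the group effects, and induced (non-phase-
locked) oscillations. Passing tests therefore demonstrate that the
implementation is correct and leakage-free under the assumed signal model,
not that comparable accuracies would be reached on clinical recordings.

## Problem sizes in tests and the acceptance script

EMD cost scales with subjects × conditions × channels. The test suite and
the acceptance script run the full 94-subject design at reduced channel
counts — 32 channels for the strong-effect classification runs, 8 for the
null (chance) run, 2 for pure count checks, and a single 128-channel
subject for the dimensionality check — chosen so the whole suite completes
comfortably on one CPU while exercising every code path at full subject
count. Channel count affects only the max-across-channels order statistics,
not the logic under test.

## Known limitations

* EMD has no uniqueness theory; different envelope/boundary conventions
  give slightly different IMFs. The frozen-reference test bounds, but does
  not eliminate, this implementation dependence.
* The "weight correlation" filter is the absolute point-biserial
  correlation; other definitions (e.g. vendor-specific importance weights)
  would rank differently. The weight function is pluggable in code.
* Mode mixing on real, noisy ERPs is not addressed (no ensemble EMD by
  design).
* With 17-per-class outcome runs, single-subject changes move accuracy by
  ~3 percentage points; resample means remain noisy.
* Nested-CV accuracy is overdispersed relative to an iid binomial count:
  in-fold selection and the shared training data correlate the outer-test
  predictions, so on zero-effect cohorts the accuracy is unbiased at chance
  (mean ≈ 0.52 across cohort seeds at n = 94) but swings with a standard
  deviation near 0.13 — roughly 2.5 times the binomial value. Chance-level
  assertions therefore either fix the seed or average several independent
  null cohorts.
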