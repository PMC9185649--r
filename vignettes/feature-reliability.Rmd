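---
title: "Methods: trunk-IMU feature reliability under running fatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trunk-IMU feature reliability under running fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fatiguegait)
```

`fatiguegait` analyses the between-day reliability of features extracted
from a centre-of-mass accelerometer during fatiguing constant-speed
treadmill runs. This vignette documents the model underneath each stage,
the parameters that matter, the numerical decisions, and what the synthetic
cohort can and cannot tell you about real data.

## The design being analysed

Each subject contributes four trials: two at the speed associated with the
maximal lactate steady state (`MLSS1`, `MLSS2`), one 5% faster (`F`), one
5% slower (`S`). A trial is a 5 min warmup at 1.92 m/s followed by the main
run, terminated at volitional exhaustion or 45 min; RPE (Borg 6–20) is
logged every five minutes. Two 5 min windows per trial enter the analysis:

* **NF** (non-fatigued): the first five minutes at the main speed. The
  warmup is excluded — including it would mix 1.92 m/s strides into a
  window meant to characterise the target speed. This is a deliberate
  reading of "first 5 min of the trial", and the alternative (including the
  warmup) is a one-line change in `condition_windows()`.
* **FT** (fatigued): the last *complete* five-minute block, aligned to the
  RPE schedule, so a trial stopped at 38 min has FT = 30–35 min and carries
  the RPE given at 35 min.

Trials shorter than warmup + 10 min are rejected: NF and FT would overlap.

## The synthetic cohort generator

No public multi-subject recordings of this design exist, so the generator
is a first-class, tested component rather than a fixture. It realises the
statistical structure the analysis assumes, at three levels:

1. **Waveform.** One step is a gravity offset (+1 g on VT), a low-frequency
   oscillation per axis, and an exponentially decaying impact transient at
   initial contact (peak `impact_vt`, rise time 6 ms); the ML lobe mirrors
   between left and right steps, making the *stride* the true period of the
   signal. White noise per axis (`noise_*`) controls irregularity and hence
   sample entropy. Units are g with gravity included, and each trial gets a
   random mounting tilt (SD 3°), so the attitude-correction stage does real
   work.
2. **Variance components.** Amplitude-like parameters carry multiplicative
   subject (`between_subject_sd`, default CV 0.10), trial
   (`between_trial_sd`, 0.04) and stride (`within_trial_sd`, 0.01) factors.
   Subject traits are drawn once and shared across that subject's four
   trials; ICC reliability is exactly the ratio of these components, which
   is what the calibration tests exploit.
3. **Fatigue.** Additive parameter shifts ramp linearly from the end of the
   NF window to the start of the final five minutes, then plateau — so NF
   is clean and FT sits on the plateau. The default shifts follow the
   directions this feature family typically shows under running fatigue:
   amplitudes up on every axis with ML largest, VT irregularity up, ML
   irregularity down.

Defaults mirror the design's protocol constants: 1125 Hz sampling, ±16 g
range, 16 subjects, MLSS speed 3.35 ± 0.4 m/s, cadence 180 ± 8 steps/min,
per-label trial durations around 40/38/29/42 min, RPE rising from ~11 to a
terminal 15.5 ± 1.6. A 2 s standing lead before the warmup provides the
static window.

`simulate_condition_means()` exposes the same variance-component model at
the level the statistical layer consumes (one value per subject × trial ×
window), which is how type-I error, power and ICC recovery are calibrated
without synthesising thousands of signals.

**What the generator does not emulate:** soft-tissue artefact and sensor
drift; spectral colour of physiological noise (white noise is used, so
absolute entropy values are not transferable); asymmetry between legs;
non-stationary pacing; device quantisation. Passing tests therefore show
that the *pipeline and statistics* behave correctly under the assumed
variance structure — not that real runners satisfy that structure.

## Preprocessing

* **Attitude correction** estimates mean acceleration over a static window
  (≥0.5 s; magnitude SD must be below 0.05 g, else an error asks for
  another window) and applies the minimal rotation taking it to +VT
  (Rodrigues form; orthonormal to 1e−9, det +1). Norms are preserved, so
  the resultant is invariant — a property tested directly. A static
  gravity vector cannot observe heading: a residual yaw of the ML/AP plane
  (of the order of the mounting tilt) remains and differs between trials.
  This is a physical limit of single-accelerometer alignment, and one
  reason ML-axis features are expected to be the least reliable.
* **Initial contacts** are local maxima of the resultant above
  median + 2·MAD, with candidates closer than half the expected step period
  suppressed in favour of the stronger peak. The detected peak lags the
  true impact onset by the transient rise time (~6 ms), within the ±10 ms
  fidelity the tests require at the native rate. The detector is validated
  against simulator ground truth, not against any published algorithm's
  internals.
* **Steps and strides.** Step lengths (samples) more than 2 SD from the
  mean are excluded; mean and *population* SD are computed once, over all
  steps of the window, before any exclusion, and SD = 0 excludes nothing.
  Foot sidedness is unobservable from one trunk sensor, so strides pair
  steps by global parity — (1,2), (3,4), … — a stride is retained only if
  both steps are, and an excluded step breaks the run so no five-stride
  sample spans the gap. Samples are non-overlapping, avoiding
  pseudo-replication in the condition means. Exclusion is applied per
  condition window, matching the windowed flow. Indices are 1-based with
  half-open `[start, end)` bounds.

## Features

Nine statistics × four axes (VT, ML, AP, resultant) + three RMS ratios
= 39 features. Conventions, chosen for cross-language reproducibility:

* SD is the sample (n−1) estimator; percentiles use linear interpolation
  between closest ranks; RMS is `sqrt(mean(x^2))`, giving the exact
  identity `rms² = mean² + var·(n−1)/n`.
* RMS ratios divide each axis RMS by the resultant RMS; their squares sum
  to one by construction. The resultant has no ratio (identically 1),
  which fixes the count at 39.
* **Sample entropy** SampEn(m, r) = −ln(A/B) with Chebyshev distance and
  self-matches excluded; both counts use the same n−m templates. Defaults
  m = 2, r = 0.2·SD — the dominant convention in the physiological-signals
  literature; r relative to SD makes the statistic scale-invariant
  (tested). The "gait-cycle approach": each stride is linearly resampled to
  `points_per_stride = 200` points before concatenation (5 × 200 = 1000
  points), comparing cycles at like phase regardless of stride-duration
  drift. The entropy estimate stabilises over longer segments (~2000
  points); raise `points_per_stride`, or set `gait_cycle = FALSE` to use
  the raw time base (~3750 points at 180 steps/min and 1125 Hz), as a
  sensitivity check. A zero-variance axis collapses the tolerance to zero,
  so its entropy is flagged `NA` (never ±Inf) and excluded, with a count,
  from condition means.

## Statistics

* **Fatigue × trial ANOVA** is within-subject: every subject contributes
  every cell, so subject is a random blocking factor and each effect is
  tested against its own subject-by-effect stratum
  (`aov(value ~ fatigue*trial + Error(subject/(fatigue*trial)))`). Whether
  the original analysis treated trial as within-subject is not decidable
  from its description; the repeated-measures choice matches the paired
  design and the ICC's two-way random model. No sphericity correction is
  applied (the fatigue factor has two levels; the four-level trial factor
  is reported uncorrected). Listwise deletion handles incomplete subjects,
  with the dropped IDs reported; residual imbalance is an error.
  Degenerate strata are patched deterministically: an effect whose sum of
  squares is round-off relative to the grand total gets F = 0, p = 1; an
  exact effect over a zero residual gets F = ∞, p = 0.
* **Direction of change** is the sign of the FT grand mean minus the NF
  grand mean, reported only when the fatigue effect is significant at α.
* **ICC(2,k)** is the classical two-way random-effects, absolute-agreement,
  average-measures form, computed from the mean squares. Absolute
  agreement is deliberate: a constant added to one trial's column lowers
  the coefficient (tested directionally), while pure rescaling does not.
  A non-positive denominator is flagged degenerate (`NA`) rather than
  reported as a number.
* **Multiple testing** is *not* corrected in the primary tables; instead
  the expected number of chance significances (n × α, e.g. 78 × 0.05 =
  3.9 ≈ 4) is reported alongside. `adjust_p = TRUE` adds a
  Benjamini–Hochberg column for sensitivity analyses.
* The **MLSS rule** classifies a trial as steady when ≥30 min were
  completed and blood lactate rose by less than 1 mmol/L between minutes
  10 and 30 (strict inequality: a rise of exactly 1.0 is not steady).

## Calibration and problem sizes

The suite cross-checks both numerical kernels against independent oracles
(brute-force template counting for entropy; explicit-loop sums of squares
for the ICC) to 1e−9, and calibrates the statistical layer on the
condition-means generator: type-I error of the fatigue effect within
binomial tolerance of 5% over 100 null replicates at n = 16; power above
80% for a one-within-subject-SD shift; ICC recovering the analytic
variance ratio (2/3 for σ²ₛ = σ²ₑ = 1, k = 2) within ±0.05 at n = 500.
Where a single replicate's sampling error exceeds the band (the null ICC at
n = 200, k = 4 has SD ≈ 0.12), the check is on a small replicate mean.

Routine tests run 15–17 min trials at 150–300 Hz with 4–16 subjects;
segmentation fidelity (±10 ms) is verified at the native 1125 Hz; the
acceptance script runs the full 16-subject cohort at 300 Hz with per-label
durations around the protocol's observed means. These sizes are the
package's choices for routine verification — all defaults remain at the
full-scale protocol values.

## Known limitations

* Absolute entropy values depend on the resampling density and noise
  colour; only within-design comparisons (NF vs FT, trial vs trial) are
  meaningful.
* Heading is unidentifiable from static gravity alone (see above); ML/AP
  features inherit a small between-trial rotation that a gyroscope-based
  alignment would remove.
* The IC detector assumes a dominant impact transient; signals with very
  weak impacts relative to the oscillation (e.g. extreme low-amplitude
  trials) fail segmentation loudly rather than silently degrading.
* Under volitional-exhaustion termination the FT window falls at different
  absolute times across trials; the analysis treats FT as a state, not a
  time, which is an assumption, not a finding.
* Frequency-domain, symmetry and discrete spatiotemporal features, and
  gyroscope channels, are out of scope.
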