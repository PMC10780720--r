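---
title: "Floating-epoch accelerometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Floating-epoch accelerometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepoch)
```

## The problem

Oxygen consumption (VO2, mL/kg/min) during walking is commonly estimated
from hip-worn accelerometer output summarised over fixed epochs — most
often the mean amplitude deviation (MAD) of the resultant acceleration over
a constant window such as 6 s. Fixed windows smooth over exactly the events
that cost extra energy in irregular, real-life walking: braking,
re-acceleration and turning. `fepoch` implements a stride-adaptive
alternative: the analysis window *floats* with the gait, spanning two
adjacent steps (one stride) and advancing one step at a time, so that each
epoch describes a single stride cycle and adjacent epochs overlap by one
step. Three per-epoch features result: the floating MAD, its change between
adjacent epochs (dMAD, whose absolute value indexes braking/propulsion
transients), and the step frequency.

## Processing chain

1. **Resultant.** `r[i] = sqrt(x^2 + y^2 + z^2)` — the vector magnitude,
   containing gravity plus movement.
2. **Baseline.** A 2nd-order recursive low-pass at 0.12 Hz with
   coefficient `a = 127/128`:
   `R_LF[i] = 2a R_LF[i-1] - a^2 R_LF[i-2] + (1-2a+a^2) r[i]`.
   This slowly varying trace is the reference the MAD deviates from; its DC
   gain is exactly 1.
3. **Gait band.** A 2nd-order Butterworth low-pass at 12 Hz followed by a
   2nd-order Butterworth band-pass at 1.0–3.0 Hz, both written as
   difference equations with fixed-point rational coefficients (see
   `filter_coefficients()`). The band-pass numerator satisfies
   `a2 = 2 a1` exactly, making its DC gain identically zero.
4. **Step segmentation.** Positive zero crossings of the band-passed trace
   through +0.05 g, with hysteresis: after a boundary the detector re-arms
   only once the signal has fallen to −0.05 g. A step is the interval
   between consecutive boundaries.
5. **Features.** Per-step MAD `MAD_k = mean |r - R_LF|` over the step's
   samples (mg); floating MAD as the sample-weighted mean of two adjacent
   steps; signed dMAD between adjacent epochs; step frequency
   `f_s = 2 * sample_rate / (N_{k-1} + N_k)` (Hz). The conventional fixed
   6 s epoch MAD is computed alongside as the comparator.
6. **Prediction.** Linear equations
   `VO2 = b0 + b1 MAD (+ b2 |dMAD| + b3 exp(f_s))`, with four bundled
   coefficient sets (`bundled_model()`) and ordinary-least-squares
   refitting (`fit_vo2_model()`), validated with bias, SEE, R², MAPE and
   Bland–Altman limits of agreement (`agreement_stats()`).

## Fixed-point coefficients, initialisation and numerics

The filter coefficients are exact binary rationals (e.g. `16139/2^22`),
kept verbatim rather than re-derived from textbook Butterworth designs:
re-designing would change the last bits and with them every downstream
boundary index. Arithmetic is double precision; the rationals are evaluated
once.

Initialisation is the one place the difference equations are silent, and it
matters only for the 0.12 Hz baseline: with a pole that slow, a zero state
would take minutes to settle, so the baseline history is seeded with the
first resultant sample (the local gravity level). The 12 Hz and band-pass
stages settle within a second from zero state; the first second of the
band-passed trace is treated as warm-up and excluded from step detection
(`warmup_s` argument).

Tie-breaks are deterministic: a sample exactly at ±0.05 g counts as having
crossed; boundaries are the first sample at or above the rising threshold
coming from below; segments are half-open `[boundary, next boundary)`.

## Step plausibility bounds and bouts

The 1–3 Hz band implies credible step times of roughly 0.33–1 s; we accept
20–250 samples (0.2–2.5 s at 100 Hz) so that irregular but genuine steps
survive while stationary stretches cannot masquerade as one giant step. A
rejected segment splits the sequence into bouts, and floating epochs are
formed only within bouts, so "adjacent" steps never straddle a non-gait
gap. The first step of each bout yields no floating epoch (no predecessor)
and the first epoch of each bout has no dMAD.

## Epoch summaries and conventions

Stage- or test-level inputs to the prediction models are unweighted means
over all epochs fully inside the analysis window: mean MAD, mean |dMAD|
(the per-epoch value is stored signed; only summaries take the absolute
value, preserving information), and mean step frequency. Duration-weighted
means were considered and rejected as the default because the equations'
published coefficients are defined for plain means.

For the fixed 6 s epoch, the deviation reference defaults to the same
`|r - R_LF|` used by the per-step MAD, keeping the two epoch kinds
comparable sample by sample; the classical definition (deviation about the
epoch's own mean resultant) is available via
`fixed_epoch_mad(..., reference = "epoch_mean")`. On steady walking the two
references differ negligibly.

Validation R² is defined as the squared Pearson correlation between
measured and predicted values (not `1 − SSE/SST`), so that a model that is
merely mis-calibrated but perfectly correlated scores 1; training R² is the
usual `1 − SSE/SST`, and the two coincide on the training set. Training SEE
uses the residual degrees of freedom (`n − p − 1`); validation SEE is the
`n − 1` SD of the differences about the bias. Bias is
`mean(measured − predicted)`.

## The synthetic generator

No public raw-data deposit exists for hip-worn walking recordings paired
with VO2, so the package ships a generator (`gait_profile()`,
`simulate_recording()`) used by every end-to-end test. The vertical axis
carries 1 g of gravity, a fundamental sinusoid at the instantaneous step
frequency, a weaker (0.3×) second harmonic, and white noise (default SD
0.02 g per axis, a realistic MEMS-plus-soft-tissue floor); the horizontal
axes carry smaller phase-shifted components. Speed maps to frequency as
`1.4 + 0.4·v` Hz (clipped to the 1.2–3 Hz detection band) and to amplitude
as `0.25·v` g with a 0.08 g floor — monotone defaults chosen once as
plausible for adult walking, not physiological claims. Turns are transient
Gaussian amplitude bursts.

Two protocol-level wrappers emulate the study designs behind the bundled
equations: `simulate_cs_cohort()` (staged constant speeds from 0.6 m/s in
0.4 m/s increments, 2.5 min stages, per-stage VO2 from a known true model
applied to the stage's pipeline features plus Gaussian noise, default SD
1 mL/kg/min) and `simulate_acdc_cohort()` (trapezoidal lap profiles on a
15 m track with turn bursts, one VO2 per subject). Because the generating
VO2 uses the pipeline's own features, a noiseless cohort admits exact
coefficient recovery by OLS — the property the recovery tests assert.

Ground truth ships with each recording: per-stage true MAD (brute-force
mean absolute deviation of the noiseless resultant about its stage mean),
true |dMAD| (from per-cycle MADs at the generator's known phase
boundaries), and true step frequency — all computed without the filter
pipeline, so pipeline-vs-truth comparisons are genuinely two-route.

**What the generator does not emulate.** Real gait acceleration is
impulsive: heel-strike transients put more energy into the 1–3 Hz band per
mg of MAD than a sinusoid does. Two consequences follow. First, with the
printed band-pass (whose peak gain is ≈0.8 near 2.5 Hz, ≈0.6 at 1.7 Hz)
and the ±0.05 g hysteresis, sinusoidal gait below ≈0.10 g fundamental
amplitude (≈65 mg MAD) cannot be segmented into steps at all, so
`simulate_steady_cohort()` floors its amplitudes there; field data with
MAD near 50 mg evidently remains segmentable because of those impact
harmonics. Second, at high amplitude the resultant folds (the vertical
signal swings through zero), compressing realized MAD to ≈590 mg no matter
the amplitude; the steady cohort therefore spans ≈65–555 mg. Passing tests
on these signals demonstrate the pipeline's algebra, filters and detector —
not classification performance on free-living data.

## Problem sizes used by the test-suite and scripts

The default suite exercises recordings of 20–120 s and cohorts of 2–12
subjects; the steady-cohort comparison of fixed-vs-floating MAD uses 29
subjects × 2 min at 100 Hz, and regression recovery uses n = 50 (noiseless)
and n = 200 (noise SD 1 mL/kg/min). These sizes give stable statistics —
the fixed-vs-floating correlation is insensitive to cohort duration beyond
about a minute per subject — while keeping a full run in seconds.

## Known limitations

* The equations and detector are walking-specific: cycling, swimming or
  vehicle travel violate the 1–3 Hz gait-band assumption.
* Eq-level step frequency follows the two-step definition
  `2·sr/(N_{k-1}+N_k)` literally; on a pure sinusoid of frequency f it
  equals f. Published field values for the same quantity sit near half the
  cadence, suggesting a stride-level reading there; the implementation does
  not reinterpret.
* Negative VO2 predictions are possible outside the calibrated feature
  range; they are returned with a warning, never clamped.
* The bundled coefficient p-values marked "<0.001"/"<0.05" in their source
  are stored as their upper bounds.
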