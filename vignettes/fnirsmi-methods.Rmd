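---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fnirsmi)
```

This vignette documents the science and the engineering decisions behind
`fnirsmi`: the measurement model, the simulator that stands in for the
(unavailable) human recordings, the classifier and its model selection, and
the numerical conventions. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Measurement model

fNIRS measures near-infrared light intensity after transmission through
cortical tissue at two wavelengths (760 and 870 nm here). Oxy- and
deoxy-hemoglobin are the dominant absorbers, with distinguishable spectra,
so two wavelengths suffice to separate their concentration changes. The
modified Beer–Lambert law (MBLL) linearizes absorption around a reference
state: the absorbance change at wavelength $\lambda$,

$$\Delta A(\lambda, t) = \log_{10} \frac{I_{\mathrm{ref}}(\lambda)}{I(\lambda, t)}
 = \big(\varepsilon_{O_2Hb}(\lambda)\,\Delta[O_2Hb](t) +
        \varepsilon_{HHb}(\lambda)\,\Delta[HHb](t)\big)\, d \cdot \mathrm{DPF}(\lambda),$$

is a linear 2×2 system in the two concentration changes, given the specific
extinction coefficients $\varepsilon$, the source–detector distance
$d$ = 12.5 mm, and the differential pathlength factor DPF (6.75 at 760 nm,
6.50 at 870 nm) that converts geometric to effective optical path length.
Concentrations are reported in µmol/l *relative to the reference state*;
they are changes, not absolute levels.

**Reference intensity.** The package defaults to the per-channel,
per-wavelength mean intensity over the opening rest phase
(`ref = "first_rest"`), because all downstream quantities are changes
relative to rest; the whole-recording mean (`ref = "whole"`) and an
explicit numeric reference are selectable. The explicit reference makes the
forward optics exactly invertible, which the roundtrip tests exploit
(≤ 1e−9 µmol/l on random configurations). With `"first_rest"`, drift and
oscillations present during the opening rest shift the recovered series by
a constant — harmless for stimulation−rest differences.

**Extinction coefficients** ship as an editable CSV
(`inst/extdata/extinction_coefficients.csv`, 1/cm per mol/l); no analysis
result depends on the specific values, only on forward/inverse consistency,
and the roundtrip tests perturb them randomly.

## 2. The acquisition chain

The emulated instrument samples at 100 Hz and its processing chain is:
ambient-light subtraction, a 7th-order Chebyshev low-pass with 20 dB
attenuation from 5 Hz, decimation to 10 Hz (plain sample picking — the
specified filter *is* the anti-alias stage), MBLL, and removal of the
linear drift by ordinary least squares over the full recording.

Decisions where the chain description is underdetermined:

* **Chebyshev type.** "20 dB attenuation at 5 Hz" is a stopband
  specification, which fits type II (monotone passband, equiripple
  stopband); type I is selectable. The implemented design matches the
  standard reference implementation (verified against
  `scipy.signal.cheby2` during development; the shipped tests pin the
  frequency-response contract: unity DC gain within 1e−6, ≥ 20 dB from
  5 Hz to Nyquist).
* **Causality.** Filtering is single-pass causal by default (an acquisition
  chain runs forward in time); `zero_phase = TRUE` applies it
  forward–reverse. The causal pass delays the signal by ≈ 0.06 s at
  hemodynamic frequencies, which alone contributes ≈ 2% error on the
  steepest response slopes; the recovery tests assert 2% fidelity for the
  zero-phase path and 3% for the causal default.
* **Startup transient.** The filter is initialized at its DC steady state
  by pre-padding each trace with 5 s of its first value. Without this, the
  zero-state transient corrupts the opening rest phase — the baseline of
  trial 1 — and biases group means by ≈ 10%.
* **Stopband edge vs decimated Nyquist.** The chain places the 5 Hz edge
  exactly at the 10 Hz stream's Nyquist frequency; the package warns only
  when the edge lies *above* it.

## 3. The synthetic world

The generator emulates the published protocol: 12 trials per condition,
15 s stimulation alternating with 20 s rest (24 trials, 14 min), 3
channels, seeded random condition interleaving with exact per-condition
counts.

**Response model.** Each trial contributes a 15 s boxcar convolved with a
gamma-density kernel, normalized so the single-trial response has unit
peak, then scaled by the condition/channel amplitude. The kernel defaults
to 6 s peak latency (the canonical hemodynamic delay) and ≈ 5 s FWHM; both
are configuration, not constants, and kernels whose support exceeds one
35 s trial cycle are rejected unless overlap is explicitly allowed. An
optional extra 2 s onset delay emulates the slower rise reported for
imagined versus executed movement (off by default).

**Amplitude semantics.** `amp_mode = "stim_rest_mean"` (default): an
amplitude is the *expected stimulation−rest mean difference recovered by
the standard chain* — the quantity group tables report. This requires
calibration, because three effects make the recovered difference smaller
than the response peak: the response ramps over ~6 s of the 15 s window;
the response tail (≈ 34% of peak averaged over the following 20 s rest)
elevates the next trial's baseline; and the causal filter plus 10 Hz
window means shave a further ~4%. The generator therefore computes, for
the actual seeded event sequence, the per-condition unit responses as seen
through the default chain, and solves the resulting 2×2 linear system so
the configured values come out in expectation. Per-trial amplitude
deviations are scaled by the analogous factor
$1/\sqrt{s_{\mathrm{stim}}^2 + s_{\mathrm{tail}}^2}$ so `trial_amp_sd` is
the SD of the recovered per-trial difference. `amp_mode = "peak"` bypasses
all of this (amplitude = response peak).

**Default amplitudes and noise** are the published group values for this
paradigm, and where the source states no value a single choice was made
and kept:

| parameter | default | rationale |
|---|---|---|
| Δ[O₂Hb] amplitudes | simple 0.101/0.054/0.038, complex 0.192/0.095/0.065 µmol/l per channel | published per-channel group means |
| Δ[HHb] amplitudes | ≈ −0.01 µmol/l, condition-specific | published; an order of magnitude smaller, negative |
| `trial_amp_sd` | 0.08 µmol/l | makes per-trial SNR (mean/SD of stim−rest differences) land near the published ≈ 0.9–1.5 |
| `subject_amp_cv` | 0.33 | overall-channels complex SE 0.011 × √12 / 0.118; a single multiplicative subject factor |
| `drift_slope` | 0.05 µmol/l per minute | typical slow instrumental/physiological drift; fully removed by detrending |
| `osc_components` | 0.1 Hz @ 0.02, 1 Hz @ 0.01 µmol/l | Mayer-wave-like and cardiac-like confounds, random phase per channel; exercise the low-pass and windowed means |
| `white_noise_sd` | 0.05 µmol/l per raw sample | broadband measurement noise; mostly removed by the 5 Hz low-pass and window averaging |

**What the generator does not model** (and hence what a green test does
not establish): motion artifacts, optode-coupling changes, superficial
(scalp) hemodynamics, serially correlated physiological noise beyond pure
sinusoids, non-canonical or condition-dependent response shapes, and any
EMG channel. Recovery and calibration results on this synthetic world
verify the *pipeline*, not the physiology.

## 4. Trial statistics

Epochs pair each 15 s stimulation segment with the *immediately preceding*
20 s rest (the design opens with rest, so every trial has one); windows are
half-open in time, `[onset − 20, onset)` and `[onset, onset + 15)`, so
sample counts are exact at any rate. The paired t-test is the classical
one (df = n − 1, two-sided); zero-variance differences yield an explicit
degenerate flag rather than an infinite statistic. SNR is the mean over
the sample SD (n − 1 denominator throughout) of the per-trial
stimulation−rest differences; the averaging domain of the published SNR
values is not recoverable from their definition, so a within-epoch
time-domain variant is selectable and neither is asserted to reproduce the
printed numbers. Channel exclusion uses α = 0.005, subject exclusion
α = 0.05 (a subject is dropped only when *all* channels are non-significant
in task and control runs); under this rule a truly null subject is excluded
with probability 0.95⁶ ≈ 73%, not ≈ 100% — six chances of a false positive
keep it in.

## 5. Features and classifier

Features are computed on the baseline-corrected Δ[O₂Hb] stimulation trace
restricted to a window from the 93-element grid (integer starts 1–11 s,
ends 5–15 s, end > start; zero-length windows are meaningless for variance
and are excluded). Conventions, pinned by oracle tests: arithmetic mean;
unbiased (n−1) variance; adjusted Fisher–Pearson skewness; bias-adjusted
*excess* kurtosis (normal → 0). Whether the original analysis used raw or
excess kurtosis is unknowable from the text; excess is the default and the
choice is configurable. Zero within-window spread flags skewness/kurtosis
undefined while mean/variance remain valid; combinations touching undefined
features are skipped and logged by the search.

Fisher's discriminant is built from scratch:
$w = (S_w + \lambda I)^{-1}(m_a - m_b)$ with $S_w$ the summed within-class
scatter, threshold at the midpoint of the projected class means (equal
priors — the design is balanced 12 v 12), ridge default 1e−8 as a purely
numerical guard. No feature standardization is applied: FLDA is
affine-equivariant, so standardization cannot change classifications beyond
round-off (tested). Accuracy is leave-one-out cross-validation over the 24
trials — every published accuracy is an exact multiple of 1/24, which LOOCV
produces naturally; the fold scheme is a package default, not a claim about
the original analysis. Ties among the 4185 combinations are broken toward
the simplest model: fewer features, then shorter window, then earlier
start, then lower channel.

The best-of-4185 accuracy is optimistically biased (selection bias); the
package reports it as the original analysis did, and the tests *quantify*
the bias on null data (best ≫ 0.5 while the median combination is at
chance) rather than correcting it — nested cross-validation is out of
scope.

The search runs through a compiled RcppArmadillo kernel with semantics
identical to the R reference path (`loocv_accuracy` over `flda_fit`);
equality of the two routes is asserted in the tests, and the R path is
additionally checked label-for-label against an independent reference
discriminant.

## 6. Group reports

`aggregate_results` computes mean, sample SD, range, channel/feature
selection counts and interval lengths from per-subject records; applied to
the packaged transcription of the published per-subject table it reproduces
every printed summary exactly after one-decimal rounding (the acceptance
suite pins this). Feature–accuracy correlations are two-tailed Pearson with
the t-transform p-value (df = n − 2), computed over the subjects whose
optimal set includes the feature, matching the published figure's
convention; an all-subjects variant is a flag away. One printed
inconsistency is resolved by using the count and ignoring the percentage
(a "6 (12%)" of 12 subjects cannot both hold).

## 7. Known limitations

* The headline human accuracies are not reproducible — the recordings were
  never deposited. The acceptance evidence is therefore: exact reproduction
  of the printed summaries from the packaged table, parameter recovery and
  calibration on the synthetic world, and oracle equivalence of the
  numerical cores.
* Amplitude calibration assumes the default causal chain; analyzing with
  `zero_phase = TRUE` recovers amplitudes ≈ 2% above the configured values.
* The simulator's per-trial amplitude deviations are Gaussian and may be
  negative (inverted responses occur in real data); per-subject scaling is
  truncated at zero.
* `replay_processing` reproduces logged runs bit-identically only because
  every preprocessing step is deterministic; the simulator's determinism is
  instead guaranteed by seeding.
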