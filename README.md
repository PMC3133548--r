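# fnirsmi

Single-trial classification of simple versus complex motor imagery from
dual-wavelength functional near-infrared spectroscopy (fNIRS) recordings —
an offline analysis pipeline plus a forward-model simulator that makes every
stage testable without human data.

## The problem

In a block-design experiment, a subject alternates 20 s rest phases with
15 s phases of either *simple* motor imagery (imagined single-finger
tapping) or *complex* motor imagery (imagined five-finger sequences), 12
trials per condition (24 trials, 14 min). A three-channel optical sensor
over secondary motor cortex records light intensity at 760 and 870 nm at
100 Hz. The scientific questions: do the two imagery conditions produce
distinguishable cortical oxygenation responses, and can single trials be
classified — the building block of an fNIRS brain–computer interface?

## What the package computes

**Preprocessing** (`subtract_ambient`, `lowpass_decimate`, `mbll`,
`detrend_linear`, or the `preprocess` chain). Ambient light is subtracted,
intensities are low-pass filtered (7th-order Chebyshev type II, 20 dB
attenuation from 5 Hz) and decimated to 10 Hz, and the modified
Beer–Lambert law converts the two-wavelength absorbance changes

&nbsp;&nbsp;ΔA(λ, t) = log₁₀ I_ref(λ) / I(λ, t) = (ε_O₂Hb(λ) Δ[O₂Hb] + ε_HHb(λ) Δ[HHb]) · d · DPF(λ)

into oxy-/deoxy-hemoglobin concentration changes in µmol/l (source–detector
distance d = 12.5 mm, differential pathlength factors 6.75 / 6.50). The
linear drift is then removed.

**Trial statistics** (`epoch`, `channel_stats`, `paired_ttest`, `snr`,
`apply_exclusions`). Each trial's 15 s stimulation segment is baseline
corrected against its preceding 20 s rest; stimulation/rest means feed
paired t-tests, SNR (mean over SD of per-trial differences), and the
channel/subject exclusion rules.

**Classification** (`extract_features`, `enumerate_windows`, `flda_fit`,
`loocv_accuracy`, `exhaustive_search`). Four statistical moments (mean,
variance, skewness, excess kurtosis) of the baseline-corrected Δ[O₂Hb]
trace are computed over 93 candidate analysis windows (starts 1–11 s, ends
5–15 s). A from-scratch Fisher linear discriminant,
w = (S_w + λI)⁻¹(m_a − m_b) with the threshold midway between projected
class means, is scored by leave-one-out cross-validation for every of the
3 × 93 × 15 = 4185 channel × window × feature-subset combinations; the
best-performing combination is reported per subject.

**Reporting** (`aggregate_results`, `feature_accuracy_correlation`,
`keystroke_error_rate`). Group-level summaries of per-subject results and
Pearson feature–accuracy correlations. The published per-subject results
table is packaged (`load_table2()`) and aggregating it reproduces the
printed group statistics exactly.

**Simulation** (`generator_config`, `simulate_subject`, `simulate_study`).
A forward model generates raw intensity recordings with known ground truth:
gamma-kernel hemodynamic responses (6 s peak latency, ~5 s FWHM) with
condition/channel-specific amplitudes, per-trial and per-subject
variability, linear drift, Mayer-wave-like (0.1 Hz) and cardiac-like (1 Hz)
oscillations, white measurement noise, and the exact inverse optics of the
MBLL — so preprocessing can be verified to machine precision and the
statistics/classifier to their sampling distributions.

## Worked example

```r
library(fnirsmi)

cfg  <- generator_config(seed = 42)      # the published protocol + Table-1-scale amplitudes
sim  <- simulate_subject(cfg)            # raw dual-wavelength intensities
hemo <- preprocess(sim$raw)              # ambient -> filter/decimate -> MBLL -> detrend
ep   <- epoch(hemo)                      # 24 trials x 3 channels

subset(channel_stats(ep), chromophore == "o2hb" & channel == 1)
#>   channel  condition chromophore stim_mean rest_mean mean_diff    t        p df   snr
#> 1       1  MI-simple        o2hb   0.00259   -0.0521    0.0547 1.73 1.11e-01 11 0.501
#> 2       1 MI-complex        o2hb   0.16074   -0.0703    0.2311 7.79 8.42e-06 11 2.248

exhaustive_search(ep)
#> <search_result> best: channel 1, 7-10 s, {variance}: accuracy 91.7% (22/24; 18 tied)

aggregate_results(load_table2())
#> <group_report> 12 subjects: accuracy 81.3 +/- 7.0% (range 70.8% - 91.7%)
#>   channels:  ch1 = 2, ch2 = 4, ch3 = 6
#>   features:  mean = 8, variance = 10, skewness = 6, kurtosis = 5
```

Reading the output: for this simulated subject, channel 1 shows a clear
complex-imagery oxygenation response (stim−rest difference 0.23 µmol/l,
p ≈ 10⁻⁵) and a weak simple-imagery response, and the exhaustive search
classifies the two conditions at 22/24 = 91.7% leave-one-out accuracy from
the Δ[O₂Hb] variance in the 7–10 s window. The group report reproduces the
published per-subject summary: 81.3 ± 7.0% mean accuracy, variance selected
by 10 of 12 subjects, channel 3 by 6 of 12. Note the best-of-4185 accuracy
is optimistically biased — on null data the best combination still scores
well above 50% even though the median combination is at chance; the tests
quantify this.

## Command line

```sh
Rscript inst/cli/fnirsmi.R simulate   --seed 1 --out data/ --subjects 3
Rscript inst/cli/fnirsmi.R preprocess --data data/subject01_intensity.csv --events data/subject01_events.csv --out hemo.csv
Rscript inst/cli/fnirsmi.R classify   --data data/subject01_intensity.csv --events data/subject01_events.csv --out result.json
Rscript inst/cli/fnirsmi.R report     --out report.json
```

See `vignettes/fnirsmi-methods.Rmd` for the model, parameter choices,
numerical decisions, and the limits of what the synthetic tests establish.
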