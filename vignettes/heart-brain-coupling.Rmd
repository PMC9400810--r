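---
title: "Methods: heart-brain coupling from simultaneous EEG and ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart-brain coupling from simultaneous EEG and ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis

`cardiocortex` implements a resting-state heart-brain coupling pipeline for
simultaneous multichannel EEG (19-channel 10/20 montage) and single-lead ECG
sampled at 256 Hz. The scientific question it serves: do across-subject
differences in vagally mediated heart rate variability (HRV) co-vary with the
power of cortical oscillations, and does the cortex respond to each
heartbeat (heartbeat-evoked potentials, HEP)? The pipeline was designed for
two-group comparisons — e.g. a patient group against controls — at the small
sample sizes typical of clinical neurophysiology (on the order of 11 + 7
subjects).

Stages, in dependency order:

1. **R-peak detection** (`detect_r_peaks`): a Pan-Tompkins-style chain —
   zero-phase 5-15 Hz band-pass, five-point derivative, squaring, 150 ms
   moving-window integration, adaptive dual-threshold picking with a 200 ms
   refractory period and search-back. Each integrator detection is snapped
   to the QRS-band energy maximum within ±150 ms and then refined to the
   raw-trace extremum (absolute deviation from the trace median) within
   ±50 ms, which makes the detector invariant to lead polarity and to
   positive rescaling.
2. **NN series** (`to_nn_series`): successive R-R differences in ms;
   intervals outside (300, 2000) ms or deviating more than 20% from the
   running median of the previous five accepted intervals are excluded and
   counted (`n_rejected`). No interpolation for time-domain metrics.
3. **HRV** (`hrv_summary`): SDNN (sample SD, denominator N−1), RMSSD, SD1
   (Poincaré rotated-axis RMS about the identity line; algebraically equal
   to RMSSD/√2, and cross-checked at run time), and absolute HF power —
   cubic-spline resampling of the tachogram to 4 Hz, linear detrend, Welch
   periodogram (Hamming, 256-point segments, 50% overlap), integrated over
   0.15-0.40 Hz, in ms².
4. **EEG band power** (`preprocess_eeg`, `band_roi_power`): zero-phase
   4th-order Butterworth band-pass 0.5-100 Hz, zero-phase 50 Hz notch
   (Q = 30), re-reference to linked mastoids when A1/A2 (M1/M2) are present,
   else to the common average with a logged downgrade. Welch PSD per channel
   (Hamming, 4-s segments, 0% overlap), mean density per band — delta
   [1,4), theta [4,8), alpha1 [8,10), alpha2 [10,13), beta [13,31) Hz —
   in dB (10·log10 of µV²/Hz), averaged over (ROI, hemisphere) cells:
   F_L{Fp1,F3,F7}, F_R{Fp2,F4,F8}, C_L{C3}, C_R{C4}, T_L{T3,T5},
   T_R{T4,T6}, P_L{P3}, P_R{P4}, O_L{O1}, O_R{O2}.
5. **HEP** (`epoch_heartbeats`, `average_hep`, `compare_groups_hep`):
   zero-phase 15 Hz low-pass on the continuous EEG, epochs at [−200, 600) ms
   around each R peak, trials with any |sample| > 100 µV rejected, per-subject
   trial average (optional cap on trial count; optional baseline, default
   off). Group statistics: per channel and per sample inside the 350-600 ms
   window of interest, a two-group one-way ANOVA on per-subject HEP
   amplitude; sample-wise p-values Bonferroni-corrected by the number of
   tested samples per channel; corrected-significant samples merged into
   maximal contiguous windows; windows shorter than 20 ms discarded.
6. **Coupling battery** (`spearman_correlogram`, `group_compare`,
   `best_subset_regression`): per group, Spearman correlations between every
   band × ROI-cell power and every HRV parameter, with exact permutation
   p-values for n ≤ 9 (untied) and the t approximation otherwise, and a
   reporting filter |ρ| ≥ 0.5 ∧ p < 0.05; two-group one-way ANOVAs with
   Bonferroni correction within declared families (4 HRV variables; the
   band × ROI family for EEG); and, per band and hemisphere, exhaustive
   best-subset ordinary least squares HRV ≈ αF + βC + δP + εT + φO
   (intercept included, QR solve), selecting the subset with maximal
   adjusted R², ties broken toward fewer predictors and then the order
   F < C < P < T < O, with coefficient standard errors, Pearson residuals
   (raw residuals / √(SSE/(n−k−1))) and a Shapiro-Wilk normality flag at 5%.

## The synthetic cohort: what it emulates

No public recordings accompany the study design this pipeline targets, so
validation rests on a generative model (`cohort_spec`, `generate_cohort`)
whose defaults are the stated acquisition conditions: 10-min recordings at
256 Hz, 19 EEG channels + 1 ECG channel per subject, cohort sizes 11
("RE-like") and 7 ("control-like").

A single latent scalar per subject — "vagal tone", a standard normal draw —
drives both sides of the coupling. This is the simplest structure able to
produce the qualitative contrast the pipeline must detect: positive
power-HRV correlations in one group, negative in the other.

* **RR series**: RR(k) = 850 ms + 30·sin(2π·0.10·t) + depth·sin(2π·0.25·t)
  + N(0, 5 ms), with depth = max(0, 40 + 15·tone) ms. The 0.10 Hz term
  stands in for baroreflex (LF) rhythm, the 0.25 Hz term for
  respiratory-gated (HF) modulation; the modulators are evaluated at the
  predicted beat time t_{k−1} + 850 ms (the exact terminating time is
  implicit in RR(k) itself, and the phase error this introduces is
  negligible against the modulation periods). Amplitudes are typical
  resting adult values; the tone gain of 15 ms/unit puts RMSSD in the
  30-70 ms range across ±2 SD of tone.
* **ECG**: a fixed sum-of-Gaussians PQRST template (R = 1 mV, the per-beat
  global maximum) at each beat time, plus 0.15 Hz baseline wander (0.05 mV)
  and white noise (0.02 mV). No beat-to-beat morphology variation — only R
  timing and bleed amplitude matter downstream.
* **EEG**: per channel, a sum over the five bands of band-shaped noise.
  Band shaping is spectral (squared Butterworth magnitude — the response
  zero-phase filtering would apply), and each band trace is *closed-loop
  calibrated*: its Welch band density (computed exactly as the band-power
  module computes it) is scaled to hit base + slope·tone dB. Calibrating
  against the pipeline's own estimator rather than an analytic filter-gain
  formula makes the round trip robust to filter-design details. Baseline
  band powers (15, 12, 12, 10, 6 dB re µV²/Hz for delta…beta) approximate a
  resting adult spectrum; coupling slopes default to +2 dB/unit-tone in the
  RE-like group and −2 in the control-like group, on all bands.
* **Heartbeat-evoked component**: a half-sine of `hep_amp_uV` (5 µV RE-like,
  2 µV control-like) at 400-500 ms after each R peak, spread over the scalp
  with a fixed dipolar topography — fronto-central maximum (weight 1),
  posterior inversion, re-centred to exactly zero mean. The zero-mean
  constraint is what a single tangential source looks like under an average
  reference; without it, common-average re-referencing would cancel a
  spatially uniform component entirely (we learned this the hard way: an
  early uniform injection vanished from every re-referenced average).
* **Cardiac-field artifact**: `cfa_gain` (2 µV/mV) times the ECG trace added
  to every channel, emulating volume-conducted contamination of early
  post-R latencies — the reason the HEP window of interest starts at 350 ms.
* **Sensor noise**: white, 10 µV SD.

Determinism: the cohort seed draws one sub-seed per subject; regenerating
with the same spec is byte-identical (EDF headers carry fixed date fields),
independent of the output directory.

What the generator does **not** emulate — and hence what a green test does
not establish: 1/f background shape beyond band-limited noise, EEG
microstates and nonstationarity, true respiratory sinus arrhythmia
physiology (the HF modulation is a fixed-frequency tone), ectopic beats and
artifacts of clinical recordings, and any nonlinear or directed coupling.
Recovery of the planted linear coupling says the estimators work, not that
real heart-brain coupling has this structure.

## Numerical choices and conventions

* **Epoch window**: sample offsets are `round(−0.2·fs)` to
  `round(0.6·fs) − 1`, i.e. a half-open [−200, 600) ms window (205 samples
  at 256 Hz, R peak at offset 0). Indexing is 0-based in all documented
  sample arithmetic; R's internal 1-based indices are an implementation
  detail.
* **Welch details**: Hamming windows; density scaling corrected for window
  power; segment means removed; one-sided spectra with DC/Nyquist not
  doubled. EEG: 4-s segments, 0% overlap. HRV tachogram: 256-point segments
  at 4 Hz (64 s), shortened to the record when the record is shorter
  (the shortest admissible record, 60 s, is below one nominal segment).
* **dB-domain ROI averaging** is the default (configurable to
  linear-then-dB); dB differences and rank correlations are invariant to
  the power unit, so the µV²/Hz convention is immaterial downstream.
* **Alpha peak frequency** (`alpha_peak_frequency`): maximum of the
  posterior mean PSD in 7-13 Hz, refined by local quadratic interpolation.
  A peak is reported only when it sits off the range boundary **and** rises
  ≥ 2 dB above the in-range median density. The prominence rule exists
  because a boundary check alone cannot distinguish a flat (white) spectrum
  from a genuine alpha peak; 2 dB is several times the Welch estimation
  ripple at the default 10-min record length.
* **Spearman p-values**: full permutation enumeration up to n = 9 (the
  n = 7 control group makes exact logic necessary — printed values like
  ρ = −1, p ≈ 0 are only reachable that way); the null distributions are
  cached per n. Ties or larger n fall back to the t approximation.
* **Best-subset search** is exhaustive over all 31 non-empty predictor
  subsets (trivially cheap at k = 5) rather than stepwise removal, which
  can miss the adjusted-R²-optimal subset. Subsets with no residual degree
  of freedom are skipped; a fit with exactly one residual df is flagged
  `saturated` (the n = 7 full-model case). Rank-deficient subsets are
  skipped with a log entry.
* **Filtering**: Butterworth designs via analog prototype + bilinear
  transform (validated coefficient-for-coefficient against a reference DSP
  implementation); zero-phase application by forward-backward filtering
  with odd-reflection padding (4 s of padding for the 0.5 Hz edge, whose
  slowest pole decays e-fold per ~0.3 s). The "4th-order band-pass" is an
  order-4 filter (order-2 prototype).
* **Config serialization** uses JSON (`jsonlite`), the structured-text
  format available in the dependency budget; named numeric fields are
  listified on write so names survive the round trip.
* **EDF**: a minimal 16-bit EDF writer/reader lives in the package (no EDF
  package is assumed); physical ranges span the observed per-channel
  amplitude, so quantization error is ≤ range/65534.

## Open design points, resolved

* **Eyes-open vs full-record analysis**: the generator is stationary, so
  segment choice cannot change any synthetic result; the pipeline exposes
  `segment` in `run_config` (default full record) for real data where it
  might matter.
* **HEP baseline correction** defaults to off: the pre-R interval carries
  the cardiac field of the preceding P/Q complex, and subtracting it moves
  cardiac artifact into the window of interest. A flag enables it.
* **Statistical unit for HEP comparisons** is the per-subject average (not
  pooled trials): amplitude differences between groups of subjects must be
  tested against between-subject variability.
* **Bonferroni families**: per-channel across window-of-interest samples
  for HEP (channels are reported descriptively); 4 tests for the HRV
  family; band × ROI cells for the EEG family. Family sizes are arguments,
  and the correlogram itself is deliberately *not* corrected for its 200
  cells — it is reported with the |ρ| ≥ 0.5 ∧ p < 0.05 descriptive filter,
  mirroring common practice in this literature; treat passing cells as
  descriptive, not confirmatory.
* **HF in short test records**: HF needs ≥ 60 s of beats; scaled-down tests
  that only exercise time-domain coupling skip HF (`compute_hf = FALSE`)
  rather than silently extrapolating.

## What the tests establish, and at what scale

The acceptance battery (`tests/testthat/test-acceptance.R`) is
property-based: metric oracles to 1e-9; HF calibration on pure tones
(Parseval); detector F1 ≥ 0.99 at power-based 10 dB SNR; ±1 dB band-power
round trips at zero noise; HEP amplitude recovery within the √N averaging
law, ≥ 80% group-window detection power at n = (11, 7) and ≤ 6%
permutation-null type-I rate; ≥ 90% coupling-sign recovery at ±2
dB/unit-tone over 200 replicates; regression/selection oracles and a 4-7%
Shapiro-Wilk null rejection band; algebraic identities (Spearman rank
formula, F = t²); and bit-identical end-to-end reruns.

To stay inside a CI time budget, simulations whose property is
scale-invariant run on shortened recordings: the coupling-sign replicates
use 24-s records (less data only *adds* estimation noise, making sign
recovery harder, not easier), the HEP power/type-I simulations use
single-channel 60-s subjects through the real epoching/averaging/ANOVA
code path, and the determinism check uses a 5+5 cohort at 64 s. The
full-scale default run (18 subjects, 10 min, 19 channels) was executed
during development: it completes in ≈ 3.3 min on one CPU — within the
15-min budget — recovers the planted coupling signs in every correlogram
cell, and detects HEP group-difference windows overlapping the injected
400-500 ms latency on all channels.

```{r}
library(cardiocortex)
spec <- cohort_spec(seed = 7)                      # the full default cohort
report <- run_pipeline(run_config(spec, "run", seed = 7))
head(report$hep_windows)
subset(report$correlograms$re_like, passes_report_filter)
```

## Known limitations

Amplitude-threshold artifact flagging replaces ICA/visual cleaning (the
irreproducible manual step); the detector is single-lead with no beat
classification; the HEP statistics are sample-wise ANOVA + Bonferroni, not
cluster-based permutation; the correlogram carries no familywise control by
design; and all validation is against the generator's linear,
single-latent-factor world.
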