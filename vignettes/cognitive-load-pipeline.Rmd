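---
title: "Methods: infra-slow alpha fluctuations and the cognitive-load pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infra-slow alpha fluctuations and the cognitive-load pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogload)
```

## The problem and the model

Cognitive load — the momentary demand a task places on working memory — is
classically manipulated with n-back tasks and read out behaviorally
(accuracy, reaction time). `cogload` implements a multi-modal feature
pipeline around one central EEG quantity: the **infra-slow fluctuations of
alpha power**, a ratio measure of how much of the rhythmic variation of
frontal alpha band power lives at periods of 64–128 s.

The chain for one 6-min task recording (6 frontal channels, 256 Hz) is:

1. **Preprocessing.** Per-channel offset removal, then a linear-phase FIR
   bandpass (4–30 Hz, order 424, Hamming-windowed sinc at 256 Hz). The even
   order makes the group delay exactly 212 samples, which `bandpass()`
   removes by shifting, so all downstream window timestamps stay aligned to
   the task clock. The first/last 212 samples carry edge transients; at
   0.83 s against 20-s analysis windows these are negligible, which is why a
   single delay-compensated pass is the default (a forward–backward variant
   is not needed for magnitude-only features).
2. **First-order band-power series.** Welch spectra of sliding 20-s windows
   advanced by 1 s, each window averaging twenty 1-s Hann-tapered,
   non-overlapping segments (1-Hz resolution). Alpha (8–13 Hz) and theta
   (4–7 Hz) power are normalized by total 4–30 Hz power, giving a unitless
   fraction per second per channel. A 300-s usable recording yields 281
   samples per channel. Values are stamped at the window start.
3. **Infra-slow index.** Per channel, the fluctuation spectrum of the alpha
   series (Welch, single 256-sample Hann segment, linear detrend,
   zero-padded to 512 for a 1/512-Hz grid) is integrated over periods
   64–128 s and divided by the integral over periods 5–128 s; the six
   channel ratios are averaged. Because the numerator band nests in the
   denominator, the index lies in [0, 1].
4. **Second-order series.** Sliding 130-s windows of the first-order series
   reduced to integrated fluctuation power at periods 40–90 s. Together
   with the first-order series this forms the 24-dimensional
   (2 orders × 2 bands × 6 channels) per-second feature of the arousal
   classifier.

Autonomic and behavioral indices complete the participant summary: RMSSD of
artifact-screened inter-beat intervals from PPG pulse detection, SCR counts
from trough-to-peak EDA deflections, n-back accuracy, mean RT, RT
interquartile range (type-7 quantiles), and the mean RT power spectral
density below 0.05 Hz. The statistics layer compares conditions by paired
t-test (after a Kolmogorov–Smirnov normality screen) with effect size
r = |z|/√N, correlates difference scores (three-back minus zero-back) by
Pearson correlation, and corrects families with Benjamini–Hochberg.

## Numerical choices

* **Band integration** uses the trapezoidal rule with linear interpolation
  at band edges. Under this rule a flat spectrum integrates to
  level × bandwidth, so the alpha fraction of a flat spectrum is exactly
  (13−8)/(30−4) = 0.1923 and the infra-slow index of a white-noise power
  series converges to (1/64−1/128)/(1/5−1/128) = 0.0407 — both serve as
  analytic anchors in the test suite. Summing whole bins would instead give
  resolution-dependent values (e.g. 6/27 = 0.222 at 1-Hz resolution).
* **Tapers.** Hann for all averaged periodograms (rectangular available via
  the `window` argument). Periodograms are scaled as one-sided densities;
  all downstream features are ratios or band integrals, so the absolute
  scale cancels.
* **Detrending.** The fluctuation spectrum linearly detrends its segment,
  so the index ignores the mean alpha level and linear drift — "fluctuation"
  deliberately excludes the mean, which the pipeline carries separately and
  which by itself is known to be an insensitive load index.
* **The 0-Hz bin** never enters a band integral (all period bands have
  finite upper period), making the index invariant to constant offsets.
* **Zero-power windows** produce `NA` band fractions, propagated rather
  than silently coerced; `infraslow_index()` interpolates isolated `NA`s.
* **Degenerate statistics inputs** are explicit: identical pairs give
  t = 0, p = 1; a constant non-zero paired difference is an error;
  zero-variance feature dimensions are flagged and zeroed by
  `z_normalize()`; effect sizes are capped at 1 with a warning.
* **Resolution warning.** A 300-s series holds barely two cycles of the
  128-s period. The numerator band of the index then rests on roughly two
  Rayleigh-resolution bins (about 4 degrees of freedom), so per-session
  index estimates at shallow modulation have a standard deviation of about
  0.09 even after 6-channel averaging. `infraslow_index()` warns when fewer
  than two full cycles of the longest period fit the series. This is an
  inherent limit of the construct at 6-min tasks, and it bounds how well
  cohort-level associations can be recovered (below).

## The synthetic-data generators

No recordings ship with the package; seeded generators emulate the protocol
conditions so that every stage is testable against known ground truth.

* `synth_eeg()`: six channels of 1/f background (RMS 14), a 4–7 Hz theta
  process (RMS 5) and an 8–13 Hz alpha process (RMS 5) whose envelope is
  `1 + depth·sin(2πt/period)` with a shared random phase across channels.
  The alpha/background ratio puts the mean normalized alpha fraction near
  0.3–0.4, typical of frontal task EEG; modulation is multiplicative on the
  alpha component only, matching the construct being measured. With these
  amplitudes the index responds over its full range without saturating at
  the leakage ceiling (~0.92) below depth 0.75.
* `synth_ppg()`: smooth two-bump pulse templates at sinusoidally modulated
  inter-beat intervals (RSA surrogate), with interval jitter and additive
  noise; true beat times are returned, enabling closed-form RMSSD checks
  (sinusoidal interval modulation of amplitude a at beat-frequency f gives
  RMSSD = a·√2·|sin(πf·T̄)|).
* `synth_eda()`: tonic level, slow drift, and difference-of-exponential SCR
  transients (~2-s rise) at known onsets.
* `synth_behavior()`: uniform digits at a 3-s ISI, responses correct with a
  set probability, RTs = base + slow sinusoidal drift + white noise.
* `synth_cohort()`: a latent bivariate-normal pair per participant
  (correlation `trait_rho`, Gaussian copula) drives the three-back
  modulation depth (uniformly over [0.1, 0.45], the responsive region of
  the index) and the three-back true accuracy (uniformly over
  [0.6, 0.95]); zero-back depth is fixed at 0.1. Three-back sessions have
  slower, more variable and more slowly drifting RTs and more SCRs,
  mirroring the direction of load effects.

What the generators do **not** emulate: volume-conducted channel
correlations (synthetic channels are independent, which makes channel
averaging slightly *more* effective than in real EEG), eye-blink and EMG
artifacts, non-stationary alpha peak frequency, and arrhythmic (scale-free)
infra-slow activity. Passing tests therefore demonstrate correctness of the
computations and recoverability of rhythmic structure, not field
performance on wearable recordings.

## Simulation scales and what they show

The acceptance-style checks run at fixed sizes chosen to keep the full
suite in the minutes range: 200 replicates for the white-noise index
anchor, 50 paired seeds for in-band/out-of-band discriminability and for
depth monotonicity, eight 2-min PPG sessions at 10 dB SNR, 1,000 sequences
for the scorer/BH oracles, 10,000 null replicates for correlation
calibration, and 12 cohorts of n = 40 (EEG + behavior) for end-to-end
recovery of a trait correlation of 0.7.

On that last point the pipeline is honest rather than flattering: with the
index measurement noise dictated by 300-s sessions (see the resolution note
above), the measured difference-score correlation concentrates near 0.5
(reliability-attenuated from the latent 0.7), with roughly half of cohorts
falling in [0.5, 0.85]. Recovering the latent association with high
fidelity would need longer recordings or repeated sessions, not a different
estimator — a useful design lesson for studies building on this index.

## Arousal model

The arousal classifier is an architecture plus training harness, not a
shipped model: a Gaussian-kernel SVM (C = 1, γ = 1/24 by default) on
z-transformed 24-dimensional features, standardized per participant–task.
Validation is leave-one-person-out — every fold holds out all seconds of
one participant, the appropriate guard when many highly autocorrelated
vectors come from few people. The trace output is binary per second; the
scalar consumed downstream is the high-arousal time portion. Decision
values can be obtained from the underlying `e1071` model for graded use.

## Known limitations

* The index's sampling variance at 6-min sessions dominates individual
  differences at shallow modulation (quantified above).
* The SCR detector is a simple trough-to-peak counter; overlapping SCRs
  within a rise window merge, so rates above ~6/min are compressed.
* Pulse detection assumes a dominant periodicity in 0.3–2 s; arrhythmias
  beyond the 25% local-median screen are discarded, not corrected.
* The EDF reader/writer covers continuous 16-bit recordings with a common
  sampling rate; EDF+ annotations and per-signal rates are unsupported.
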