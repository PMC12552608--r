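---
title: "Cortical temperature as a readout of sleep-wake state and EEG oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical temperature as a readout of sleep-wake state and EEG oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermosleep)
```

## The scientific problem

Brain activity generates heat, and the mouse cortex warms and cools in a
stereotyped way as the animal cycles through wakefulness, NREM sleep and REM
sleep: temperature falls approximately linearly over the first tens of
seconds of NREM sleep and of the wakefulness that follows REM sleep, rises
approximately linearly when the animal wakes from NREM sleep, and rises
along a sigmoidal time course when NREM sleep transitions into REM sleep.
Within states, discrete oscillatory events — sleep spindles (sigma,
11–15 Hz) during NREM sleep, theta (6–10 Hz) and gamma (55–85 Hz) during
REM sleep and theta-dominated wakefulness (TDW) — are followed by small
temperature increases with a delay on the order of 10–14 s.

`thermosleep` implements this analysis chain end to end:

1. **Temperature-only sleep scoring** (`score_states()`): predict
   Wake/NREM/REM from a 10 Hz cortical temperature trace alone.
2. **TDW detection** (`label_tdw()`): label theta-dominated wake epochs
   from the EEG using CWT relative theta power with a REM-calibrated
   threshold.
3. **Infraslow rhythm detection** (`infraslow_period_histogram()`): the
   ~50 s periodicity of sigma power and temperature within NREM episodes,
   via Lomb–Scargle periodograms with analytic false-alarm levels.
4. **Cross-correlation lag estimation** (`cross_correlate()`,
   `crosscorr_spectrum()`): the delay between EEG band power and the
   temperature response.
5. **Transition-aligned averaging** (`select_transitions()`,
   `aligned_delta_t()`, `transition_spectra()`): relative temperature
   (ΔT) and epoch spectra around state switches, including the cataplexy
   chain Wake/TDW → CAS → REM-sleep-like → Wake of hypocretin-deficient
   mice.

Because the methods are exercised on synthetic data, the package ships a
first-class generator (`simulate_recording()`) that produces coupled
hypnogram + EEG + temperature recordings with known ground truth.

## The temperature-only scoring algorithm

Scoring works directly on the published decision rules:

* **Wakefulness.** Continuous temperature drops lasting more than 5 s mark
  wake *ends*; the wake *start* is found by scanning backward for the
  beginning of the rise that brought the temperature to the wake-end
  level.  "Continuous" is defined on noisy 10 Hz data as the derivative of
  a 1 s moving-average-smoothed trace staying negative throughout
  (`drop_smoothing`); the backward scan tracks the running minimum with a
  tolerance (`wake_start_tol`, default 0.02 °C) and gives up when it runs
  into the preceding drop, so declines inside sleep do not spawn spurious
  wake episodes.
* **REM sleep.** A 2 s window slides in 0.1 s steps; windows whose
  4-parameter logistic fit reaches R² > 0.97 are candidate onsets,
  candidates within 3 s keep the earlier one, the episode ends at the
  first continuous drop longer than 0.4 s, and 4 s of wakefulness are
  appended after every REM end.
* **NREM sleep** is everything else.  Sample labels are binned into 4 s
  epochs by majority vote (ties broken REM > Wake > NREM, the rarer state
  winning).

The R² criterion alone cannot distinguish a logistic from any sufficiently
clean rise: a near-linear segment is fit perfectly by the middle of a
logistic, and an exponential wake onset by one of its halves.  The fit is
therefore declared invalid unless (i) the fitted amplitude is positive and
above the noise floor, (ii) the inflection lies inside the window with at
least 5% of the transition on each side, and (iii) at least 25% of the
amplitude is traversed within the window.  Two data-side guards complete
the separation of REM onsets from wake rises, both scale-free:

* **acceleration** — the slope over the first 0.3 s of the window must stay
  below 0.7 of the steepest 0.3 s slope in the window (a sigmoid onset
  accelerates; an ongoing rise is already at full slope), and
* **plateau** — the mean slope between 2 s and 10 s after the window must
  stay below 0.25 of the window's steepest slope, and the smoothed trace
  must not climb more than half the fitted amplitude above the fitted
  upper asymptote (a genuine sigmoid saturates; a wake rise keeps
  climbing).

These guards are deliberate additions: the published rule set is silent on
them, but without them the method mislabels wake onsets as REM sleep on
any data, synthetic or real, whose wake rises are smooth.  Their
thresholds are dimensionless shape ratios, not temperature scales, so they
transfer across amplitude calibrations.

The REM sliding search runs over the *whole* recording and REM labels take
precedence over wake labels.  The alternative reading — restricting the
search to non-wake regions — turns out to be self-defeating: the wake
detector necessarily claims the sigmoidal REM rise (it is a rise ending in
the post-REM decline), so a masked search can never see a REM onset at
all.

Episodes shorter than 20 s produce no interpretable temperature excursion
and cannot be captured; short wake and REM bouts are therefore scored as
NREM sleep, and NREM time is overestimated — a known, direction-tested
property, not a defect.

`compare_hourly()` contrasts predicted and reference minutes-in-state per
1 h interval with a two-sided rank-sum test on the per-epoch state
indicators (normal approximation with tie correction); an hour is flagged
when any state differs at p < 0.05.  Under a permuted-epoch null the
flagged fraction sits at the nominal level (checked by simulation).

## TDW detection

The EEG is decomposed with a continuous wavelet transform on the 0–100 Hz,
0.25 Hz grid.  For every time sample the highest spectral peak between 3.5
and 15 Hz is located; when it falls between 6.5 and 12 Hz, relative theta
power is the power in the observed peak ± 1 Hz divided by the total power
between 3.5 and 45 Hz.  The high-theta threshold is read off the inverse
cumulative distribution (1-CDF) of REM-sleep relative theta power at the
0.95 level — i.e. the 5th percentile of the REM distribution, a permissive
threshold retaining 95% of REM time points — computed separately for the
light and dark phases.  The published wording is ambiguous between the 5th
and the 95th percentile; the 1-CDF = 0.95 reading is implemented, and the
`percentile` parameter reaches the alternative.  Wake epochs with more
than 25% high-theta samples are provisionally TDW and then filtered once,
in a fixed order: (1) the preceding epoch must be Wake or TDW, (2) the
following epoch must not be NREM sleep, (3) isolated TDW epochs are
removed.  Each filter sees the output of the previous one; TDW only ever
replaces Wake labels.

### The wavelet

The transform uses an analytic wavelet family with Gaussian frequency
response and constant relative bandwidth (σ_f = 0.07·f), evaluated by FFT
filtering, with rows normalized so that the band-integrated power of a
pure tone is independent of its frequency.  The original analyses used a
complex Shannon kernel; what the downstream statistics consume is band
power localization on a 0.25 Hz grid, which any analytic wavelet of
equivalent resolution provides.  The Gaussian response is smooth (no
side-lobes) and makes the tone-power normalization exact; a two-tone test
(8 Hz vs 60 Hz, equal amplitude, band-integrated power ratio within 10% of
1) pins down the contract.  For long recordings the power is mean-binned
in time to 10 Hz (`out_rate`), matching the temperature sampling and
bounding memory.

## Infraslow rhythm and cross-correlations

Within NREM episodes longer than 200 s, sigma band power (11–15 Hz,
binned to 1 Hz samples, mean-subtracted) and temperature (second-order
polynomial detrended) are subjected to a Lomb–Scargle periodogram
(classic Scargle normalization, oversampling 4, periods from the Nyquist
period up to half the episode length, restricted by default to 20–120 s
for the infraslow analysis).  The p = 0.05 false-alarm level uses the
Horne–Baliunas estimate of independent frequencies; Monte-Carlo
calibration on white noise lands near the nominal rate (slightly
conservative).  Sigma power is handed to the periodogram in 1 s bins
because the analytic false-alarm level assumes approximately independent
samples; at 10 Hz the packet structure of spindle activity leaves
neighbouring samples correlated and would inflate the false-alarm rate.

Cross-correlations are Pearson-normalized with a fixed denominator (means
subtracted, divided by the product of the full-series standard deviations
— the convention of the common econometric routines), computed over lags
up to ±100 s.  The sign convention is asserted in tests: a positive peak
lag means temperature *follows* band power.  Peaks larger than 2/√N are
significant.  Band power is smoothed with a 20 s centered moving window
(truncated at the edges); temperature is detrended with the second-order
polynomial (NREM, wake) or with a sigmoid for REM episodes.  The sigmoid
detrend model is a 4-parameter logistic *plus a linear drift term*: the
within-REM temperature course is a fast sigmoidal rise riding on a slow
sustained drift, and a pure logistic would leave a monotone residual that
swamps the millikelvin coupling response.

The fixed-denominator convention tapers the correlation by (1 − |k|/N),
which pulls broad peaks slightly toward zero lag; with ≥ 240 s episodes
the bias stays well under the ±1 s recovery tolerance, and episode-level
curves are averaged (within, then across subjects) before the peak is
read off.

The thermal-diffusion helper `diffusion_length()` evaluates
μ(t) = √(4Dt); with the calf-brain diffusivity D = 0.147 mm²/s the
10–14 s delays correspond to 2.4–2.9 mm.

## Transition analysis

Qualifying transitions require at least 3 uniform epochs (12 s) before and
8 (32 s) after the switch.  ΔT traces subtract the temperature at the
transition point (interpolated to the epoch boundary), are clipped to the
flanking episodes, and are averaged first within and then among
recordings; dispersion is reported as the SEM across the averaged units.
Epoch spectra are 4 s discrete-Fourier power spectra at 0.25 Hz resolution
with a Hamming taper and the 49–51 Hz notch region masked; post/pre ratios
are formed per event and then averaged (the ratio-then-average order; the
alternative is a one-line change).  Events whose window contains an
Artifact-labeled epoch are dropped from the spectral averages but kept in
the temperature analyses.

## The synthetic-data generator

`simulate_recording()` draws a semi-Markov hypnogram (truncated log-normal
dwell times on the 4 s grid; cataplexy entries only during the dark phase
of the 12:12 h schedule), synthesizes EEG as a 1/f background plus
state-gated oscillations, and integrates the temperature as a piecewise
state-driven baseline plus a delayed oscillation-power response plus
measurement noise.  Key default choices, made once:

* **Temperature dynamics.**  NREM and CAS entries relax exponentially
  toward their asymptotes (35.4 / 35.5 °C, τ = 60 / 30 s), which is
  near-linear over the first ~30 s.  Wake and TDW use a two-component
  model — fast equilibration toward a base level (τ = 10 s) plus a slow
  activity-driven rise (τ = 60 s) — so that wakefulness entered from REM
  sleep shows the characteristic decrease-then-increase course while
  wakefulness from NREM sleep rises throughout.  REM and REM-sleep-like
  entries are a fast logistic jump (0.45 / 0.30 °C, k = 0.9 / 0.7 s⁻¹,
  midpoint 6 s) plus a slow drift (7 / 3 mK/s) sustaining the
  within-episode rise.  Absolute amplitudes are free parameters of the
  generator; no quantitative state differences are published, so they were
  set to a plausible ~1 °C span for the mouse cortex.
* **Oscillations.**  NREM: 1–4 Hz delta noise plus 11–15 Hz sigma wave
  packets of 0.5–2 s whose Poisson rate is modulated sinusoidally at the
  infraslow period (default 50 s, modulation depth 0.9).  REM/TDW: theta
  at 8.0/8.1 Hz and 55–85 Hz gamma with correlated slow envelopes
  (Gaussian-low-pass fluctuations, ~0.02 Hz cutoff).  CAS: large
  irregular ~7 Hz theta (±0.8 Hz frequency wander) mixed with 3–4 Hz
  delta.  Waking carries 3.5–45 Hz broadband activity so that its
  relative theta power sits well below the REM-calibrated threshold, as
  in real desynchronized wake EEG.
* **Coupling.**  The drive is the standardized sum of squared theta,
  sigma and gamma envelopes, convolved with a causal Gaussian kernel
  (width 4 s) centered at the coupling lag (default 12 s), scaled by
  4 mK per SD.
* **Noise.**  Temperature noise is 1.5 mK at 10 Hz — the realistic scale
  for an NTC thermistor driven at 100 µA — and the EEG background is 1/f
  with 15 µV SD.  The published detection thresholds themselves constrain
  this choice: R² > 0.97 in a 2 s window requires the window's signal
  range to exceed about 20 noise SDs, so centikelvin-scale noise would
  make physiological REM onsets undetectable in principle.

What the generator does **not** emulate: EMG, realistic spindle waveform
morphology beyond band-limited packets, circadian temperature drift
beyond the state asymptotes, movement artifacts, inter-animal
variability, or scorer disagreement.  Passing recovery tests on this
generator therefore demonstrates that the implementations are faithful to
the stated rules and internally consistent — not that the rules would
reach the same accuracy on arbitrary real recordings.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 240–280 s single-state
episodes (20 per condition) for lag and infraslow recovery, a 6 h
recording for scoring recovery, 2 h dark-phase recordings for the
cataplexy chain, and 1000-replicate Monte-Carlo calibrations for the
statistical levels; these sizes put every Monte-Carlo error comfortably
inside its decision margin.  Nonlinear fits use Levenberg–Marquardt
(`minpack.lm`) with data-driven starts and bounded parameters; singular
or non-converged fits are treated as invalid, never as errors.  Peak
detection on the discrete frequency grid breaks ties toward the lower
frequency.  Degenerate inputs (constant windows, empty episodes, traces
shorter than a window) return empty results or invalid fits rather than
raising, except where the input contract is violated (non-positive
voltages, unknown state tokens, sub-Nyquist sampling), which raise
informative errors.

## Known limitations

* The scoring algorithm cannot see episodes < 20 s, systematically
  overestimates NREM sleep, and labels the declining first half-minute of
  post-REM wakefulness as NREM sleep; these mirror the published
  method's own limitations.
* The REM-onset shape guards assume REM temperature jumps are fast
  relative to the 2 s fit window; on data where the sigmoid unfolds over
  minutes the detector would need a longer window.
* The Lomb–Scargle false-alarm level is analytic and slightly
  conservative; episodes with strongly autocorrelated band power (heavy
  smoothing) would need an empirical null instead.
* EDF support is deliberately minimal: single-channel, 16-bit, 1 s
  records.
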