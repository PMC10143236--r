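---
title: "Methods: 24-hour wrist HRV analysis and depression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 24-hour wrist HRV analysis and depression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wristhrv)
```

## Overview

`wristhrv` implements a complete analysis chain for 24-hour wrist recordings
of photoplethysmography (PPG, the "blood volume pulse" channel, nominally
64 Hz) and 3-axis acceleration (nominally 32 Hz, device counts of 1/64 g):

1. **Actigraphic sleep/wake scoring** from per-minute activity amplitudes,
   with three conservative rescoring rules and selection of the main sleep
   segment.
2. **Pulse-rate estimation** per 1-minute epoch from a centred 3-minute PPG
   window, using a MUSIC pseudospectrum gated by a frequency-domain signal
   quality index (`SQI_pr`).
3. **Peak-to-peak interval (PPI) extraction and ultra-short-term HRV**
   (RMSSD, SDNN, LF, HF, LF/HF, TP per epoch), gated by a harmonic-ratio
   quality index (`SQI_hrv`) and validated against the independent pulse
   rate.
4. **Sleep-anchored phase features** (five phases around sleep onset and
   final wake) and an **L2-regularized logistic screening model** evaluated
   with repeated stratified cross-validation.

A synthetic-session generator with complete ground truth (beat times, sleep
schedule, artifact mask, cohort label) makes every stage testable without
clinical data, which are not publicly available for this kind of study.

## Signal model and quality indices

The quality gates treat the PPG spectrum as a quasi-periodic pulse: energy
concentrated at the heartbeat fundamental and its low harmonics. Both gates
operate on the same Welch power spectral density of the 0.5–5 Hz bandpassed
window (Blackman–Harris segments of 30 s, 50% overlap, two-fold
zero-padding for ~0.5 bpm bins).

`SQI_pr` asks *how concentrated* the spectrum is: all bins above −5 dB
relative to the dominant pulse peak are collected over the target range
(up to twice the initial estimate), and the index is
`1 − 3·sd(bins)/range width` (population sd, bins in bpm). A single-line
spectrum scores exactly 1; broadband motion energy drives it down. Epochs
below 0.5 skip the (more expensive) MUSIC stage — the gate exists for
efficiency, not accuracy.

`SQI_hrv` asks *how harmonic* the spectrum is: the ratio of summed density
in the three harmonic bands `k·f ± 0.1 Hz` (k = 1, 2, 3) to the summed
density in the gaps between them, reported as `log(1 + ratio)`. Epochs
below 1.0 carry no HRV. Two degenerate-case notes:

* A perfectly line-like spectrum has zero inharmonic power; the printed
  definition returns 0.0 (worst quality) there, and that is the default.
  `wristhrv_config()$hrv$clean_spectrum_passes` flips this to a large
  constant for users who prefer to treat it as best quality; the situation
  does not arise with real (noisy) sensors.
* The harmonic half-band (`f_margin_hz = 0.1`) must stay below a quarter of
  the fundamental so the bands cannot overlap; this bounds usable
  fundamentals to ≥ 40 bpm, which the search ranges enforce anyway.

## Pulse rate: Welch screening, MUSIC estimation

MUSIC estimates the pulse rate as the maximal pseudospectrum peak over a
0.25 bpm grid inside the state-dependent range: 40–120 bpm asleep, 40–160
bpm awake/resting. Parameter choices that required judgement:

* **Working rate 8 Hz.** The pulse-band signal is decimated before the
  eigendecomposition. A 4 Hz rate would be cheaper still, but its 2 Hz
  Nyquist cannot represent the awake search ceiling (160 bpm = 2.67 Hz);
  8 Hz covers 240 bpm.
* **Autocorrelation dimension 64** (8 s of lags), estimated from stride-2
  Hankel snapshots of the 3-minute window.
* **Model order 2**, i.e. a single real sinusoid pair. On very clean
  signals, any order large enough to admit the second harmonic into the
  signal subspace makes the pseudospectrum peaks at `f` and `2f` both
  near-singular, and the argmax between them is decided by rounding noise —
  producing octave errors. Order 2 keeps all harmonics in the noise
  subspace; on the synthetic overnight sweep this gives a mean absolute
  error below 0.1 bpm, versus ~3.7 bpm at order 6.

Missing epochs (gate failures or degenerate windows) are filled afterwards
with the median of measured values inside a 7-minute window; epochs with no
measured neighbour stay missing, and interpolated values are flagged.

## PPI extraction and HRV indices

Windows passing `SQI_hrv` are 4× upsampled (polyphase, to 256 Hz),
differenced once, and bandpass filtered between 0.75 and 6.5 times the
fundamental (zero-phase Butterworth, order 3). Peaks are local maxima with
a minimum separation of half a nominal beat period. Two detector details go
beyond that bare description and are deliberate choices of this package:

* only **positive** local maxima count (the filtered signal is zero-mean,
  and a genuine systolic upstroke peak is positive; small negative wiggle
  maxima between beats are not beats);
* peak positions are refined by a **least-squares parabola over ±60 ms**
  around the sample maximum (shift clamped to one sample). The wide fit
  matters: band-limited sensor noise is correlated over tens of samples,
  so a 3-point interpolation inherits nearly all of it, while the wide fit
  averages it down and roughly halves beat-timing jitter.

Double peaks are removed by the valley rule: a peak whose immediately
preceding valley (minimum since the previous retained peak) is above zero
is discarded. Inside the epoch loop, each 3-minute window is padded with
2 s of real neighbouring signal before filtering so that filter settling
never affects retained peaks; standalone calls fall back to odd-reflection
extension.

The resulting interval series is validated twice against the independent
MUSIC pulse rate — peak count versus expected count, and mean PPI versus
the rate reciprocal, both within ±30% — and invalid epochs carry no HRV and
are never interpolated. RMSSD and SDNN come straight from the intervals
(population sd). Frequency-domain indices resample the intervals to a
uniform 4 Hz grid by cubic spline against the peak times, remove the mean,
and integrate a Welch PSD (90 s Blackman–Harris segments, 50% overlap) over
LF (0.04–0.15 Hz), HF (0.15–0.40 Hz) and total power (0.0033–0.40 Hz),
in ms².

## Sleep scoring and rescoring

Activity per epoch is the sum over 60 s of per-second maxima of the
absolute bandpass-filtered (0.25–3 Hz) acceleration magnitude. Scoring uses
a weighted moving sum over ±10 epochs (uniform weights 0.0064 by default,
threshold 1.0; both exposed in `wristhrv_config()` since published
coefficient sets vary). The three rescoring rules convert sleep to awake
only:

1. sleep runs shorter than 120 min bracketed on both sides by epochs above
   the 75th activity percentile (computed over the whole record, linear
   interpolation) become awake;
2. sleep fragments connected across wake gaps of ≤ 100 min form segments
   (transitively), and only the segment with the most sleep epochs is kept
   (ties to the earliest); *segment size by sleep-epoch count* is this
   package's reading of "longest";
3. within what remains, the longest consecutive-sleep core is found with
   awakenings under 4 min ignored, and sleep fragments shorter than 60 min
   strictly outside the core's ends become awake.

The three-rule pass is iterated to a fixed point. A single pass is almost
always already stable; iterating guarantees idempotence even on adversarial
sequences where removing one fragment re-opens a gap for rule 2.

Phases are anchored on the main segment: P1 = 90 min before onset,
P2/P3 = first/second 90 min of sleep, P4 = the remainder until wake
(variable, possibly as short as 90 min), P5 = 90 min after wake.
Participants need ≥ 270 min of sleep; shorter records raise a classed
exclusion error. Truncated margins shorten P1/P5 with a warning rather than
failing, since the handling of recording edges is a policy question the
method itself leaves open.

## Phase features and screening

Per phase, contributing epochs must be resting (asleep, or awake with
activity ≤ 300 counts), carry valid HRV, be sleep-scored for P2–P4, and
pass both quality gates (per gating condition). The 20 features are per
phase: mean pulse rate, mean log LF, mean log HF, mean LF/HF. LF and HF are
log-transformed per epoch before averaging (natural log, 1e−12 ms² floor);
the alternative — log of the phase mean — is monotone-equivalent for the
standardized classifier but changes the weighting of within-phase spread,
and per-epoch transformation matches how log-normal quantities are usually
handled. RMSSD/SDNN/TP are computed and reported per epoch but excluded
from the classifier: they are strongly collinear with LF + HF (variance
inflation factors far above 10; `vif_screen()` reproduces this diagnosis).

The screener is an L2-penalized logistic regression (glmnet ridge path,
`lambda = 1/(n·C)`) behind per-fold z-score standardization. Evaluation is
stratified 10-fold cross-validation repeated 100 times with reshuffling;
`C` is grid-searched (13 logarithmic points, 1e−3…1e3) by nested 5-fold CV
inside each training fold, so no test row influences scaling, fitting or
tuning. Metrics come from pooled out-of-fold predictions per repeat at a
0.5 threshold; AUC from the pooled out-of-fold ROC per repeat; summary
means carry normal-approximation 95% CIs over repeats. Four gating
conditions (gates everywhere, nowhere, awake phases only, sleep phases
only) are compared from a single per-epoch pass under identical CV seeds.

## The synthetic session generator

The generator emulates exactly the features the pipeline depends on:

* **RR series**: mean level per state (wake/sleep heart rates, smoothed over
  3 min at transitions) plus narrowband LF and HF modulation. Each band is
  one deterministic tone (0.10 / 0.25 Hz) carrying 70% of the requested
  band power and five stochastic sinusoids clustered within ±0.002 /
  ±0.003 Hz of it. The narrow cluster gives the band's local power a
  coherence time of roughly ten minutes — the quasi-stationary drift that
  real short-window HRV estimation relies on. With components spread across
  the whole band instead, windowed band power becomes white estimator noise
  and the 3-min/5-min window correlation collapses toward
  `sqrt(180/300) ≈ 0.77` regardless of estimator quality.
* **PPG**: an integral pulse model. A monotone C¹ phase interpolant passes
  through integer k at beat k, and the waveform is a sum of sine harmonics
  with relative amplitudes (1, 0.4, 0.15) — energy at f, 2f, 3f with a
  steep systolic-like upstroke at each beat, so the differenced signal
  peaks exactly once per beat. Baseline wander (0.08 Hz) and white sensor
  noise (sd 0.03 relative to unit fundamental) are added.
* **Artifacts**: additive 0.5–5 Hz band-limited noise bursts, scaled
  relative to the pulse RMS, and always co-occurring with injected
  acceleration activity (motion-locked): heavy bursts (3–6× pulse) during
  active-wake movement seconds, moderate bursts (1–2.5×) in ~35% of quiet
  rest minutes and ~5% of sleep minutes.
* **Acceleration**: gravity on z plus class-dependent noise and 1.5–2.5 Hz
  movement bursts, calibrated so activity amplitudes land near 1 000 counts
  in active wake (above the 300-count rest threshold), ~30 in quiet rest
  (awake-scored, rest-flagged) and ~1 asleep.

The default session is 24 h (sleep onset at minute 660, 450 min of sleep,
three 3-min awakenings); the cohort generator uses 690-minute sessions with
sleep onset at minute 120, the shortest schedule that holds all five phases,
so that multi-participant studies stay tractable. The depressed-like group
scales sleep HF by 0.4 and LF by 0.7 (raising LF/HF by 1.75×), shifts heart
rate by +3 bpm, and attenuates the wake-period effect to its square root;
per-participant variation is lognormal (sd 0.35) on band powers and
Gaussian (sd 2.5 bpm) on heart rate. These magnitudes were fixed once, as
plausible group contrasts of nocturnal autonomic function, before any
screening results were inspected.

What the generator does **not** model: realistic pulse morphology (dicrotic
notch hemodynamics), respiration as a physical process, REM/NREM
architecture, and non-motion artifact sources (ambient light, contact
pressure). Passing tests therefore demonstrate internal consistency of the
pipeline under a controlled measurement model — not clinical performance.

## Numerical choices

* Welch PSDs use 4-term Blackman–Harris windows, per-segment mean removal,
  and one-sided densities verified Parseval-consistent.
* Zero-phase filtering runs forward–backward over a compiled IIR kernel
  with odd-reflection extension (about two periods of the lowest passband
  frequency) and prior mean removal, so constant inputs map to exactly zero
  and boundary transients stay out of the data.
* Polyphase upsampling uses an order-5 windowed-sinc kernel, normalized per
  phase so constants are preserved exactly; decimation uses a 65-tap FIR
  evaluated only at retained samples.
* Problem sizes in the test suite (cohorts of 20 + 20 participants with
  690-minute sessions, 8-hour sweeps, 2-hour RR series) were chosen as the
  smallest sizes at which every stage still operates in its intended
  regime: all five phases exist, the 270-min rule binds, and windowed
  estimates have enough epochs to average over.

## Known limitations

* The Scripps-style scoring weights are uniform by default; with a ±10 min
  uniform window, isolated 1–3-minute awakenings are either invisible or
  smeared over the whole window — total sleep time is recovered to within a
  few percent, but brief awakening counts are not trustworthy.
* `SQI_pr` is intentionally an efficiency gate; moderate artifacts that
  leave the spectral peak dominant pass it and must be caught by `SQI_hrv`
  or the PPI validation.
* The octave guard built into the MUSIC stage is its low model order;
  signals whose second harmonic genuinely dominates the fundamental (some
  reflective-sensor morphologies) would need an explicit sub-harmonic
  check.
* Screening results on synthetic cohorts quantify the pipeline's ability to
  preserve a constructed group difference through extraction and gating —
  they are not estimates of clinical screening accuracy.
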