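---
title: "Methods: quantifying fatigue across a simulated futsal match"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying fatigue across a simulated futsal match}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matchfatigue)
```

# What the package computes

`matchfatigue` turns the raw signals of a simulated futsal match study into
the derived quantities used to characterise fatigue, and runs the inference
layer on top of them:

* **Running performance** from 30-Hz 2-D player tracking: distance covered
  (DC, m), distance per minute (DC~MIN~, m·min⁻¹), number of sprint bouts
  (S~N~) and total sprint time (S~T~, s), per 10-min period, per half and
  per match.
* **Finishing-kick performance** from 240-Hz 3-D ball trajectories: release
  speed (km·h⁻¹) by regression over ten post-contact frames, and accuracy
  (m) as the distance from the goal-plane crossing point to the nearest
  point of a 1 × 1 m target.
* **Neuromuscular function** from 1000-Hz knee-extension force with doublet
  stimulation and 2000-Hz surface EMG: peak force (F~PEAK~), control and
  superimposed twitch amplitudes (TC, TS), voluntary activation (VA), EMG
  RMS, M-wave amplitude and the RMS/M-wave ratio.
* **Aerobic capacity** from breath-by-breath gas exchange on an incremental
  treadmill test: V̇O₂max with plateau / RER / heart-rate criteria, and the
  lowest speed at which V̇O₂max is reached (vV̇O₂max), which becomes each
  athlete's sprint threshold.
* **Statistics**: paired t, one-way ANOVA, Pearson r, Cohen's *d* on the
  pooled SD of the two moments, the smallest worthwhile change
  (SWC = 0.2 × between-subject SD), and magnitude-based inference (MBI)
  chances with qualitative labels.

Every signal type has a generator with known ground truth
(`gen_player_track()`, `gen_kick()`, `gen_mvc_trace()`, `gen_emg_trace()`,
`gen_breath_series()`, `gen_cohort()`), so every estimator is covered by a
parameter-recovery test rather than trusting visual inspection.

# Signal processing choices

## Zero-phase Butterworth filtering

Player coordinates are low-passed with a 3rd-order Butterworth at 0.4 Hz;
force with a 4th-order at 15 Hz; EMG band-passed at 20–500 Hz. All filters
are applied forward and backward (`butter_zerophase()`), so there is no
phase lag to bias distances or event timings; the effective magnitude
response is the squared single-pass response, which the attenuation tests
account for. Start-up transients are handled by removing the
endpoint-to-endpoint trend and padding both ends with three cutoff periods
of odd-reflected signal; a constant or linear input passes through exactly.

A zero-phase filter applied to a waveform with a fast onset (an evoked
twitch) slightly reshapes its peak — both evoked twitches pass through the
same response, so the effect cancels exactly in the TS/TC ratio that VA is
built from.

## Running metrics

Speed is estimated by central finite differences on the filtered
coordinates. A sprint bout is a maximal run of samples with speed strictly
above the athlete's vV̇O₂max; no minimum bout duration is imposed by
default because none is established for this protocol (it is a parameter).
DC is the sum of Euclidean steps of the filtered track; segments that
bridge a rest interval are excluded.

The DC~MIN~ denominator is deliberately explicit: the published half values
(1986.6 m at 103.2 m·min⁻¹) imply an effective playing time of about
19.25 min rather than the scheduled 20 min, so `summarize_running()` offers
both `"scheduled"` (default) and `"effective"` denominators and asserts
neither as canonical.

## Kick speed and accuracy

Horizontal velocity components are OLS slopes of the unfiltered x(t) and
y(t) over the ten airborne frames after contact. The vertical component is
a gravity-constrained quadratic fit — an OLS line through
`z(t) + g t²/2` — which has strictly lower variance than an unconstrained
quadratic under digitisation noise (the suite verifies this by Monte
Carlo). The fit origin is the first airborne frame; vz is reported at
contact by adding back one frame of gravitational loss. Crossing points
below the floor or outside the goal mouth are flagged, never discarded,
and the target-centre height defaults to 1.0 m (centre of a 2-m goal
mouth), configurable because only "centre of the goal" is established.

## Twitch interpolation

F~PEAK~ is the maximum 100-ms moving average of the filtered force over
windows free of stimulation artifact. The mask spans 100 ms before to
300 ms after the superimposed doublet: the pre-extension accounts for the
backward spread of zero-phase filtering, and with a doublet relaxation
constant of ~120 ms the tail that survives the 300-ms mask biases F~PEAK~
by under 1%, which is negligible for the VA correction it feeds. Twitch
amplitudes are peak force in the 300-ms post-stimulus window minus the
50-ms pre-stimulus mean. VA uses the uncorrected formula
`VA = (1 − TS/TC) × 100` when the stimulation landed on the plateau
(force at stimulation ≥ 95% of F~PEAK~, a declared convention), and the
corrected form `VA = (1 − TS·(F_stim/F_PEAK)/TC) × 100` otherwise. VA
values outside [0, 100] are reported and flagged, not clamped. Two MVC
attempts per session are reduced by taking the one with higher F~PEAK~.

## V̇O₂max

Breath-by-breath values are smoothed with a centred 5-breath moving
average and linearly interpolated to 1 Hz. V̇O₂max is the highest mean
over the final 30 s of a stage; it is accepted when at least two of three
criteria hold: stage-to-stage stabilisation below 2.1 mL·kg⁻¹·min⁻¹, peak
RER above 1.1, and peak heart rate above 90% of the age-predicted maximum
(220 − age by default; the coefficients are parameters). vV̇O₂max is the
lowest stage speed whose final-30-s mean comes within 1.0 mL·kg⁻¹·min⁻¹ of
V̇O₂max — the tolerance is a declared convention, since "the lowest speed
at which V̇O₂max was reached" needs an operational rule.

# The statistics layer

Effect sizes use the pooled SD of the two testing moments,
`d = Δm / √((s₁² + s₂²)/2)`, with magnitudes trivial (≤ 0.2), small,
moderate and large (> 0.8). The SWC is 0.2 × between-subject SD, taken by
default as that same pooled SD (a baseline-SD mode is provided; which SD
the convention intends is genuinely ambiguous).

MBI chances use a normal sampling distribution for the observed mean
change with `SE = Δsd/√n`: the chance of a negative true change is
`Φ((−SWC − Δm)/SE)`, of a positive one `Φ((Δm − SWC)/SE)`, trivial the
remainder. This choice reproduces the published worked example — for the
peak-force change −88.6 ± 80.1 N over six athletes the negative chance
rounds to 98% — whereas a t-distribution (available via `dist = "t"`) gives
slightly fatter tails. Labels follow the qualitative scale (possibly,
likely, very likely, almost certain), with "unclear" whenever the positive
and negative chances both exceed 5%; at 97–98% the scale reads "very
likely", which is what the package prints. Chances are kept at full
precision internally and rounded half-up to integers for display.

Under a true null (Δ = 0), the long-run rate of "very likely"-or-stronger
directional labels at n = 6 stays below 10% — asserted in the suite as a
regression property of the layer, not as a claim about any published data.

# What the generators emulate

The generators define the study conditions; their defaults were fixed once,
from the published group values, and recovery tests are run at those
defaults.

* **Tracking** (`gen_player_track()`): piecewise-constant-speed bouts along
  a smooth elliptical circuit inside a 40 × 20 m court, sampled at 30 Hz
  with i.i.d. positional jitter of 0.14 m SD (the reported static-position
  error). The default 24-s cycle — stand / walk / run / walk / jog /
  sprint / jog — covers ~100 m·min⁻¹ with one 1.5-s sprint at 5.5 m·s⁻¹
  per cycle, i.e. ~50 sprint bouts and ~75 s of sprinting per 20-min half;
  a 6.6% speed decrement is applied to the second half. Bout durations
  jitter by ±20%. This is a schedule, not a gait model: only path length
  and threshold crossings matter downstream. It does not emulate occlusion,
  identity switches, or camera distortion.
* **Kicks** (`gen_kick()`): drag-free projectile flight (linear x, y;
  quadratic z) with 2-mm digitisation noise — deliberately the same model
  family the estimator fits, so recovery isolates estimation error. Drag
  and spin are out of scope.
* **MVC** (`gen_mvc_trace()`): half-cosine ramp to a plateau with additive
  difference-of-exponentials doublet twitches (rise 30 ms, decay 120 ms),
  normalised so the peak equals the configured amplitude; the superimposed
  amplitude is constructed as `TC × (1 − VA/100)`, making the VA formula
  exactly invertible and VA recovery a closed loop. Force noise SD 2 N.
* **EMG** (`gen_emg_trace()`): Gaussian interference noise shaped to a
  30–350 Hz physiological band (inside the 20–500 Hz acquisition band, so
  downstream band-passing leaves the RMS essentially unchanged), scaled to
  an exact RMS, plus one biphasic M-wave normalised to an exact
  peak-to-peak amplitude.
* **Breaths** (`gen_breath_series()`): 3-min stages from 10 km·h⁻¹ in
  1-km·h⁻¹ steps, first-order V̇O₂ kinetics (τ = 20 s) toward per-stage
  levels that plateau at the true V̇O₂max over the final two stages,
  irregular breath spacing (~2 s) and 1.0 mL·kg⁻¹·min⁻¹ breath noise — the
  scale of an ergospirometer's internally averaged output.

Passing recovery tests on these generators demonstrates that the
estimators are correct under the stated signal models; it does not certify
performance on real video tracking (occlusions, identity switches),
real ball flight (drag, spin), or real gas-exchange artifacts.

# Problem sizes and numerical conventions

The test suite exercises 2-min periods for tracking recoveries (the
estimator is agnostic to period length) and the acceptance checks use the
full 10-min-period default track, 100 seeds per condition for kick-speed
and VA recovery, 50 incremental tests for V̇O₂max recovery, and 10⁵ random
draws for the MBI closure properties — sizes chosen so the whole suite
documents the behaviour of every stage while remaining quick to run on a
laptop. Times are seconds from session start; intervals are half-open
`[start, end)`; CSV schemas are UTF-8 with "." decimals and a
`#schema=` comment line (see `pipeline_schemas()`).

`run_study()` ties everything together: it simulates a cohort (default ten
players, six with neuromuscular assessment, matching the published group
sizes), couples the second-half running decrement and the force loss
through a latent per-player fatigue factor (default correlation 0.85), and
returns running, physiological, kick and neuromuscular summaries plus the
correlation of the running declines with the neuromuscular declines. With
the coupling at zero and no decrement, the running effect labels are not
negative-dominant — the null behaves like a null.

# Known limitations

* The MBI layer implements the conventional spreadsheet procedure,
  including its known liberal behaviour at small n; the type-I property
  above bounds it but does not remove it.
* Published effect sizes other than the peak-lactate example are not
  recoverable from the printed summary statistics (they were evidently
  computed on raw athlete data) and are not used as oracles.
* The tracking generator cannot produce the published between-player
  spread exactly; group-level comparisons against published running values
  are directional, not numeric.
* Accuracy from a frontal-camera crossing file shares the target geometry
  code path but no frontal-camera digitisation model is simulated.
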