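# matchfatigue

Quantifying fatigue across a simulated futsal match — from raw time-series
signals to inference.

Futsal is high-intensity intermittent exercise, and a 40-min simulated match
measurably degrades both running output and neuromuscular function. This
package implements, as tested and reusable R functions, the full analysis
chain such a study needs: time-motion metrics from 2-D player tracking,
finishing-kick ball speed and accuracy from short 3-D trajectories,
maximal-force and voluntary-activation extraction from twitch-interpolation
force traces, EMG RMS and M-wave processing, V̇O₂max determination from
breath-by-breath gas exchange, blood-lactate and heart-rate summaries, and a
magnitude-based-inference statistics layer. It is written for exercise
physiologists and sports biomechanists who want the computations explicit,
deterministic and testable rather than buried in spreadsheets.

## The core quantities

* **Running**: distance covered DC (sum of Euclidean steps of the
  0.4-Hz-low-passed track), DC per minute, sprint count S_N and sprint time
  S_T, where a sprint is any excursion of speed above the athlete's
  vV̇O₂max.
* **Kicks**: release speed `|v| = √(vx² + vy² + vz²)` with vx, vy the OLS
  slopes of the unfiltered horizontal displacements over ten post-contact
  frames and vz from a gravity-constrained quadratic fit
  `z(t) = z₀ + vz·t − g t²/2`; accuracy is the distance from the goal-plane
  crossing to the nearest point of a 1 × 1 m target.
* **Neuromuscular**: F_PEAK = max 100-ms moving average of the 15-Hz-filtered
  force (stimulation windows masked); voluntary activation
  `VA = (1 − TS/TC) × 100`, with the off-plateau correction
  `VA = (1 − TS·(F_stim/F_PEAK)/TC) × 100`; EMG RMS over the 1-s plateau,
  M-wave peak-to-peak, and RMS/MW.
* **V̇O₂max**: highest final-30-s stage mean of the 1-Hz-interpolated
  breath series, accepted on two of three criteria (plateau < 2.1
  mL·kg⁻¹·min⁻¹, RER > 1.1, HR > 90% predicted maximum).
* **Inference**: Cohen's `d = Δm/√((s₁²+s₂²)/2)`, smallest worthwhile change
  `SWC = 0.2·SD`, and MBI chances
  `P(negative) = Φ((−SWC − Δm)/(Δsd/√n))` with qualitative labels and the
  "unclear" rule when both directional chances exceed 5%.

Every input type has a synthetic generator with known ground truth
(`gen_player_track()`, `gen_kick()`, `gen_mvc_trace()`, `gen_emg_trace()`,
`gen_breath_series()`, `gen_cohort()`), so each estimator ships with
parameter-recovery tests. See the methods vignette
(`vignettes/match-fatigue-methods.Rmd`) for models, conventions and
limitations.

## Worked example

Simulate and analyse a full study — ten players tracked over four 10-min
periods, six assessed neuromuscularly before and after — with one call:

```r
library(matchfatigue)
report <- run_study(study_config(seed = 1))
print(report)
```

```
Simulated-match study report
  players: 10 (6 with neuromuscular assessment)
  DC half 1: 1991.8 +/- 12.0 m; half 2: 1846.9 +/- 41.4 m
  VO2max: 51.9 +/- 5.3 mL/kg/min

Neuromuscular effects (before vs after):
 variable delta_mean delta_sd      p       d            inference
   F_PEAK   -89.2945  90.4921 0.0603 -1.2642 very likely negative
       TC   -27.3731  57.0780 0.2930 -0.4650    possibly negative
       VA   -13.4942  12.5402 0.0462 -0.9716 very likely negative
      RMS    -0.0114   0.1457 0.8559 -0.0696              unclear
    MWave     0.8603   1.4031 0.1934  0.4573      likely positive
   RMS_MW    -0.0287   0.0759 0.3968 -0.1828     possibly trivial

  r(dF_PEAK, dDC) = 0.92 (p = 0.009)
```

Reading: distance covered drops ~145 m between halves; maximal force and
voluntary activation decline with "very likely negative" MBI labels while
the peripheral markers (TC, M-wave) do not, and the force loss correlates
strongly with the running decline — the pattern of centrally mediated
fatigue. Individual stages are available directly, e.g.:

```r
g <- gen_mvc_trace(mvc_sim_config(va_true = 85.9, tc_amp = 288.6, seed = 2))
analyze_mvc(g$trace)$va
#> Voluntary activation: 85.9% (uncorrected formula)
#>   TS = 41.41 N, TC = 294.56 N
```

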