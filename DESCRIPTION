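Package: matchfatigue
Title: Simulated Futsal Match Fatigue: Tracking, Kicks, Neuromuscular and
    Physiological Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying fatigue across a simulated
    futsal match. Processes 2-D player tracking into running-performance
    variables (distance covered, distance per minute, sprint counts and times),
    estimates finishing-kick ball speed and accuracy from short 3-D ball
    trajectories by projectile-constrained regression, extracts maximal
    voluntary force, doublet twitch amplitudes and voluntary activation from
    force traces by twitch interpolation, computes EMG RMS and M-wave
    amplitudes, determines maximal oxygen uptake from incremental-test
    breath-by-breath data with plateau/RER/heart-rate criteria, and summarises
    blood lactate and heart rate per half. A statistics layer provides paired
    t-tests, one-way ANOVA, Pearson correlations, pooled-SD Cohen's d, the
    smallest worthwhile change, and magnitude-based inference with qualitative
    labels. Every input signal type can be simulated with known ground truth,
    so each estimator has parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
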