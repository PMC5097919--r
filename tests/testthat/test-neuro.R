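test_that("force filtering keeps DC level and rejects 100 Hz interference", {
  t <- (0:4999) / 1000
  tr <- data.frame(t = t, force = 800, stim = 0L)
  expect_equal(filter_force(tr)$force, rep(800, 5000), tolerance = 1e-6)
  tr2 <- data.frame(t = t, force = 50 * sin(2 * pi * 100 * t), stim = 0L)
  expect_lt(max(abs(filter_force(tr2)$force[1000:4000])), 0.1)
})

test_that("plateau detection recovers the configured MVC force", {
  # VA = 100: no superimposed twitch, no noise; the 100-ms mean is exact
  g <- gen_mvc_trace(mvc_sim_config(mvc_force = 840.2, va_true = 100,
                                    noise_sd = 0, seed = 1))
  plat <- detect_plateau(filter_force(g$trace))
  expect_equal(plat$F_PEAK, 840.2, tolerance = 0.05)
})

test_that("the superimposed twitch cannot inflate the masked peak force", {
  g <- gen_mvc_trace(mvc_sim_config(mvc_force = 800, va_true = 86,
                                    tc_amp = 288.6, noise_sd = 0, seed = 1))
  plat <- detect_plateau(filter_force(g$trace))
  # truth 800; the +40 N evoked twitch falls in the masked window, leaving
  # only the slow-relaxation tail (< 1%) beyond the 300-ms mask
  expect_lt(abs(plat$F_PEAK - 800), 6)
  expect_gt(810, plat$F_PEAK)
})

test_that("peak force under noise stays within moving-average theory", {
  errs <- sapply(1:40, function(s) {
    g <- gen_mvc_trace(mvc_sim_config(mvc_force = 800, va_true = 100,
                                      noise_sd = 5, seed = s))
    detect_plateau(filter_force(g$trace))$F_PEAK - 800
  })
  expect_lt(mean(abs(errs)), 3)
})

test_that("twitch amplitudes are exact on noise-free raw traces", {
  g <- gen_mvc_trace(mvc_sim_config(tc_amp = 288.6, va_true = 85.9,
                                    noise_sd = 0, seed = 1))
  tc <- twitch_amplitude(g$trace, 1.0)
  expect_equal(tc$amplitude, 288.6, tolerance = 1e-3)
  expect_equal(tc$baseline, 0, tolerance = 1e-6)
  ts <- twitch_amplitude(g$trace, 9.5)
  expect_equal(ts$amplitude, 288.6 * 0.141, tolerance = 0.01)
  flat <- data.frame(t = (0:1999) / 1000, force = 500, stim = 0L)
  expect_equal(twitch_amplitude(flat, 1.0)$amplitude, 0)
  expect_error(twitch_amplitude(flat, 1.95), "exceeds")
})

test_that("twitch amplitudes are recovered under default noise", {
  errs <- sapply(1:25, function(s) {
    g <- gen_mvc_trace(mvc_sim_config(va_true = 85.9, tc_amp = 288.6,
                                      seed = s))
    f <- filter_force(g$trace)
    c(ts = twitch_amplitude(f, 9.5)$amplitude - g$truth$TS,
      tc = twitch_amplitude(f, 1.0)$amplitude - g$truth$TC)
  })
  # the zero-phase filter response adds a small common gain (~2%) to both
  # evoked peaks plus residual noise; the gain cancels in VA
  expect_lt(mean(abs(errs["ts", ])), 1.2)
  expect_lt(max(abs(errs["ts", ])), 2.5)
  expect_lt(max(abs(errs["tc", ])) / 288.6, 0.03)
})

test_that("voluntary activation formulas match direct evaluation", {
  expect_equal(voluntary_activation(0, 288.6)$VA, 100)
  expect_equal(voluntary_activation(288.6, 288.6)$VA, 0)
  expect_equal(voluntary_activation(40, 288.6)$VA, 86.14, tolerance = 0.005)
  corr <- voluntary_activation(40, 288.6, force_at_stim = 700,
                               F_PEAK = 840.2, on_plateau = FALSE)
  expect_equal(corr$VA, (1 - (40 * (700 / 840.2) / 288.6)) * 100,
               tolerance = 1e-9)
  expect_equal(corr$VA, 88.45, tolerance = 0.005)
  expect_true(corr$corrected)
  # corrected and uncorrected coincide when stimulation force equals F_PEAK
  a <- voluntary_activation(40, 288.6, force_at_stim = 840.2,
                            F_PEAK = 840.2, on_plateau = FALSE)
  b <- voluntary_activation(40, 288.6)
  expect_equal(a$VA, b$VA, tolerance = 1e-9)
  expect_error(voluntary_activation(40, 0), "TC")
  out <- voluntary_activation(300, 288.6)
  expect_true(out$out_of_range)
})

test_that("VA recovery is within 2 percentage points across conditions", {
  for (va in c(60, 85.9, 95)) for (tc in c(150, 288.6)) {
    errs <- sapply(1:10, function(s) {
      g <- gen_mvc_trace(mvc_sim_config(va_true = va, tc_amp = tc,
                                        seed = s * 7))
      analyze_mvc(g$trace)$va$VA - va
    })
    expect_lt(max(abs(errs)), 2)
  }
})

test_that("EMG RMS over the plateau window matches closed forms", {
  t <- (0:19999) / 2000
  const <- data.frame(t = t, mv = 0.5, stim = 0L)
  expect_equal(rms_over_plateau(const, c(4, 6)), 0.5, tolerance = 1e-12)
  A <- 1.3
  sine <- data.frame(t = t, mv = A * sin(2 * pi * 80 * t), stim = 0L)
  expect_equal(rms_over_plateau(sine, c(4, 6)), A / sqrt(2),
               tolerance = 0.001)
  expect_error(rms_over_plateau(sine, c(50, 51)), "unavailable")
})

test_that("RMS recovery from the generator is within 2%", {
  g <- gen_emg_trace(emg_sim_config(rms_true = 0.53, duration_s = 12,
                                    seed = 3))
  f <- bandpass_emg(g$trace)
  est <- rms_over_plateau(f, c(8, 9))
  expect_lt(abs(est - 0.53) / 0.53, 0.02)
})

test_that("M-wave amplitude and RMS/MW ratio are recovered", {
  g <- gen_emg_trace(emg_sim_config(rms_true = 1e-9, mwave_amp = 3.75,
                                    seed = 4))
  f <- bandpass_emg(g$trace)
  mw <- mwave_amplitude(f, rms = 0.53)
  expect_equal(mw$MWave, 3.75, tolerance = 0.05)
  expect_equal(mw$RMS_MW, 0.53 / mw$MWave, tolerance = 1e-12)
  expect_equal(0.53 / 3.75, 0.141, tolerance = 0.005)
  # no marker: ratio reported missing
  nm <- g$trace; nm$stim <- 0L
  expect_true(is.na(mwave_amplitude(nm)$MWave))
  # noise-only window flagged unreliable
  gn <- gen_emg_trace(emg_sim_config(rms_true = 0.5, mwave_amp = 0.01,
                                     seed = 5))
  expect_false(mwave_amplitude(bandpass_emg(gn$trace))$reliable)
})

test_that("RMS of concatenated identical windows equals one window", {
  t <- (0:3999) / 2000
  set.seed(1)
  w <- rnorm(2000)
  x <- data.frame(t = t, mv = c(w, w), stim = 0L)
  expect_equal(rms_over_plateau(x, c(0.4, 0.6), span_s = 1),
               rms_over_plateau(x, c(0.5, 1.5), span_s = 2),
               tolerance = 1e-9)
})
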