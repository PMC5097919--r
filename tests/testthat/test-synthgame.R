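test_that("track generator is deterministic and matches its schedule truth", {
  cfg <- track_sim_config(duration_s = 120, n_periods = 1, seed = 11)
  a <- gen_player_track(cfg)
  b <- gen_player_track(cfg)
  expect_identical(a, b)
  # truth distance equals the realized schedule integral
  expect_equal(unname(a$truth$distance_m["P1"]),
               sum(a$truth$schedule$speed * a$truth$schedule$duration))
})

test_that("positional jitter inflates the raw path length but not the truth", {
  cfg <- track_sim_config(
    duration_s = 60, n_periods = 1, noise_sd = 0.05, half2_decrement = 0,
    bout_speeds = data.frame(speed = 2, duration = 60),
    duration_jitter = 0, seed = 7)
  g <- gen_player_track(cfg)
  expect_equal(unname(g$truth$distance_m["P1"]), 120)
  expect_gt(raw_path_length(g$track$x, g$track$y), 120 * 1.5)
  # noise-free version lies on the true path length to sampling precision
  cfg0 <- track_sim_config(
    duration_s = 60, n_periods = 1, noise_sd = 0,
    bout_speeds = data.frame(speed = 2, duration = 60),
    duration_jitter = 0, seed = 7)
  g0 <- gen_player_track(cfg0)
  expect_equal(raw_path_length(g0$track$x, g0$track$y), 120,
               tolerance = 2e-3)
})

test_that("second-half decrement scales bout speeds down", {
  cfg <- track_sim_config(duration_s = 240, n_periods = 4,
                          half2_decrement = 0.2, noise_sd = 0, seed = 3)
  g <- gen_player_track(cfg)
  s <- g$truth$schedule
  expect_lt(max(s$speed[s$period %in% c("P3", "P4")]),
            max(s$speed[s$period %in% c("P1", "P2")]))
  d <- g$truth$distance_m
  expect_lt(d["P3"] + d["P4"], d["P1"] + d["P2"])
})

test_that("track config invariants are enforced", {
  expect_error(track_sim_config(duration_s = -1), "positive")
  expect_error(track_sim_config(half2_decrement = 1), "half2_decrement")
  expect_error(track_sim_config(noise_sd = -0.1), "noise_sd")
})

test_that("kick generator reproduces projectile kinematics exactly", {
  cfg <- kick_sim_config(v0 = c(20, 25, 5), p0 = c(0, 0, 1), noise_sd = 0,
                         seed = 1)
  g <- gen_kick(cfg)
  expect_equal(g$truth$speed_ms, sqrt(1050))
  expect_equal(g$truth$speed_kmh, 3.6 * sqrt(1050))
  # z(t) = p0z + v0z t - g t^2 / 2 at t = 0.2 with v0z = 0
  cfg2 <- kick_sim_config(v0 = c(0, 25, 0), p0 = c(0, 0, 1), noise_sd = 0,
                          sample_rate = 5, n_frames = 3, seed = 1)
  g2 <- gen_kick(cfg2)
  expect_equal(g2$trajectory$z[g2$trajectory$t == 0.2], 1 - 0.1962)
  expect_error(kick_sim_config(v0 = c(0, 25, 0), n_frames = 2),
               "underdetermined")
})

test_that("kick digitisation noise has the configured SD", {
  devs <- unlist(lapply(1:400, function(s) {
    cfg <- kick_sim_config(v0 = c(5, 25, 3), noise_sd = 0.002, n_frames = 10,
                           seed = s)
    g <- gen_kick(cfg)
    t <- g$trajectory$t
    clean <- cfg$p0[3] + cfg$v0[3] * t - 0.5 * cfg$gravity * t^2
    g$trajectory$z - clean
  }))
  expect_equal(sd(devs), 0.002, tolerance = 0.03)
})

test_that("MVC generator encodes the twitch-interpolation truth", {
  # superimposed amplitude TC * (1 - VA/100)
  g <- gen_mvc_trace(mvc_sim_config(va_true = 85.9, tc_amp = 288.6,
                                    noise_sd = 0, seed = 1))
  expect_equal(g$truth$TS, 288.6 * (1 - 0.859), tolerance = 1e-12)
  # VA = 100 means no superimposed twitch at all
  g100 <- gen_mvc_trace(mvc_sim_config(va_true = 100, noise_sd = 0, seed = 1))
  expect_equal(g100$truth$TS, 0)
  # noise-free plateau sits exactly at the configured force (window taken
  # before the superimposed doublet, clear of both twitch transients)
  sel <- g$trace$t >= 7.5 & g$trace$t <= 9.3
  expect_equal(mean(g$trace$force[sel]), 840.2, tolerance = 1e-6)
  expect_error(mvc_sim_config(va_true = 0), "va_true")
  expect_error(mvc_sim_config(va_true = 101), "va_true")
})

test_that("EMG generator hits the configured RMS and M-wave amplitude", {
  g <- gen_emg_trace(emg_sim_config(rms_true = 0.53, duration_s = 10,
                                    seed = 5))
  ok <- abs(g$trace$t - g$truth$mwave_time_s) > 0.06
  expect_equal(sqrt(mean(g$trace$mv[ok]^2)), 0.53, tolerance = 0.02)
  # peak-to-peak of the evoked window is exact by construction
  gq <- gen_emg_trace(emg_sim_config(rms_true = 1e-9, mwave_amp = 3.75,
                                     seed = 2))
  win <- gq$trace$t >= gq$truth$mwave_time_s &
    gq$trace$t <= gq$truth$mwave_time_s + 0.05
  expect_equal(max(gq$trace$mv[win]) - min(gq$trace$mv[win]), 3.75,
               tolerance = 1e-9)
  expect_identical(gen_emg_trace(emg_sim_config(seed = 9))$trace,
                   gen_emg_trace(emg_sim_config(seed = 9))$trace)
  expect_error(emg_sim_config(band = c(20, 1500)), "band")
})

test_that("breath generator stage truth follows its construction", {
  cfg <- breath_sim_config(vo2max = 50.6, noise_sd = 0, seed = 1)
  g <- gen_breath_series(cfg)
  expect_equal(g$truth$vo2max, 50.6)
  expect_equal(g$truth$vvo2max, 14)   # plateau onset at stage 5 of 10,11,...
  # a 3.0-step between the final stages defeats the 2.1 plateau rule
  cfg2 <- breath_sim_config(vo2_per_stage = c(37, 40, 43, 46, 47.6, 50.6),
                            stage_speeds = 10:15, noise_sd = 0, seed = 1)
  expect_gt(diff(tail(cfg2$vo2_per_stage, 2)), 2.1)
  expect_error(breath_sim_config(stage_speeds = numeric(0)), "stage")
})

test_that("cohort generator delivers the configured paired effects", {
  big <- gen_cohort(10000, list(v = list(mean = 0, sd = 1, delta_mean = 0,
                                         delta_sd = 1)), seed = 2)
  expect_lt(abs(mean(big$after - big$before)), 0.05)
  small <- gen_cohort(6, list(F_PEAK = list(mean = 840.2, sd = 66.2,
                                            delta_mean = -88.6,
                                            delta_sd = 80.1)), seed = 3)
  expect_identical(small,
                   gen_cohort(6, list(F_PEAK = list(mean = 840.2, sd = 66.2,
                                                    delta_mean = -88.6,
                                                    delta_sd = 80.1)),
                              seed = 3))
  const <- gen_cohort(5, list(v = list(mean = 1, sd = 0, delta_mean = 2,
                                       delta_sd = 0)), seed = 1)
  expect_true(all(const$after - const$before == 2))
  expect_error(gen_cohort(1, list(v = list())), "n_players")
})
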