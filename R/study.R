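#' Configuration of a full simulated-match study
#'
#' Bundles the protocol structure (two 20-min halves of two 10-min periods,
#' 5-min rests within halves and 10 min at half-time), the cohort size, and
#' the generator settings of every signal type. Defaults reproduce the
#' demands of professional futsal simulated match play: a ~6.6 percent
#' second-half speed decrement coupled, through a latent per-player fatigue
#' factor, to the decline in maximal voluntary force.
#'
#' @param n_players tracked cohort size.
#' @param neuro_players how many players undergo the neuromuscular and kick
#'   assessments (first `neuro_players` of the cohort).
#' @param period_minutes scheduled period length (min).
#' @param n_periods number of periods (two per half).
#' @param vo2max_mean,vo2max_sd cohort V-dot-O2max distribution
#'   (mL/kg/min).
#' @param age cohort age in years (predicted-HRmax criterion).
#' @param decrement_mean,decrement_sd second-half speed decrement
#'   distribution (fraction).
#' @param coupling correlation between the latent fatigue factor driving
#'   the running decrement and the force loss.
#' @param track_noise_sd positional jitter SD (m).
#' @param neuro_effects named list of per-variable change settings
#'   (`delta_mean`, `delta_sd`) for F_PEAK, TC, VA, RMS, MWave.
#' @param kick_set_speed_kmh true mean release speed per set (km/h).
#' @param kick_player_sd,kick_within_sd between-player and within-set speed
#'   SDs (km/h).
#' @param kick_aim_sd aim scatter of the goal-plane crossing point (m).
#' @param lactate_half_mean,lactate_half_sd per-half mean blood lactate
#'   distribution (mmol/L).
#' @param hr_half_mean,hr_half_sd per-half mean heart rate distribution
#'   (bpm).
#' @param seed master seed (mandatory; every stage draws from one stream).
#' @return A `study_config` object.
#' @export
study_config <- function(n_players = 10L, neuro_players = 6L,
                         period_minutes = 10, n_periods = 4L,
                         vo2max_mean = 50.6, vo2max_sd = 4.9, age = 22,
                         decrement_mean = 0.066, decrement_sd = 0.03,
                         coupling = 0.85, track_noise_sd = 0.14,
                         neuro_effects = list(
                           F_PEAK = list(delta_mean = -88.6, delta_sd = 80.1),
                           TC = list(delta_mean = -40.6, delta_sd = 54.4),
                           VA = list(delta_mean = -11.9, delta_sd = 11.2),
                           RMS = list(delta_mean = -0.04, delta_sd = 0.12),
                           MWave = list(delta_mean = 0.62, delta_sd = 1.16)),
                         kick_set_speed_kmh = c(109.3, 113.1, 110.2),
                         kick_player_sd = 6, kick_within_sd = 3,
                         kick_aim_sd = 0.35,
                         lactate_half_mean = c(4.8, 4.2),
                         lactate_half_sd = c(2.3, 2.2),
                         hr_half_mean = c(168.4, 166.4),
                         hr_half_sd = c(12.4, 12.5),
                         seed = 1L) {
  if (n_players < 2L) stop_config("n_players must be >= 2")
  if (neuro_players < 2L || neuro_players > n_players) {
    stop_config("neuro_players must be between 2 and n_players")
  }
  if (is.null(seed)) stop_config("a seed is mandatory")
  structure(as.list(environment()), class = "study_config")
}

# Latent-coupled draw: value = mean + sd * (rho * u + sqrt(1-rho^2) * e).
coupled_draw <- function(mean, sd, u, rho) {
  mean + sd * (rho * u + sqrt(1 - rho^2) * stats::rnorm(length(u)))
}

# Release velocity that crosses the goal plane at `cross` with speed
# `speed_ms` (fixed-point iteration on the flight time).
aim_velocity <- function(speed_ms, cross, p0 = c(0, 0, 0.11),
                         plane_y = 10, g = 9.81) {
  vy <- speed_ms
  for (i in 1:4) {
    tf <- (plane_y - p0[2]) / vy
    vz <- (cross[2] - p0[3] + 0.5 * g * tf^2) / tf
    vx <- (cross[1] - p0[1]) / tf
    vy <- sqrt(max(speed_ms^2 - vx^2 - vz^2, 1))
  }
  c(vx, vy, vz)
}

simulate_player_neuro <- function(before, after) {
  run_session <- function(p) {
    attempts <- lapply(1:2, function(k) {
      cfg <- mvc_sim_config(mvc_force = p$F_PEAK * stats::runif(1, 0.985, 1.0),
                            va_true = p$VA, tc_amp = p$TC, seed = NULL)
      analyze_mvc(gen_mvc_trace(cfg)$trace)
    })
    best <- attempts[[which.max(vapply(attempts, `[[`, 0, "F_PEAK"))]]
    emg <- gen_emg_trace(emg_sim_config(rms_true = p$RMS,
                                        mwave_amp = p$MWave, seed = NULL))
    emg_f <- bandpass_emg(emg$trace)
    # EMG recorded over the MVC: RMS read on the 1-s plateau span
    rms <- rms_over_plateau(emg_f,
                            plateau_window = emg$truth$mwave_time_s + c(2, 3))
    mw <- mwave_amplitude(emg_f, rms = rms)
    c(F_PEAK = best$F_PEAK, TC = best$TC, VA = best$va$VA,
      RMS = rms, MWave = mw$MWave, RMS_MW = mw$RMS_MW)
  }
  list(before = run_session(before), after = run_session(after))
}

simulate_player_kicks <- function(speeds_kmh, aim_sd, goal) {
  lapply(seq_along(speeds_kmh), function(i) {
    cross <- goal$centre + stats::rnorm(2, 0, aim_sd)
    v0 <- aim_velocity(speeds_kmh[i] / 3.6, cross, plane_y = goal$plane_y)
    gen_kick(kick_sim_config(v0 = v0, plane_y = goal$plane_y, seed = NULL),
             kick_id = sprintf("k%d", i))
  })
}

#' Run the full simulated-match study replica
#'
#' Simulates the cohort (incremental test, match tracking, kick sets,
#' neuromuscular assessments, lactate and heart rate), processes every
#' signal with the package's estimators, and assembles the study-level
#' report: running summaries per half, physiological summaries, kick set
#' means with one-way ANOVA, a table of paired effect rows for the
#' neuromuscular variables, and the correlation of the running declines
#' with the neuromuscular declines.
#'
#' @param cfg a [study_config()].
#' @return Object of class `study_report`; see the list elements
#'   `running`, `physio`, `kicks`, `neuro`, `correlations`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  with_seed(cfg$seed, {
    np <- cfg$n_players
    u <- stats::rnorm(np)                      # latent fatigue factor

    # --- incremental tests: vVO2max as each player's sprint threshold
    vo2_true <- stats::rnorm(np, cfg$vo2max_mean, cfg$vo2max_sd)
    vo2res <- lapply(seq_len(np), function(i) {
      b <- gen_breath_series(breath_sim_config(vo2max = vo2_true[i],
                                               seed = NULL))
      vo2max(resample_breaths(b$breaths), age = cfg$age)
    })
    vvo2_ms <- vapply(vo2res, function(r) r$vvo2max, 0) / 3.6

    # --- match tracking
    decr <- pmin(pmax(cfg$decrement_mean + cfg$decrement_sd * u, 0), 0.3)
    running <- lapply(seq_len(np), function(i) {
      tr <- gen_player_track(track_sim_config(
        duration_s = cfg$period_minutes * 60 * cfg$n_periods,
        n_periods = cfg$n_periods, half2_decrement = decr[i],
        noise_sd = cfg$track_noise_sd, seed = NULL))
      rs <- summarize_running(tr$track, vvo2max_ms = vvo2_ms[i],
                              period_minutes = cfg$period_minutes)
      rs$player_id <- sprintf("S%02d", i)
      rs
    })
    running_tab <- do.call(rbind, lapply(running, as.data.frame))
    half <- function(tab, sc, col) tab[tab$scope == sc, col]
    delta_dc <- half(running_tab, "half2", "DC_m") -
      half(running_tab, "half1", "DC_m")
    delta_dcmin <- half(running_tab, "half2", "DCmin_m_per_min") -
      half(running_tab, "half1", "DCmin_m_per_min")

    # --- lactate and heart rate per half
    la <- hrv <- vector("list", np)
    for (i in seq_len(np)) {
      lh <- stats::rnorm(2, cfg$lactate_half_mean, cfg$lactate_half_sd)
      lh <- pmax(lh, 0.8)
      per_la <- c(lh[1] * c(0.85, 1.15), lh[2] * c(1.15, 0.85))
      hb <- stats::rnorm(2, cfg$hr_half_mean, cfg$hr_half_sd)
      tsec <- seq(0, cfg$period_minutes * 120 - 1)
      mk_hr <- function(base) base + 10 * sin(2 * pi * tsec / 150) +
        stats::rnorm(length(tsec), 0, 3)
      la[[i]] <- list(h1 = lactate_summary(per_la[1:2]),
                      h2 = lactate_summary(per_la[3:4]))
      hrv[[i]] <- list(h1 = hr_summary(mk_hr(hb[1])),
                       h2 = hr_summary(mk_hr(hb[2])))
    }
    pull <- function(lst, hh, f) vapply(lst, function(e) e[[hh]][[f]], 0)
    physio_rows <- rbind(
      effect_report(pull(la, "h1", "La_PEAK"), pull(la, "h2", "La_PEAK"),
                    "La_PEAK"),
      effect_report(pull(la, "h1", "La_MEAN"), pull(la, "h2", "La_MEAN"),
                    "La_MEAN"),
      effect_report(pull(hrv, "h1", "HR_PEAK"), pull(hrv, "h2", "HR_PEAK"),
                    "HR_PEAK"),
      effect_report(pull(hrv, "h1", "HR_MEAN"), pull(hrv, "h2", "HR_MEAN"),
                    "HR_MEAN"))

    # --- kick sets (baseline, half-time, post)
    nk <- cfg$neuro_players
    goal <- goal_target()
    kick_speed <- matrix(0, nk, 3)
    kick_acc <- matrix(0, nk, 3)
    for (i in seq_len(nk)) {
      off <- stats::rnorm(1, 0, cfg$kick_player_sd)
      for (s in 1:3) {
        sp <- stats::rnorm(3, cfg$kick_set_speed_kmh[s] + off,
                           cfg$kick_within_sd)
        kicks <- simulate_player_kicks(sp, cfg$kick_aim_sd, goal)
        res <- lapply(kicks, function(k) ball_speed(k$trajectory, goal))
        sm <- summarize_set(res)
        kick_speed[i, s] <- sm$speed_kmh
        kick_acc[i, s] <- sm$accuracy_m
      }
    }
    kick_sets <- data.frame(
      set = 1:3,
      speed_kmh = colMeans(kick_speed), speed_sd = apply(kick_speed, 2, stats::sd),
      accuracy_m = colMeans(kick_acc), accuracy_sd = apply(kick_acc, 2, stats::sd))
    kick_anova <- list(
      speed = oneway_anova(split(kick_speed, col(kick_speed))),
      accuracy = oneway_anova(split(kick_acc, col(kick_acc))))

    # --- neuromuscular assessment before/after (neuro subset)
    ne <- cfg$neuro_effects
    before <- data.frame(
      F_PEAK = stats::rnorm(nk, 840.2, 66.2),
      TC = pmax(stats::rnorm(nk, 288.6, 45.5), 60),
      VA = pmin(pmax(stats::rnorm(nk, 85.9, 7.5), 40), 99),
      RMS = pmax(stats::rnorm(nk, 0.53, 0.14), 0.1),
      MWave = pmax(stats::rnorm(nk, 3.75, 1.41), 0.8))
    after <- data.frame(
      F_PEAK = before$F_PEAK + coupled_draw(ne$F_PEAK$delta_mean,
        ne$F_PEAK$delta_sd, -u[seq_len(nk)], cfg$coupling),
      TC = pmax(before$TC + stats::rnorm(nk, ne$TC$delta_mean,
        ne$TC$delta_sd), 40),
      VA = pmin(pmax(before$VA + stats::rnorm(nk, ne$VA$delta_mean,
        ne$VA$delta_sd), 20), 99),
      RMS = pmax(before$RMS + stats::rnorm(nk, ne$RMS$delta_mean,
        ne$RMS$delta_sd), 0.05),
      MWave = pmax(before$MWave + stats::rnorm(nk, ne$MWave$delta_mean,
        ne$MWave$delta_sd), 0.5))
    meas <- lapply(seq_len(nk), function(i) {
      simulate_player_neuro(as.list(before[i, ]), as.list(after[i, ]))
    })
    vars <- c("F_PEAK", "TC", "VA", "RMS", "MWave", "RMS_MW")
    mb <- sapply(vars, function(v) vapply(meas, function(m) m$before[[v]], 0))
    ma <- sapply(vars, function(v) vapply(meas, function(m) m$after[[v]], 0))
    neuro_tab <- do.call(rbind, lapply(vars, function(v) {
      effect_report(mb[, v], ma[, v], v)
    }))

    # --- correlations of running declines with neuromuscular declines
    dn <- ma - mb
    run_delta <- cbind(dDC = delta_dc[seq_len(nk)],
                       dDCmin = delta_dcmin[seq_len(nk)])
    cors <- array(NA_real_, c(ncol(run_delta), length(vars), 2),
                  dimnames = list(colnames(run_delta), vars, c("r", "p")))
    for (a in colnames(run_delta)) for (v in vars) {
      pr <- pearson_r(run_delta[, a], dn[, v])
      cors[a, v, "r"] <- pr$r; cors[a, v, "p"] <- pr$p
    }

    structure(list(
      config = cfg,
      running = running_tab,
      vo2 = data.frame(player = sprintf("S%02d", seq_len(np)),
                       vo2max = vapply(vo2res, `[[`, 0, "vo2max"),
                       vvo2max_kmh = vapply(vo2res, `[[`, 0, "vvo2max")),
      physio = physio_rows,
      kicks = list(sets = kick_sets, anova = kick_anova),
      neuro = neuro_tab,
      correlations = cors),
      class = "study_report")
  })
}

#' @export
print.study_report <- function(x, ...) {
  cat("Simulated-match study report\n")
  cat(sprintf("  players: %d (%d with neuromuscular assessment)\n",
              x$config$n_players, x$config$neuro_players))
  h1 <- x$running[x$running$scope == "half1", ]
  h2 <- x$running[x$running$scope == "half2", ]
  cat(sprintf("  DC half 1: %.1f +/- %.1f m; half 2: %.1f +/- %.1f m\n",
              mean(h1$DC_m), stats::sd(h1$DC_m),
              mean(h2$DC_m), stats::sd(h2$DC_m)))
  cat(sprintf("  VO2max: %.1f +/- %.1f mL/kg/min\n",
              mean(x$vo2$vo2max), stats::sd(x$vo2$vo2max)))
  cat("\nNeuromuscular effects (before vs after):\n")
  print(as.data.frame(x$neuro)[, c("variable", "delta_mean", "delta_sd",
                                   "p", "d", "inference")],
        row.names = FALSE, digits = 3)
  cat(sprintf("\n  r(dF_PEAK, dDC) = %.2f (p = %.3f)\n",
              x$correlations["dDC", "F_PEAK", "r"],
              x$correlations["dDC", "F_PEAK", "p"]))
  invisible(x)
}
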