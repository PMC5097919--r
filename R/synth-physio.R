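#' Configuration for the incremental-test breath-by-breath simulator
#'
#' Emulates a treadmill incremental test: stages of fixed duration starting
#' at 10 km/h with 1 km/h increments, oxygen uptake approaching a per-stage
#' level with first-order kinetics, RER and HR rising across stages, and
#' irregular breath spacing. The terminal stages plateau at the true
#' V-dot-O2max so the plateau criterion is controllable.
#'
#' @param vo2max true maximal oxygen uptake (mL/kg/min).
#' @param stage_speeds stage speeds in km/h (default 10, 11, ... for
#'   `n_stages` stages).
#' @param vo2_per_stage steady-state V-dot-O2 level of each stage; default
#'   rises linearly from running economy at 10 km/h and is capped at
#'   `vo2max` over the last `plateau_stages` stages.
#' @param rer_profile per-stage respiratory exchange ratio.
#' @param hr_profile per-stage heart rate (bpm).
#' @param n_stages,plateau_stages number of stages and how many terminal
#'   stages sit at `vo2max`.
#' @param stage_s stage duration in seconds.
#' @param breath_interval_s mean inter-breath interval (s); actual intervals
#'   jitter uniformly by +/-30 percent.
#' @param kinetics_tau_s first-order time constant of the within-stage
#'   V-dot-O2 response (s).
#' @param noise_sd breath-to-breath V-dot-O2 noise SD (mL/kg/min).
#' @param vvo2max_tol_ml tolerance defining the lowest speed at which
#'   V-dot-O2max is reached (mL/kg/min).
#' @param seed integer seed.
#' @return A `breath_sim_config` list.
#' @export
breath_sim_config <- function(vo2max = 50.6, stage_speeds = NULL,
                              vo2_per_stage = NULL, rer_profile = NULL,
                              hr_profile = NULL, n_stages = 6L,
                              plateau_stages = 2L, stage_s = 180,
                              breath_interval_s = 2.0,
                              kinetics_tau_s = 20, noise_sd = 1.0,
                              vvo2max_tol_ml = 1.0, seed = 1L) {
  if (is.null(stage_speeds)) stage_speeds <- 10 + seq_len(n_stages) - 1
  n_stages <- length(stage_speeds)
  if (n_stages < 1L) stop_config("at least one stage is required")
  if (is.null(vo2_per_stage)) {
    base <- 36.8                      # running economy at 10 km/h
    rise <- if (n_stages > plateau_stages) {
      (vo2max - base) / (n_stages - plateau_stages)
    } else 0
    vo2_per_stage <- pmin(vo2max, base + rise * (seq_len(n_stages) - 1))
    vo2_per_stage[seq.int(n_stages - plateau_stages + 1L, n_stages)] <- vo2max
  }
  if (length(vo2_per_stage) != n_stages) {
    stop_config("vo2_per_stage must match stage_speeds in length")
  }
  if (is.null(rer_profile)) {
    rer_profile <- seq(0.85, 1.15, length.out = max(n_stages, 2L))[seq_len(n_stages)]
  }
  if (is.null(hr_profile)) {
    hr_profile <- 198 - 70 * exp(-(seq_len(n_stages) - 1) / 2.2)
  }
  if (stage_s <= 0 || breath_interval_s <= 0) {
    stop_config("stage_s and breath_interval_s must be positive")
  }
  structure(list(vo2max = vo2max, stage_speeds = stage_speeds,
                 vo2_per_stage = vo2_per_stage, rer_profile = rer_profile,
                 hr_profile = hr_profile, stage_s = stage_s,
                 breath_interval_s = breath_interval_s,
                 kinetics_tau_s = kinetics_tau_s, noise_sd = noise_sd,
                 vvo2max_tol_ml = vvo2max_tol_ml, seed = seed),
            class = "breath_sim_config")
}

#' Simulate an incremental-test breath-by-breath series
#'
#' @param cfg a [breath_sim_config()].
#' @return List with `breaths` (data frame `t, vo2, vco2, hr, stage_kmh`,
#'   the `breaths.csv` schema) and `truth` (`vo2max`, `vvo2max`, per-stage
#'   levels).
#' @export
gen_breath_series <- function(cfg) {
  stopifnot(inherits(cfg, "breath_sim_config"))
  with_seed(cfg$seed, {
    n_stages <- length(cfg$stage_speeds)
    total_s <- n_stages * cfg$stage_s
    # irregular breath times
    gaps <- cfg$breath_interval_s * stats::runif(ceiling(total_s /
      cfg$breath_interval_s * 1.6) + 10L, 0.7, 1.3)
    t <- cumsum(gaps)
    t <- t[t < total_s]
    stage <- pmin(findInterval(t, (0:n_stages) * cfg$stage_s), n_stages)
    stage_t0 <- (stage - 1) * cfg$stage_s
    lev <- cfg$vo2_per_stage[stage]
    prev <- c(cfg$vo2_per_stage[1] * 0.35, cfg$vo2_per_stage)[stage]
    vo2 <- lev + (prev - lev) * exp(-(t - stage_t0) / cfg$kinetics_tau_s)
    if (cfg$noise_sd > 0) vo2 <- vo2 + stats::rnorm(length(t), 0, cfg$noise_sd)
    rer <- cfg$rer_profile[stage]
    vco2 <- vo2 * rer
    hr_lev <- cfg$hr_profile[stage]
    hr_prev <- c(cfg$hr_profile[1] * 0.7, cfg$hr_profile)[stage]
    hr <- hr_lev + (hr_prev - hr_lev) * exp(-(t - stage_t0) / 30) +
      if (cfg$noise_sd > 0) stats::rnorm(length(t), 0, 2) else 0
    truth_vvo2 <- cfg$stage_speeds[
      which(cfg$vo2_per_stage >= max(cfg$vo2_per_stage) - cfg$vvo2max_tol_ml)[1]]
    list(breaths = data.frame(t = t, vo2 = vo2, vco2 = vco2, hr = hr,
                              stage_kmh = cfg$stage_speeds[stage]),
         truth = list(vo2max = max(cfg$vo2_per_stage), vvo2max = truth_vvo2,
                      vo2_per_stage = cfg$vo2_per_stage))
  })
}

#' Simulate a paired before/after cohort
#'
#' Draws per-subject baseline values and paired changes with configured true
#' change mean and SD, for end-to-end tests of the statistics layer.
#'
#' @param n_players number of subjects (>= 2).
#' @param effect_config named list; each element a list with `mean`, `sd`
#'   (baseline distribution) and `delta_mean`, `delta_sd` (distribution of
#'   the paired change).
#' @param seed integer seed.
#' @return Long data frame `subject, variable, before, after` (the
#'   `paired.csv` schema).
#' @export
gen_cohort <- function(n_players, effect_config, seed = 1L) {
  if (n_players < 2) stop_config("n_players must be >= 2")
  if (!length(effect_config) || is.null(names(effect_config))) {
    stop_config("effect_config must be a named list of variable settings")
  }
  with_seed(seed, {
    rows <- lapply(names(effect_config), function(v) {
      e <- effect_config[[v]]
      before <- stats::rnorm(n_players, e$mean %||% 0, e$sd %||% 0)
      delta <- stats::rnorm(n_players, e$delta_mean %||% 0, e$delta_sd %||% 0)
      data.frame(subject = sprintf("S%02d", seq_len(n_players)),
                 variable = v, before = before, after = before + delta)
    })
    do.call(rbind, rows)
  })
}
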