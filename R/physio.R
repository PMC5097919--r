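#' Resample breath-by-breath data to 1 Hz
#'
#' Smooths each gas-exchange channel with a centred moving average over
#' `smooth_breaths` breaths, then interpolates linearly onto a 1-s grid
#' spanning the test, the conventional pre-processing before applying
#' V-dot-O2max criteria.
#'
#' @param breaths data frame `t, vo2, vco2, hr, stage_kmh` (irregular
#'   breath times).
#' @param smooth_breaths moving-average span in breaths (odd; default 5).
#' @return Data frame with the same columns on a 1-s grid (`stage_kmh`
#'   carried as a step function).
#' @export
resample_breaths <- function(breaths, smooth_breaths = 5L) {
  if (nrow(breaths) < 2L) stop_config("need at least 2 breaths")
  b <- breaths[order(breaths$t), , drop = FALSE]
  grid <- seq(ceiling(min(b$t)), floor(max(b$t)), by = 1)
  sm <- function(x) stats::approx(b$t, moving_average(x, smooth_breaths),
                                  grid)$y
  data.frame(t = grid,
             vo2 = sm(b$vo2), vco2 = sm(b$vco2), hr = sm(b$hr),
             stage_kmh = stats::approx(b$t, b$stage_kmh, grid,
                                       method = "constant", rule = 2)$y)
}

#' V-dot-O2max determination with plateau, RER and heart-rate criteria
#'
#' V-dot-O2max is the highest V-dot-O2 average over the final 30 s of an
#' exercise stage. It is accepted when at least two of three criteria hold:
#' (1) plateau - the final two stages' 30-s averages differ by less than
#' `plateau_ml`; (2) peak respiratory exchange ratio above `rer_max`;
#' (3) peak heart rate above `hr_frac` of the age-predicted maximum
#' (`hrmax_intercept - hrmax_slope * age`). The speed at V-dot-O2max
#' (vVO2max) is the lowest stage speed whose final-30-s average comes within
#' `vvo2max_tol_ml` of V-dot-O2max.
#'
#' @param series1hz 1-Hz series from [resample_breaths()].
#' @param age athlete age in years (for predicted HRmax).
#' @param plateau_ml plateau criterion range (mL/kg/min).
#' @param rer_max RER criterion threshold.
#' @param hr_frac fraction of predicted HRmax for the HR criterion.
#' @param hrmax_intercept,hrmax_slope predicted-HRmax formula coefficients.
#' @param vvo2max_tol_ml tolerance defining vVO2max (mL/kg/min).
#' @param final_s length of the stage-final averaging window (s).
#' @return Object of class `vo2max_result`: list with `vo2max`, `vvo2max`,
#'   `criteria` (logical `plateau`, `rer`, `hr`; plateau is `NA` with fewer
#'   than two stages), `met_count`, `accepted`, `stage_means`.
#' @export
vo2max <- function(series1hz, age = 22, plateau_ml = 2.1, rer_max = 1.1,
                   hr_frac = 0.9, hrmax_intercept = 220, hrmax_slope = 1,
                   vvo2max_tol_ml = 1.0, final_s = 30) {
  s <- series1hz
  stages <- unique(s$stage_kmh)
  stage_means <- vapply(stages, function(sp) {
    tt <- s$t[s$stage_kmh == sp]
    hi <- max(tt)
    mean(s$vo2[s$stage_kmh == sp & s$t > hi - final_s], na.rm = TRUE)
  }, 0)
  vo2max_est <- max(stage_means)
  k <- length(stages)
  plateau <- if (k >= 2L) {
    abs(stage_means[k] - stage_means[k - 1L]) < plateau_ml
  } else NA
  rer <- max(s$vco2 / s$vo2, na.rm = TRUE) > rer_max
  hr <- max(s$hr, na.rm = TRUE) > hr_frac * (hrmax_intercept - hrmax_slope * age)
  met <- sum(c(plateau, rer, hr), na.rm = TRUE)
  vvo2 <- stages[which(stage_means >= vo2max_est - vvo2max_tol_ml)[1]]
  structure(list(vo2max = vo2max_est, vvo2max = vvo2,
                 criteria = list(plateau = plateau, rer = rer, hr = hr),
                 met_count = met, accepted = met >= 2L,
                 stage_means = stats::setNames(stage_means,
                                               paste0(stages, "kmh"))),
            class = "vo2max_result")
}

#' @export
print.vo2max_result <- function(x, ...) {
  cat(sprintf("VO2max: %.1f mL/kg/min at vVO2max = %g km/h (%s)\n",
              x$vo2max, x$vvo2max,
              if (x$accepted) "accepted" else "not accepted"))
  cr <- x$criteria
  cat(sprintf("  criteria met: %d/3 (plateau %s, RER %s, HR %s)\n",
              x$met_count, cr$plateau, cr$rer, cr$hr))
  invisible(x)
}

#' Blood lactate summary over a scope
#'
#' Peak (highest sample) and mean of per-period lactate concentrations.
#'
#' @param samples numeric lactate values (mmol/L) of the periods in scope.
#' @return List with `La_PEAK` and `La_MEAN`.
#' @export
lactate_summary <- function(samples) {
  samples <- samples[!is.na(samples)]
  if (!length(samples)) stop_config("no lactate samples in scope")
  list(La_PEAK = max(samples), La_MEAN = mean(samples))
}

#' Heart-rate summary over a scope
#'
#' Peak and mean of beat-by-beat heart rate inside the scope (rest intervals
#' are excluded by whatever scope the caller supplies).
#'
#' @param bpm numeric heart-rate values (beats per minute).
#' @return List with `HR_PEAK` and `HR_MEAN`.
#' @export
hr_summary <- function(bpm) {
  bpm <- bpm[!is.na(bpm)]
  if (!length(bpm)) stop_config("no heart-rate samples in scope")
  list(HR_PEAK = max(bpm), HR_MEAN = mean(bpm))
}
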