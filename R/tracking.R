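#' Low-pass filter a player track
#'
#' Applies a zero-phase 3rd-order Butterworth filter (0.4 Hz cutoff by
#' default) independently to the x and y coordinates of each period. The
#' track must be uniformly sampled within each period (1 percent jitter
#' tolerance); it is linearly resampled onto a uniform grid first if not.
#'
#' @param track data frame with columns `player_id, t, x, y, period`.
#' @param order filter order.
#' @param cutoff_hz cutoff frequency in Hz.
#' @return The track with `x` and `y` replaced by their filtered values.
#' @export
filter_track <- function(track, order = 3L, cutoff_hz = 0.4) {
  check_track(track)
  parts <- split(track, track$period)
  parts <- lapply(parts, function(p) {
    p <- p[order(p$t), , drop = FALSE]
    if (!is_uniformly_sampled(p$t)) {
      grid <- seq(min(p$t), max(p$t), by = stats::median(diff(p$t)))
      p2 <- data.frame(player_id = p$player_id[1], t = grid,
                       x = stats::approx(p$t, p$x, grid)$y,
                       y = stats::approx(p$t, p$y, grid)$y,
                       period = p$period[1])
      p <- p2
    }
    fs <- 1 / stats::median(diff(p$t))
    p$x <- butter_zerophase(p$x, fs, cutoff_hz, order)
    p$y <- butter_zerophase(p$y, fs, cutoff_hz, order)
    p
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$t), , drop = FALSE]
}

check_track <- function(track) {
  need <- c("player_id", "t", "x", "y", "period")
  miss <- setdiff(need, names(track))
  if (length(miss)) stop_config("track is missing column(s): %s",
                                paste(miss, collapse = ", "))
  if (any(!is.finite(track$x)) || any(!is.finite(track$y))) {
    stop_config("track has missing coordinates")
  }
  if (any(table(track$period) < 2L)) {
    stop_config("each period needs at least 2 samples")
  }
  invisible(track)
}

#' Instantaneous speed from a (filtered) track
#'
#' Central finite differences on interior samples, one-sided at the ends of
#' each period.
#'
#' @param track data frame `player_id, t, x, y, period` (filtered).
#' @return The track with an added `speed` column in m/s.
#' @export
compute_speed <- function(track) {
  check_track(track)
  parts <- split(track, track$period)
  parts <- lapply(parts, function(p) {
    p <- p[order(p$t), , drop = FALSE]
    n <- nrow(p)
    if (n < 2L) stop_config("need at least 2 samples per period for speed")
    sp <- numeric(n)
    i <- 2:(n - 1)
    sp[i] <- sqrt((p$x[i + 1] - p$x[i - 1])^2 + (p$y[i + 1] - p$y[i - 1])^2) /
      (p$t[i + 1] - p$t[i - 1])
    sp[1] <- sqrt((p$x[2] - p$x[1])^2 + (p$y[2] - p$y[1])^2) /
      (p$t[2] - p$t[1])
    sp[n] <- sqrt((p$x[n] - p$x[n - 1])^2 + (p$y[n] - p$y[n - 1])^2) /
      (p$t[n] - p$t[n - 1])
    p$speed <- sp
    p
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$t), , drop = FALSE]
}

#' Distance covered inside a time window
#'
#' Sum of Euclidean steps of the (filtered) track whose segments fall inside
#' the half-open window `[start, end)`.
#'
#' @param track data frame with `t, x, y` (use the filtered track).
#' @param window length-2 numeric `c(start, end)` in seconds; `NULL` uses
#'   the whole track.
#' @return Distance in metres.
#' @export
distance_covered <- function(track, window = NULL) {
  if (is.null(window)) window <- c(min(track$t), max(track$t) + 1e-9)
  if (window[2] <= window[1]) stop_config("empty window")
  p <- track[track$t >= window[1] & track$t < window[2], , drop = FALSE]
  p <- p[order(p$t), , drop = FALSE]
  if (nrow(p) < 2L) return(0)
  # do not bridge rest gaps between periods
  dt <- diff(p$t)
  step <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  sum(step[dt <= 3 * stats::median(dt)])
}

#' Distance covered per minute
#'
#' @param dc distance covered in metres.
#' @param effective_minutes playing time in minutes used as the denominator
#'   (scheduled period length or analysed effective time; the choice is the
#'   caller's).
#' @return m/min.
#' @export
distance_per_minute <- function(dc, effective_minutes) {
  if (effective_minutes <= 0) stop_config("effective_minutes must be positive")
  dc / effective_minutes
}

#' Detect sprint bouts above a speed threshold
#'
#' A sprint bout is a maximal contiguous run of samples with speed strictly
#' above the threshold (the athlete's speed at V-dot-O2max). Bouts shorter
#' than `min_duration_s` are discarded.
#'
#' @param track track with a `speed` column (see [compute_speed()]).
#' @param threshold speed threshold in m/s (> 0).
#' @param min_duration_s minimum bout duration in seconds (default one
#'   sample, i.e. no minimum).
#' @return List with `bouts` (data frame `start, end, duration` in seconds),
#'   `S_N` (bout count) and `S_T` (total sprint time, s).
#' @export
detect_sprints <- function(track, threshold, min_duration_s = 0) {
  if (threshold <= 0) stop_config("threshold must be positive")
  if (is.null(track$speed)) stop_config("track has no speed column; run compute_speed()")
  p <- track[order(track$t), , drop = FALSE]
  dt_med <- stats::median(diff(p$t))
  above <- p$speed > threshold
  # break runs across rest gaps
  gap <- c(FALSE, diff(p$t) > 3 * dt_med)
  grp <- cumsum(gap)
  starts <- ends <- numeric(0)
  for (g in unique(grp)) {
    sel <- which(grp == g)
    r <- rle(above[sel])
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- sel[s[k]]; i1 <- sel[e[k]]
      starts <- c(starts, p$t[i0])
      ends <- c(ends, p$t[i1] + dt_med)   # sample covers [t, t + dt)
    }
  }
  bouts <- data.frame(start = starts, end = ends,
                      duration = ends - starts)
  bouts <- bouts[bouts$duration >= max(min_duration_s, dt_med / 2), ,
                 drop = FALSE]
  rownames(bouts) <- NULL
  list(bouts = bouts, S_N = nrow(bouts), S_T = sum(bouts$duration))
}

#' Running-performance summary per period, half and match
#'
#' Filters the track, computes speed, and aggregates distance covered (DC),
#' distance per minute (DC_MIN), sprint count (S_N) and sprint time (S_T)
#' per period, per half (first vs second half of the period sequence) and
#' for the whole match.
#'
#' @param track raw track `player_id, t, x, y, period`.
#' @param vvo2max_ms sprint threshold in m/s (the athlete's speed at
#'   V-dot-O2max).
#' @param period_minutes scheduled period length in minutes, used as the
#'   DC_MIN denominator when `dcmin_denominator = "scheduled"`.
#' @param dcmin_denominator `"scheduled"` (nominal period length) or
#'   `"effective"` (time span actually analysed).
#' @param min_sprint_s minimum sprint-bout duration in seconds.
#' @param filter_order,cutoff_hz track filter settings.
#' @return Data frame of class `running_summary` with one row per scope:
#'   `player_id, scope, DC_m, DCmin_m_per_min, S_N, S_T_s`.
#' @export
summarize_running <- function(track, vvo2max_ms, period_minutes = 10,
                              dcmin_denominator = c("scheduled", "effective"),
                              min_sprint_s = 0, filter_order = 3L,
                              cutoff_hz = 0.4) {
  dcmin_denominator <- match.arg(dcmin_denominator)
  check_track(track)
  ft <- compute_speed(filter_track(track, filter_order, cutoff_hz))
  periods <- unique(track$period)
  per <- lapply(periods, function(pl) {
    p <- ft[ft$period == pl, , drop = FALSE]
    dc <- distance_covered(p)
    eff_min <- if (dcmin_denominator == "scheduled") period_minutes
               else (max(p$t) - min(p$t)) / 60
    spr <- detect_sprints(p, vvo2max_ms, min_sprint_s)
    data.frame(player_id = p$player_id[1], scope = pl, DC_m = dc,
               DCmin_m_per_min = distance_per_minute(dc, eff_min),
               S_N = spr$S_N, S_T_s = spr$S_T,
               minutes = eff_min)
  })
  per <- do.call(rbind, per)
  half_of <- rep(c("half1", "half2"),
                 c(ceiling(length(periods) / 2),
                   floor(length(periods) / 2)))
  agg <- function(rows, scope) {
    data.frame(player_id = rows$player_id[1], scope = scope,
               DC_m = sum(rows$DC_m),
               DCmin_m_per_min = sum(rows$DC_m) / sum(rows$minutes),
               S_N = sum(rows$S_N), S_T_s = sum(rows$S_T_s),
               minutes = sum(rows$minutes))
  }
  halves <- do.call(rbind, lapply(split(seq_along(periods), half_of),
                                  function(i) agg(per[i, ], half_of[i][1])))
  match_row <- agg(per, "match")
  out <- rbind(per, halves, match_row)
  out$minutes <- NULL
  rownames(out) <- NULL
  class(out) <- c("running_summary", class(out))
  out
}

#' @export
print.running_summary <- function(x, digits = 1, ...) {
  cat("Running performance summary\n")
  y <- as.data.frame(x)
  y$DC_m <- round(y$DC_m, digits)
  y$DCmin_m_per_min <- round(y$DCmin_m_per_min, digits)
  y$S_T_s <- round(y$S_T_s, digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}
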