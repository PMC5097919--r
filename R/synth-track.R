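#' Configuration for the player-track simulator
#'
#' Describes an intermittent-locomotion bout schedule sampled as 2-D court
#' positions. The default schedule is a repeating walk/jog/run/sprint cycle
#' tuned to the demands of simulated futsal match play: roughly 100 m per
#' minute, one ~1.5 s sprint bout every ~24 s, with a fractional speed
#' decrement applied to the second half.
#'
#' @param duration_s total playing time in seconds (split into `n_periods`
#'   equal periods; default four 10-min periods).
#' @param sample_rate sampling frequency in Hz.
#' @param bout_speeds data frame with columns `speed` (m/s) and `duration`
#'   (s): one cycle of the bout schedule.
#' @param transition_scheme `"cycle"` repeats the schedule in order with
#'   per-bout duration jitter; `"markov"` draws each bout at random with
#'   probability proportional to its scheduled duration.
#' @param half2_decrement fraction in `[0, 1)` by which all bout speeds are
#'   reduced in the second half.
#' @param noise_sd positional jitter SD in metres added independently to x
#'   and y (default 0.14 m, a typical static-position digitisation error for
#'   gym-camera tracking).
#' @param n_periods number of equal playing periods (labelled P1, P2, ...).
#' @param rest_s rest gap inserted in the time base between periods; a vector
#'   recycled across the `n_periods - 1` gaps. Default 5 min between periods
#'   within a half and 10 min at half-time.
#' @param duration_jitter multiplicative bout-duration jitter half-width
#'   (each bout duration is scaled by `U(1 - j, 1 + j)`).
#' @param court length-2 court dimensions in metres (long side first).
#' @param seed integer seed for reproducibility.
#' @return A `track_sim_config` list.
#' @export
track_sim_config <- function(duration_s = 2400,
                             sample_rate = 30,
                             bout_speeds = default_bout_schedule(),
                             transition_scheme = c("cycle", "markov"),
                             half2_decrement = 0.066,
                             noise_sd = 0.14,
                             n_periods = 4L,
                             rest_s = c(300, 600, 300),
                             duration_jitter = 0.2,
                             court = c(40, 20),
                             seed = 1L) {
  transition_scheme <- match.arg(transition_scheme)
  if (duration_s <= 0) stop_config("duration_s must be positive")
  if (sample_rate <= 0) stop_config("sample_rate must be positive")
  if (half2_decrement < 0 || half2_decrement >= 1) {
    stop_config("half2_decrement must lie in [0, 1)")
  }
  if (noise_sd < 0) stop_config("noise_sd must be non-negative")
  bout_speeds <- as.data.frame(bout_speeds)
  if (!all(c("speed", "duration") %in% names(bout_speeds)) ||
      nrow(bout_speeds) == 0L) {
    stop_config("bout_speeds needs columns 'speed' and 'duration'")
  }
  if (any(bout_speeds$speed < 0) || any(bout_speeds$duration <= 0)) {
    stop_config("bout speeds must be >= 0 and durations > 0")
  }
  structure(list(duration_s = duration_s, sample_rate = sample_rate,
                 bout_speeds = bout_speeds,
                 transition_scheme = transition_scheme,
                 half2_decrement = half2_decrement, noise_sd = noise_sd,
                 n_periods = as.integer(n_periods), rest_s = rest_s,
                 duration_jitter = duration_jitter, court = court,
                 seed = seed),
            class = "track_sim_config")
}

#' Default walk/jog/run/sprint bout cycle
#'
#' One 24-s cycle covering 40 m (1.67 m/s, ~100 m/min) with a single 1.5-s
#' sprint at 5.5 m/s, so a 20-min half holds ~50 sprint bouts totalling
#' ~75 s of sprinting.
#'
#' @return Data frame with columns `state`, `speed` (m/s), `duration` (s).
#' @export
default_bout_schedule <- function() {
  data.frame(
    state = c("stand", "walk", "run", "walk", "jog", "sprint", "jog"),
    speed = c(0.3, 1.1, 3.2, 1.1, 2.0, 5.5, 2.0),
    duration = c(5.5, 6.0, 3.5, 3.0, 3.0, 1.5, 1.5)
  )
}

# Map arc length travelled (from angle theta0) to ellipse angle, by
# inverting a dense cumulative arc-length table; exact to the table
# resolution, vectorised over s.
ellipse_angle_at_arclength <- function(s, a, b, theta0) {
  m <- 8192L
  th <- seq(0, 2 * pi, length.out = m + 1L)
  seg <- sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2)
  # trapezoid cumulative arc length over the angle grid
  cum <- c(0, cumsum((seg[-1] + seg[-(m + 1L)]) / 2 * diff(th)))
  per <- cum[m + 1L]
  s0 <- stats::approx(th, cum, theta0 %% (2 * pi))$y
  stot <- s + s0
  lap <- floor(stot / per)
  rem <- stot - lap * per
  stats::approx(cum, th, rem)$y + 2 * pi * lap
}

# Realize a jittered bout sequence covering at least `total_s` seconds.
draw_bout_sequence <- function(cfg, total_s, speed_scale) {
  sched <- cfg$bout_speeds
  j <- cfg$duration_jitter
  speeds <- numeric(0); durs <- numeric(0); states <- character(0)
  elapsed <- 0
  repeat {
    idx <- if (cfg$transition_scheme == "cycle") {
      seq_len(nrow(sched))
    } else {
      sample.int(nrow(sched), nrow(sched), replace = TRUE,
                 prob = sched$duration)
    }
    for (i in idx) {
      d <- sched$duration[i] * stats::runif(1, 1 - j, 1 + j)
      speeds <- c(speeds, sched$speed[i] * speed_scale)
      durs <- c(durs, d)
      states <- c(states, if (is.null(sched$state)) NA_character_
                  else sched$state[i])
      elapsed <- elapsed + d
      if (elapsed >= total_s) break
    }
    if (elapsed >= total_s) break
  }
  # trim the last bout to the period boundary
  over <- elapsed - total_s
  durs[length(durs)] <- durs[length(durs)] - over
  keep <- durs > 1e-9
  data.frame(state = states[keep], speed = speeds[keep],
             duration = durs[keep])
}

#' Simulate a 2-D player track with known ground truth
#'
#' The player advances along a smooth elliptical circuit inside the court at
#' the piecewise-constant speeds of the realized bout schedule; positions are
#' sampled at `sample_rate` and corrupted with i.i.d. Gaussian jitter. Second
#' half bout speeds are scaled by `1 - half2_decrement`. Rest intervals
#' appear as gaps in the time base (no samples), so each period's samples are
#' contiguous and uniformly spaced.
#'
#' @param cfg a [track_sim_config()].
#' @return A list with:
#' \describe{
#'   \item{track}{data frame `player_id, t, x, y, period` (the `track.csv`
#'     schema).}
#'   \item{truth}{list with `distance_m` per period, `schedule` (the realized
#'     bouts with absolute start/end times and true speeds), and
#'     `sprint_bouts(threshold)` is recoverable from the schedule via
#'     [true_sprint_bouts()].}
#' }
#' @export
gen_player_track <- function(cfg) {
  stopifnot(inherits(cfg, "track_sim_config"))
  with_seed(cfg$seed, {
    fs <- cfg$sample_rate
    dt <- 1 / fs
    n_per <- cfg$n_periods
    period_s <- cfg$duration_s / n_per
    rests <- rep_len(cfg$rest_s, max(n_per - 1L, 0L))
    half_cut <- ceiling(n_per / 2)

    a <- cfg$court[1] / 2 - 3; b <- cfg$court[2] / 2 - 2
    cx <- cfg$court[1] / 2; cy <- cfg$court[2] / 2
    theta <- stats::runif(1, 0, 2 * pi)

    out <- vector("list", n_per)
    sched_all <- vector("list", n_per)
    dist_true <- numeric(n_per)
    t0 <- 0
    for (p in seq_len(n_per)) {
      scale <- if (p > half_cut) 1 - cfg$half2_decrement else 1
      sched <- draw_bout_sequence(cfg, period_s, scale)
      ends <- cumsum(sched$duration)
      starts <- c(0, ends[-length(ends)])
      n <- round(period_s * fs)
      tt <- (seq_len(n) - 1L) * dt
      # true instantaneous speed per sample (bout of the sample's interval)
      bout_idx <- findInterval(tt, c(0, ends), rightmost.closed = TRUE)
      bout_idx[bout_idx > nrow(sched)] <- nrow(sched)
      v <- sched$speed[bout_idx]
      # advance along the ellipse by arc length: s(t) from the speed
      # profile, mapped to the ellipse angle through a lookup table
      s_along <- c(0, cumsum(v[-n]) * dt)
      ang <- ellipse_angle_at_arclength(s_along, a, b, theta)
      xs <- cx + a * cos(ang); ys <- cy + b * sin(ang)
      theta <- ang[n] + v[n] * dt /
        sqrt(a^2 * sin(ang[n])^2 + b^2 * cos(ang[n])^2)
      if (cfg$noise_sd > 0) {
        xs <- xs + stats::rnorm(n, 0, cfg$noise_sd)
        ys <- ys + stats::rnorm(n, 0, cfg$noise_sd)
      }
      out[[p]] <- data.frame(player_id = "sim", t = t0 + tt, x = xs, y = ys,
                             period = sprintf("P%d", p))
      sched$start <- t0 + starts
      sched$end <- t0 + ends
      sched$period <- sprintf("P%d", p)
      sched_all[[p]] <- sched
      dist_true[p] <- sum(sched$speed * sched$duration)
      t0 <- t0 + period_s + if (p < n_per) rests[p] else 0
    }
    track <- do.call(rbind, out)
    schedule <- do.call(rbind, sched_all)
    names(dist_true) <- sprintf("P%d", seq_len(n_per))
    list(track = track,
         truth = list(distance_m = dist_true, schedule = schedule))
  })
}

#' True sprint bouts from a simulated schedule
#'
#' Returns the intervals of a realized bout schedule whose true speed exceeds
#' a threshold, merging adjacent above-threshold bouts.
#'
#' @param schedule realized schedule from [gen_player_track()] truth.
#' @param threshold speed threshold in m/s.
#' @return Data frame `start, end, duration` of true sprint bouts.
#' @export
true_sprint_bouts <- function(schedule, threshold) {
  above <- schedule$speed > threshold
  if (!any(above)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0)))
  }
  n <- nrow(schedule)
  # a rest gap between periods splits a bout even if both sides are fast
  gap <- c(FALSE, abs(schedule$start[-1] - schedule$end[-n]) > 1e-9)
  grp <- cumsum(!above | gap)
  keep <- which(above)
  starts <- tapply(schedule$start[keep], grp[keep], min)
  ends <- tapply(schedule$end[keep], grp[keep], max)
  out <- data.frame(start = as.numeric(starts), end = as.numeric(ends))
  out <- out[order(out$start), , drop = FALSE]
  out$duration <- out$end - out$start
  rownames(out) <- NULL
  out
}
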