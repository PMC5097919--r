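#' Goal target geometry
#'
#' The 1 x 1 m target fixed in the centre of the goal, on the goal plane at
#' `plane_y` metres from the kick mark. The target-centre height above the
#' floor defaults to 1.0 m (centre of a 2-m futsal goal mouth).
#'
#' @param plane_y goal-line distance in metres.
#' @param centre_x,centre_z target centre coordinates on the goal plane (m).
#' @param half_width half side length of the square target (m).
#' @return A `goal_target` list.
#' @export
goal_target <- function(plane_y = 10, centre_x = 0, centre_z = 1.0,
                        half_width = 0.5) {
  structure(list(plane_y = plane_y, centre = c(x = centre_x, z = centre_z),
                 half_width = half_width),
            class = "goal_target")
}

# Frames used for velocity regression: the n_frames airborne frames after
# contact, with time re-origined at the first fitted frame.
airborne_frames <- function(traj, n_frames) {
  traj <- traj[order(traj$t), , drop = FALSE]
  ci <- which(traj$is_contact == 1L)
  ci <- if (length(ci)) ci[length(ci)] else 0L
  post <- traj[(ci + 1L):nrow(traj), , drop = FALSE]
  if (ci >= nrow(traj) || nrow(post) < n_frames) {
    stop_config("need %d airborne frames after contact, have %d",
                n_frames, max(nrow(traj) - ci, 0L))
  }
  post[seq_len(n_frames), , drop = FALSE]
}

#' Horizontal ball-velocity components by linear regression
#'
#' Ordinary least-squares slopes of the unfiltered x(t) and y(t)
#' displacements over the airborne frames after contact.
#'
#' @param traj data frame `kick_id, t, x, y, z, is_contact`.
#' @param n_frames number of post-contact frames to fit.
#' @return List with `vx`, `vy` (m/s) and intercepts `x0`, `y0` at the fit
#'   time origin `t0` (the first fitted frame).
#' @export
fit_horizontal_velocity <- function(traj, n_frames = 10L) {
  f <- airborne_frames(traj, n_frames)
  tt <- f$t - f$t[1]
  fx <- stats::lm.fit(cbind(1, tt), f$x)$coefficients
  fy <- stats::lm.fit(cbind(1, tt), f$y)$coefficients
  list(vx = unname(fx[2]), vy = unname(fy[2]),
       x0 = unname(fx[1]), y0 = unname(fy[1]), t0 = f$t[1])
}

#' Vertical ball velocity by gravity-constrained quadratic regression
#'
#' Fits `z(t) = z0 + vz t - g t^2 / 2` with the curvature fixed at the
#' gravitational value: equivalently an OLS straight-line fit of
#' `z(t) + g t^2 / 2`. The slope is the vertical velocity at the fit time
#' origin (first fitted frame).
#'
#' @inheritParams fit_horizontal_velocity
#' @param g gravitational acceleration (m/s^2).
#' @return List with `vz` (m/s), `z0`, `t0`.
#' @export
fit_vertical_velocity <- function(traj, n_frames = 10L, g = 9.81) {
  f <- airborne_frames(traj, n_frames)
  tt <- f$t - f$t[1]
  fz <- stats::lm.fit(cbind(1, tt), f$z + 0.5 * g * tt^2)$coefficients
  list(vz = unname(fz[2]), z0 = unname(fz[1]), t0 = f$t[1])
}

#' Ball speed and goal-plane crossing of one kick
#'
#' Combines the regression velocity components into the release speed and
#' extrapolates the fitted flight to the goal plane for the accuracy
#' measure. Crossing points below floor level or outside a 3 x 2 m goal
#' mouth are flagged, not rejected.
#'
#' @param traj data frame `kick_id, t, x, y, z, is_contact`.
#' @param goal a [goal_target()].
#' @param n_frames frames fitted after contact.
#' @param g gravitational acceleration (m/s^2).
#' @return Object of class `kick_result`: list with `kick_id`, `speed_kmh`,
#'   `v` (vx, vy, vz), `crossing` (x, z), `accuracy_m`, `flags`.
#' @export
ball_speed <- function(traj, goal = goal_target(), n_frames = 10L, g = 9.81) {
  h <- fit_horizontal_velocity(traj, n_frames)
  v <- fit_vertical_velocity(traj, n_frames, g)
  # report vz at contact: the fit origin is the first airborne frame, one
  # sampling interval after contact, by which time gravity has acted
  tc <- traj$t[traj$is_contact == 1L]
  tc <- if (length(tc)) tc[length(tc)] else v$t0
  vz_contact <- v$vz + g * (v$t0 - tc)
  speed_ms <- sqrt(h$vx^2 + h$vy^2 + vz_contact^2)
  crossing <- goal_plane_crossing(h, v, goal, g)
  flags <- character(0)
  if (crossing["z"] < 0) flags <- c(flags, "below_ground")
  if (abs(crossing["x"] - goal$centre["x"]) > 1.5 ||
      crossing["z"] > 2) flags <- c(flags, "outside_goal_mouth")
  structure(list(kick_id = traj$kick_id[1], speed_kmh = 3.6 * speed_ms,
                 v = c(vx = h$vx, vy = h$vy, vz = vz_contact),
                 crossing = crossing,
                 accuracy_m = kick_accuracy(crossing, goal),
                 flags = flags),
            class = "kick_result")
}

#' @export
print.kick_result <- function(x, ...) {
  cat(sprintf("Kick %s: %.1f km/h (vx %.2f, vy %.2f, vz %.2f m/s)\n",
              x$kick_id, x$speed_kmh, x$v[1], x$v[2], x$v[3]))
  cat(sprintf("  crosses goal plane at x = %.3f m, z = %.3f m; accuracy %.3f m\n",
              x$crossing["x"], x$crossing["z"], x$accuracy_m))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Goal-plane crossing point of the fitted flight
#'
#' Solves the fitted y(t) for the goal-plane distance and evaluates the
#' fitted x(t) and z(t) there.
#'
#' @param h horizontal fit from [fit_horizontal_velocity()].
#' @param v vertical fit from [fit_vertical_velocity()].
#' @param goal a [goal_target()].
#' @param g gravitational acceleration (m/s^2).
#' @return Named vector `c(x, z)` in metres.
#' @export
goal_plane_crossing <- function(h, v, goal = goal_target(), g = 9.81) {
  if (h$vy <= 0) stop_config("ball never reaches the goal plane (vy <= 0)")
  tstar <- (goal$plane_y - h$y0) / h$vy
  c(x = h$x0 + h$vx * tstar,
    z = v$z0 + v$vz * tstar - 0.5 * g * tstar^2)
}

#' Kick accuracy: distance to the nearest point of the target square
#'
#' Euclidean distance from the goal-plane crossing point to the nearest
#' point of the closed 1 x 1 m target; 0 when the crossing lies inside or on
#' the boundary.
#'
#' @param crossing named or plain length-2 vector `(x, z)` in metres.
#' @param goal a [goal_target()].
#' @return Distance in metres (>= 0).
#' @export
kick_accuracy <- function(crossing, goal = goal_target()) {
  dx <- crossing[1] - goal$centre["x"]
  dz <- crossing[2] - goal$centre["z"]
  ex <- max(abs(dx) - goal$half_width, 0)
  ez <- max(abs(dz) - goal$half_width, 0)
  unname(sqrt(ex^2 + ez^2))
}

#' Per-set means of kick speed and accuracy
#'
#' @param results list of `kick_result` objects (one set of attempts).
#' @return List with `speed_kmh` and `accuracy_m` set means and `n`.
#' @export
summarize_set <- function(results) {
  if (!length(results)) stop_config("empty kick set")
  list(speed_kmh = mean(vapply(results, `[[`, 0, "speed_kmh")),
       accuracy_m = mean(vapply(results, `[[`, 0, "accuracy_m")),
       n = length(results))
}
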