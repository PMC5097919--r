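#' Configuration for the ball-flight simulator
#'
#' Drag-free projectile flight digitised at high speed: x and y advance
#' linearly, z follows `p0z + v0z t - g t^2 / 2`, and i.i.d. Gaussian
#' digitisation noise is added per coordinate. Axes follow the kick frame:
#' y horizontal toward the goal centre, z vertical up, x lateral.
#'
#' @param v0 length-3 true release velocity (m/s), ordered (vx, vy, vz).
#' @param p0 length-3 release position (m).
#' @param sample_rate camera frequency in Hz.
#' @param n_frames number of airborne frames after contact (>= 3).
#' @param noise_sd digitisation noise SD in metres.
#' @param gravity gravitational acceleration (m/s^2), acting on z.
#' @param plane_y goal-line distance (m) used for the true crossing point.
#' @param seed integer seed.
#' @return A `kick_sim_config` list.
#' @export
kick_sim_config <- function(v0, p0 = c(0, 0, 0.11), sample_rate = 240,
                            n_frames = 10L, noise_sd = 0.002,
                            gravity = 9.81, plane_y = 10, seed = 1L) {
  if (length(v0) != 3L || length(p0) != 3L) {
    stop_config("v0 and p0 must be length-3 vectors")
  }
  if (n_frames < 3L) stop_config("n_frames must be >= 3 (regression underdetermined)")
  if (sample_rate <= 0) stop_config("sample_rate must be positive")
  if (gravity <= 0) stop_config("gravity must be positive")
  if (noise_sd < 0) stop_config("noise_sd must be non-negative")
  structure(list(v0 = as.numeric(v0), p0 = as.numeric(p0),
                 sample_rate = sample_rate, n_frames = as.integer(n_frames),
                 noise_sd = noise_sd, gravity = gravity, plane_y = plane_y,
                 seed = seed),
            class = "kick_sim_config")
}

#' Simulate one digitised kick trajectory with known ground truth
#'
#' Emits a contact frame at the release position followed by `n_frames`
#' airborne frames. The truth record carries the exact release speed and the
#' noise-free goal-plane crossing point.
#'
#' @param cfg a [kick_sim_config()].
#' @param kick_id identifier stored in the trajectory table.
#' @return List with `trajectory` (data frame `kick_id, t, x, y, z,
#'   is_contact`) and `truth` (`speed_ms`, `speed_kmh`, `v0`, `crossing`
#'   as `c(x, z)` at `plane_y`, or NULL when the ball never reaches it).
#' @export
gen_kick <- function(cfg, kick_id = "k1") {
  stopifnot(inherits(cfg, "kick_sim_config"))
  with_seed(cfg$seed, {
    dt <- 1 / cfg$sample_rate
    t <- (0:cfg$n_frames) * dt
    x <- cfg$p0[1] + cfg$v0[1] * t
    y <- cfg$p0[2] + cfg$v0[2] * t
    z <- cfg$p0[3] + cfg$v0[3] * t - 0.5 * cfg$gravity * t^2
    if (cfg$noise_sd > 0) {
      x <- x + stats::rnorm(length(t), 0, cfg$noise_sd)
      y <- y + stats::rnorm(length(t), 0, cfg$noise_sd)
      z <- z + stats::rnorm(length(t), 0, cfg$noise_sd)
    }
    speed <- sqrt(sum(cfg$v0^2))
    crossing <- NULL
    if (cfg$v0[2] > 0) {
      tstar <- (cfg$plane_y - cfg$p0[2]) / cfg$v0[2]
      crossing <- c(x = cfg$p0[1] + cfg$v0[1] * tstar,
                    z = cfg$p0[3] + cfg$v0[3] * tstar -
                      0.5 * cfg$gravity * tstar^2)
    }
    traj <- data.frame(kick_id = kick_id, t = t, x = x, y = y, z = z,
                       is_contact = c(1L, rep(0L, cfg$n_frames)))
    list(trajectory = traj,
         truth = list(speed_ms = speed, speed_kmh = 3.6 * speed,
                      v0 = cfg$v0, crossing = crossing))
  })
}
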