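# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# Exact paired test by exhaustive sign flips of the differences: two-sided
# p = proportion of sign assignments with |t| >= |t_observed|.
sign_flip_p <- function(d) {
  n <- length(d)
  stopifnot(n <= 12)
  tstat <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tobs <- abs(tstat(d))
  tperm <- abs(apply(signs * rep(d, each = nrow(signs)), 1, tstat))
  mean(tperm >= tobs - 1e-12)
}

# Nearest point on an axis-aligned rectangle by box-constrained numerical
# minimisation of the squared distance.
rect_distance_optim <- function(px, pz, cx, cz, hw) {
  f <- function(q) (q[1] - px)^2 + (q[2] - pz)^2
  gr <- function(q) 2 * c(q[1] - px, q[2] - pz)
  o <- optim(c(cx, cz), f, gr, method = "L-BFGS-B",
             lower = c(cx - hw, cz - hw), upper = c(cx + hw, cz + hw),
             control = list(factr = 10, pgtol = 1e-14, maxit = 500))
  sqrt(o$value)
}

# Raw path length of a track (no filtering).
raw_path_length <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))

# A square test track: four 10-m legs walked at constant speed, 30 Hz.
square_track <- function(speed = 2, fs = 30) {
  leg <- function(x0, y0, x1, y1) {
    n <- round(10 / speed * fs)
    s <- seq(0, 1, length.out = n + 1)[-(n + 1)]
    cbind(x0 + s * (x1 - x0), y0 + s * (y1 - y0))
  }
  xy <- rbind(leg(0, 0, 10, 0), leg(10, 0, 10, 10),
              leg(10, 10, 0, 10), leg(0, 10, 0, 0), c(0, 0))
  data.frame(player_id = "sq", t = (seq_len(nrow(xy)) - 1) / fs,
             x = xy[, 1], y = xy[, 2], period = "P1")
}
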