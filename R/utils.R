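# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulation helpers are deterministic
#' without disturbing the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_config("seed must be a single finite number, got %s", format(seed))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Centered moving average over an odd number of points; ends use the
# available shorter window (no NA padding).
moving_average <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  cs <- cumsum(c(0, x))
  half <- (k - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Rolling mean of fixed window length w (in samples), aligned so element i
# covers samples [i, i + w - 1]; returns n - w + 1 values.
rolling_mean <- function(x, w) {
  n <- length(x)
  if (w > n) stop_config("rolling window (%d) longer than series (%d)", w, n)
  cs <- cumsum(c(0, x))
  (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
}

# Round half away from zero (display convention for integer percentages).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_uniformly_sampled <- function(t, tol = 0.01) {
  if (length(t) < 3L) return(TRUE)
  dt <- diff(t)
  m <- stats::median(dt)
  all(abs(dt - m) <= tol * m)
}
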