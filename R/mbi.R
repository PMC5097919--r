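#' Paired change summary
#'
#' Per-subject differences (after - before), their mean and sample SD
#' (n - 1 denominator).
#'
#' @param before,after paired numeric vectors of equal length (n >= 2).
#' @return List with `delta_mean`, `delta_sd`, `n`.
#' @export
delta_summary <- function(before, after) {
  if (length(before) != length(after)) stop_config("before/after lengths differ")
  if (length(before) < 2L) stop_config("need at least 2 pairs")
  d <- after - before
  list(delta_mean = mean(d), delta_sd = stats::sd(d), n = length(d))
}

#' Paired (dependent-samples) t-test
#'
#' @inheritParams delta_summary
#' @return List with `t`, `p` (two-sided), `df`, and `degenerate = TRUE`
#'   when the differences have zero variance (then `t` is 0 or +/-Inf).
#' @export
paired_t <- function(before, after) {
  d <- after - before
  n <- length(d)
  if (n < 2L) stop_config("need at least 2 pairs")
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p = if (mean(d) == 0) 1 else 0, df = n - 1L,
                degenerate = TRUE))
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' One-way analysis of variance
#'
#' Classical between/within F with (k - 1, N - k) degrees of freedom.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
oneway_anova <- function(groups) {
  if (length(groups) < 2L) stop_config("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2L)) {
    stop_config("every group needs n >= 2")
  }
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  ow <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), p = ow$p.value,
       df1 = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors (n >= 3, non-degenerate).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_config("x/y lengths differ")
  if (length(x) < 3L) stop_config("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_config("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cohen's d with the pooled SD of the two moments
#'
#' `d = (mean2 - mean1) / sqrt((sd1^2 + sd2^2) / 2)`.
#'
#' @param mean1,sd1 first moment (e.g. before) mean and SD.
#' @param mean2,sd2 second moment (e.g. after) mean and SD.
#' @return d (signed).
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  if (sd1 < 0 || sd2 < 0) stop_config("SDs must be non-negative")
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (pooled == 0) stop_config("both SDs are zero: d undefined")
  (mean2 - mean1) / pooled
}

#' Qualitative magnitude of an effect size
#'
#' Thresholds: |d| > 0.2 small, > 0.5 moderate, > 0.8 large; at or below
#' 0.2, trivial.
#'
#' @param d Cohen's d.
#' @return One of "trivial", "small", "moderate", "large".
#' @export
magnitude_label <- function(d) {
  a <- abs(d)
  if (a > 0.8) "large" else if (a > 0.5) "moderate"
  else if (a > 0.2) "small" else "trivial"
}

#' Smallest worthwhile change
#'
#' 0.2 times the between-subject SD (Cohen's d principle). The default
#' between-subject SD in [effect_report()] is the pooled SD of the two
#' testing moments.
#'
#' @param sd_between between-subject SD (> 0).
#' @return The SWC on the variable's own scale.
#' @export
swc <- function(sd_between) {
  if (sd_between <= 0) stop_config("sd_between must be positive")
  0.2 * sd_between
}

#' Magnitude-based inference chances
#'
#' Chances (in percent) that the true mean change is beyond +SWC
#' (positive), within +/-SWC (trivial), or beyond -SWC (negative), using a
#' normal sampling distribution for the observed mean change with
#' `SE = delta_sd / sqrt(n)` (a t distribution is available via `dist`).
#'
#' @param delta_mean,delta_sd mean and SD of the paired changes.
#' @param n number of pairs.
#' @param swc smallest worthwhile change (>= 0), on the variable's scale.
#' @param dist `"normal"` (default) or `"t"` (df = n - 1).
#' @return Named numeric `c(positive, trivial, negative)` in percent,
#'   unrounded (sums to 100).
#' @export
mbi_chances <- function(delta_mean, delta_sd, n, swc,
                        dist = c("normal", "t")) {
  dist <- match.arg(dist)
  if (n < 2) stop_config("n must be >= 2")
  if (swc < 0) stop_config("swc must be non-negative")
  se <- delta_sd / sqrt(n)
  if (se == 0) {
    pos <- 100 * (delta_mean > swc)
    neg <- 100 * (delta_mean < -swc)
    return(c(positive = pos, trivial = 100 - pos - neg, negative = neg))
  }
  cdf <- if (dist == "normal") {
    function(q) stats::pnorm(q)
  } else {
    function(q) stats::pt(q, df = n - 1)
  }
  # both tails via the lower-tail CDF so the sign-flip antisymmetry
  # (positive(delta) == negative(-delta)) holds to the last bit
  neg <- cdf((-swc - delta_mean) / se) * 100
  pos <- cdf((delta_mean - swc) / se) * 100
  tri <- max(100 - (pos + neg), 0)
  c(positive = pos, trivial = tri, negative = neg)
}

#' Qualitative label for MBI chances
#'
#' When the chances of positive and negative changes are both above 5
#' percent the effect is "unclear". Otherwise the largest chance's category
#' is reported with the qualitative scale: <= 1 almost certainly not,
#' 1-5 very unlikely, 5-25 unlikely, 25-75 possibly, 75-95 likely, 95-99
#' very likely, > 99 almost certain. Ties for the largest chance are
#' reported "unclear".
#'
#' @param chances numeric `c(positive, trivial, negative)` in percent.
#' @return A label such as "very likely negative".
#' @export
mbi_label <- function(chances) {
  stopifnot(length(chances) == 3L)
  pos <- chances[1]; tri <- chances[2]; neg <- chances[3]
  if (pos > 5 && neg > 5) return("unclear")
  mx <- max(chances)
  if (sum(chances == mx) > 1L) return("unclear")
  dir <- c("positive", "trivial", "negative")[which.max(chances)]
  qual <- if (mx > 99) "almost certainly" else if (mx > 95) "very likely"
  else if (mx > 75) "likely" else if (mx > 25) "possibly"
  else if (mx > 5) "unlikely" else if (mx > 1) "very unlikely"
  else "almost certainly not"
  paste(qual, dir)
}

#' One Table-style effect row for a paired variable
#'
#' Composes the change summary, paired t-test, pooled-SD Cohen's d with its
#' magnitude label, the SWC, the MBI chances (rounded half-up to integer
#' percent for display) and the qualitative inference label.
#'
#' @inheritParams delta_summary
#' @param variable variable name carried into the row.
#' @param sd_basis SD used for the SWC: `"pooled"` (pooled SD of the two
#'   moments, default) or `"baseline"` (before SD).
#' @param dist sampling distribution for the MBI chances, `"normal"` or
#'   `"t"`.
#' @return Object of class `effect_report`: one-row data frame with columns
#'   `variable, mean_before, sd_before, mean_after, sd_after, delta_mean,
#'   delta_sd, t, p, d, magnitude, swc, positive, trivial, negative,
#'   inference` (chance columns in integer percent; unrounded chances in
#'   attribute `"chances"`).
#' @export
effect_report <- function(before, after, variable = "var",
                          sd_basis = c("pooled", "baseline"),
                          dist = c("normal", "t")) {
  sd_basis <- match.arg(sd_basis)
  dist <- match.arg(dist)
  ds <- delta_summary(before, after)
  tt <- paired_t(before, after)
  sdb <- stats::sd(before); sda <- stats::sd(after)
  d <- cohens_d(mean(before), sdb, mean(after), sda)
  sw <- swc(if (sd_basis == "pooled") sqrt((sdb^2 + sda^2) / 2) else sdb)
  ch <- mbi_chances(ds$delta_mean, ds$delta_sd, ds$n, sw, dist)
  out <- data.frame(variable = variable,
                    mean_before = mean(before), sd_before = sdb,
                    mean_after = mean(after), sd_after = sda,
                    delta_mean = ds$delta_mean, delta_sd = ds$delta_sd,
                    t = tt$t, p = tt$p, d = d,
                    magnitude = magnitude_label(d), swc = sw,
                    positive = round_half_up(ch[["positive"]]),
                    trivial = round_half_up(ch[["trivial"]]),
                    negative = round_half_up(ch[["negative"]]),
                    inference = mbi_label(ch))
  attr(out, "chances") <- ch
  class(out) <- c("effect_report", class(out))
  out
}

#' @export
print.effect_report <- function(x, ...) {
  cat(sprintf(
    "%s: %.2f +/- %.2f -> %.2f +/- %.2f (delta %.2f +/- %.2f)\n",
    x$variable, x$mean_before, x$sd_before, x$mean_after, x$sd_after,
    x$delta_mean, x$delta_sd))
  cat(sprintf("  t = %.2f, p = %.3f; d = %.2f (%s); SWC = %.3f\n",
              x$t, x$p, x$d, x$magnitude, x$swc))
  cat(sprintf("  chances +/trivial/-: %d/%d/%d%% -> %s\n",
              x$positive, x$trivial, x$negative, x$inference))
  invisible(x)
}
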