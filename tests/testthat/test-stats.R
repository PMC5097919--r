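test_that("paired change summaries reproduce printed-mean arithmetic", {
  # any pairing with the stated group means gives the stated mean change
  before <- 840.2 + c(-66.2, 0, 66.2)
  after <- 751.6 + c(-114.3, 0, 114.3)
  expect_equal(delta_summary(before, after)$delta_mean, -88.6,
               tolerance = 1e-9)
  expect_equal(delta_summary(288.6 + c(-1, 1), 248.0 + c(-1, 1))$delta_mean,
               -40.6, tolerance = 1e-9)
  same <- c(1, 2, 3)
  expect_equal(delta_summary(same, same), list(delta_mean = 0, delta_sd = 0,
                                               n = 3L))
  expect_error(delta_summary(1, 1), "at least 2")
})

test_that("paired t matches hand computation and symmetry", {
  b <- c(0, 0, 0)
  a <- c(1, 2, 3)
  tt <- paired_t(b, a)
  expect_equal(tt$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(tt$df, 2)
  flip <- paired_t(a, b)
  expect_equal(flip$t, -tt$t, tolerance = 1e-12)
  expect_equal(flip$p, tt$p, tolerance = 1e-12)
  idt <- paired_t(a, a)
  expect_true(idt$degenerate)
  expect_equal(idt$t, 0)
  expect_equal(idt$p, 1)
})

test_that("paired t agrees with the exhaustive sign-flip oracle", {
  set.seed(20)
  diffs <- c(0, 0)
  for (i in 1:30) {
    d <- rnorm(8, mean = runif(1, -1, 1))
    p_t <- paired_t(rep(0, 8), d)$p
    p_perm <- sign_flip_p(d)
    diffs <- diffs + c(abs(p_t - p_perm), 1)
  }
  expect_lt(diffs[1] / diffs[2], 0.05)
})

test_that("one-way ANOVA matches the classical F", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  a <- oneway_anova(g)
  expect_equal(a$F, 3.0, tolerance = 1e-9)
  expect_equal(c(a$df1, a$df2), c(2, 6))
  shifted <- oneway_anova(lapply(g, `+`, 100))
  expect_equal(shifted$F, a$F, tolerance = 1e-9)
  ident <- oneway_anova(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(ident$F, 0)
  expect_error(oneway_anova(list(1, c(1, 2))), "n >= 2")
})

test_that("Pearson correlation matches hand computation", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  expect_equal(pearson_r(x, c(1, 3, 2, 4))$r, 0.8, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 4)), "zero variance")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
})

test_that("Cohen's d uses the pooled SD of the two moments", {
  expect_equal(round(cohens_d(5.6, 2.6, 5.5, 3.5), 2), -0.03)
  expect_equal(cohens_d(3, 1, 3, 2), 0)
  expect_equal(cohens_d(0, 1, 1, 1), 1)
  expect_error(cohens_d(1, 0, 2, 0), "undefined")
  # brute-force agreement on random inputs
  set.seed(4)
  for (i in 1:200) {
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1, 0.1, 3)
    s2 <- runif(1, 0.1, 3)
    expect_equal(cohens_d(m1, s1, m2, s2),
                 (m2 - m1) / sqrt((s1^2 + s2^2) / 2), tolerance = 1e-12)
  }
})

test_that("effect-size magnitude thresholds are exclusive at boundaries", {
  expect_equal(magnitude_label(-1.32), "large")
  expect_equal(magnitude_label(0.2), "trivial")
  expect_equal(magnitude_label(0.21), "small")
  expect_equal(magnitude_label(0.5), "small")
  expect_equal(magnitude_label(0.6), "moderate")
  expect_equal(magnitude_label(0.8), "moderate")
  expect_equal(magnitude_label(-0.81), "large")
})

test_that("the smallest worthwhile change is 0.2 between-subject SDs", {
  expect_equal(swc(1), 0.2)
  expect_equal(swc(sqrt((66.2^2 + 114.3^2) / 2)), 18.68, tolerance = 0.005)
  expect_equal(swc(7), 7 * swc(1), tolerance = 1e-12)
  expect_error(swc(0), "positive")
})

test_that("MBI chances reproduce the published peak-force cell", {
  ch <- mbi_chances(-88.6, 80.1, 6, swc(sqrt((66.2^2 + 114.3^2) / 2)))
  expect_equal(unname(round(ch["negative"])), 98)
  expect_equal(mbi_label(ch), "very likely negative")
})

test_that("MBI chances are symmetric and well-normalised", {
  ch0 <- mbi_chances(0, 2, 6, 1)
  expect_equal(unname(ch0["positive"]), unname(ch0["negative"]),
               tolerance = 1e-12)
  deg <- mbi_chances(0, 2, 6, 0)
  expect_equal(unname(deg), c(50, 0, 50), tolerance = 1e-9)
  set.seed(30)
  for (i in 1:300) {
    dm <- rnorm(1, 0, 5); dsd <- runif(1, 0.1, 10); n <- sample(2:12, 1)
    sw <- runif(1, 0, 3)
    a <- mbi_chances(dm, dsd, n, sw)
    b <- mbi_chances(-dm, dsd, n, sw)
    expect_equal(sum(a), 100, tolerance = 1e-9)
    expect_equal(unname(a["positive"]), unname(b["negative"]),
                 tolerance = 1e-9)
    expect_equal(unname(a["trivial"]), unname(b["trivial"]),
                 tolerance = 1e-9)
  }
  # t-distribution mode is fatter-tailed than the normal
  at <- mbi_chances(-10, 10, 6, 2, dist = "t")
  an <- mbi_chances(-10, 10, 6, 2, dist = "normal")
  expect_lt(at[["negative"]], an[["negative"]])
})

test_that("MBI labels follow the qualitative scale and the unclear rule", {
  expect_equal(mbi_label(c(2, 0, 98)), "very likely negative")
  expect_equal(mbi_label(c(21, 4, 75)), "unclear")
  expect_equal(mbi_label(c(50, 0, 50)), "unclear")
  expect_equal(mbi_label(c(0, 99.5, 0.5)), "almost certainly trivial")
  expect_equal(mbi_label(c(87, 2, 11)), "unclear")
  expect_equal(mbi_label(c(1, 19, 80)), "likely negative")
  expect_equal(mbi_label(c(0.5, 30, 69.5)), "possibly negative")
})

test_that("effect reports compose the layer and are scale invariant", {
  set.seed(7)
  before <- rnorm(6, 100, 10)
  after <- before + rnorm(6, -8, 6)
  r1 <- effect_report(before, after, "v")
  r2 <- effect_report(before * 3.7, after * 3.7, "v")
  expect_equal(r1$d, r2$d, tolerance = 1e-9)
  expect_equal(r1$inference, r2$inference)
  expect_equal(c(r1$positive, r1$trivial, r1$negative),
               c(r2$positive, r2$trivial, r2$negative))
  same <- effect_report(before, before, "null")
  expect_equal(same$d, 0)
  expect_equal(same$t, 0)
})

test_that("under a true null the layer rarely claims a very likely change", {
  set.seed(11)
  n_rep <- 1500
  labels <- character(n_rep)
  for (i in seq_len(n_rep)) {
    d <- rnorm(6)
    ch <- mbi_chances(mean(d), sd(d), 6, swc(1))
    labels[i] <- mbi_label(ch)
  }
  strong <- grepl("very likely (positive|negative)|almost certain",
                  labels)
  expect_lt(mean(strong), 0.10)
})
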