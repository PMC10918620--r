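test_that("deviations subtract the reference and use the n-1 standard deviation", {
  # a reference material measured at -0.70 against an accepted -0.68
  s <- ssb_series("SELM-1", -0.70, prop_se = 0.08, reference_delta = -0.68)
  d <- deviations(s)
  expect_equal(d$deviations, -0.02)
  expect_equal(d$delta_avg, -0.70)
  expect_true(is.na(d$sd))  # single observation: no spread estimate

  # hand-computed 3-point example: sd over n-1
  h <- deviations(ssb_series("H", c(0, 0.1, 0.2), 0, reference_delta = 0))
  expect_equal(h$sd, 0.1)
  expect_equal(h$deviation_avg, 0.1)

  # constant deltas equal to the reference: all deviations zero
  z <- deviations(ssb_series("Z", rep(-0.5, 4), 0, reference_delta = -0.5))
  expect_identical(z$deviations, rep(0, 4))
  expect_identical(z$sd, 0)
})

test_that("mean substitution zeroes the average deviation exactly", {
  s <- ssb_series("BC210a", c(-2.2, -2.3, -2.2), prop_se = 0.08)
  expect_identical(s$reference_source, "sample_mean")
  d <- deviations(s)
  expect_lt(abs(d$deviation_avg), 1e-14)
  # and the zero-mean t-test is exactly uninformative: p prints as 1.0000
  p <- test_zero_mean(d$deviations)
  expect_equal(round(p, 4), 1)
  expect_gt(p, 1 - 1e-8)
})

test_that("sample_series picks literature references and falls back to the mean", {
  deltas <- data.frame(
    label = c("A", "A", "B", "B"),
    seq_index = 0:3,
    delta_permil = c(0.1, 0.3, -2.2, -2.4),
    prop_se = 0.05
  )
  ref <- reference_table("A", 0.15)
  sl <- sample_series(deltas, ref)
  expect_identical(sl$A$reference_source, "literature")
  expect_equal(sl$A$reference_delta, 0.15)
  expect_identical(sl$B$reference_source, "sample_mean")
  expect_equal(sl$B$reference_delta, -2.3)
})

test_that("the normality check returns calibrated p-values and NA markers", {
  # under the null the p-value should essentially never be tiny
  set.seed(7)
  ps <- replicate(50, test_normality(stats::rnorm(200)))
  expect_true(all(ps > 0.001))
  expect_true(all(ps >= 0 & ps <= 1))

  # strongly bimodal sample is rejected decisively
  set.seed(8)
  bim <- c(stats::rnorm(50, -1, 0.05), stats::rnorm(50, 1, 0.05))
  expect_lt(test_normality(bim), 0.001)

  # not-applicable markers: degenerate and out-of-range inputs
  expect_identical(test_normality(rep(0, 10)), NA_real_)
  expect_identical(test_normality(c(0.1, 0.2)), NA_real_)
  expect_identical(test_normality(stats::rnorm(5001)), NA_real_)
})

test_that("the zero-mean t-test matches the closed-form oracle", {
  # symmetric set: t is exactly zero
  expect_equal(test_zero_mean(c(-1, 0, 1)), 1)

  # frozen textbook evaluation: t = mean/(sd/sqrt(n)), p = 2*pt(-|t|, n-1)
  x <- c(1, 1.1, 0.9, 1.05)
  expect_equal(test_zero_mean(x), 0.000164309517832884, tolerance = 1e-12)
  oracle <- 2 * stats::pt(-abs(mean(x) / (stats::sd(x) / 2)), df = 3)
  expect_equal(test_zero_mean(x), oracle)

  expect_identical(test_zero_mean(0.3), NA_real_)
  expect_identical(test_zero_mean(rep(0.2, 5)), NA_real_)
})

test_that("expanded uncertainty is the normal-quantile multiple of the SD", {
  expect_equal(expanded_uncertainty(0.0701), stats::qnorm(0.975) * 0.0701)
  expect_identical(expanded_uncertainty(0), 0)
  expect_equal(expanded_uncertainty(1, coverage = 0.99),
               stats::qnorm(0.995))
  expect_error(expanded_uncertainty(0.1, coverage = 1), "between 0 and 1")
  expect_error(expanded_uncertainty(-0.1), "non-negative")
})

test_that("the Monte Carlo SD is seeded-deterministic and chunking-invariant", {
  sl <- make_campaign(c(A = 20L, B = 15L), seed = 5)
  a <- monte_carlo_sd(sl, runs = 3000, seed = 11)
  b <- monte_carlo_sd(sl, runs = 3000, seed = 11)
  expect_identical(a$pooled, b$pooled)
  expect_identical(a$per_series, b$per_series)
  # internal chunking must not change the draws
  c3 <- monte_carlo_sd(sl, runs = 3000, seed = 11, chunk_size = 700L)
  expect_identical(c3$pooled, a$pooled)
})

test_that("zero propagated errors reproduce the plain SD exactly at any run count", {
  set.seed(6)
  dev <- stats::rnorm(30, 0, 0.07)
  sl <- list(ssb_series("A", dev, prop_se = 0, reference_delta = 0))
  for (runs in c(1, 17, 5000)) {
    mc <- monte_carlo_sd(sl, runs = runs, seed = 1)
    expect_identical(mc$pooled, stats::sd(dev))
    expect_identical(unname(mc$per_series), stats::sd(dev))
  }
})

test_that("noise injection adds variance and respects monotonicity and scaling", {
  set.seed(9)
  dev <- stats::rnorm(200, 0, 0.07)
  base <- stats::sd(dev)
  sl <- function(se) list(ssb_series("A", dev, prop_se = se,
                                     reference_delta = 0))
  m1 <- monte_carlo_sd(sl(0.05), runs = 2000, seed = 3)
  m2 <- monte_carlo_sd(sl(0.10), runs = 2000, seed = 3)
  expect_gt(m1$pooled, base)       # injection cannot shrink spread
  expect_gt(m2$pooled, m1$pooled)  # larger errors, larger MC SD

  # scale equivariance: scaling deltas, reference and errors by c scales SDs by c
  c_scale <- 3.7
  sc <- list(ssb_series("A", c_scale * dev, prop_se = c_scale * 0.05,
                        reference_delta = 0))
  ms <- monte_carlo_sd(sc, runs = 2000, seed = 3)
  expect_equal(ms$pooled, c_scale * m1$pooled, tolerance = 1e-12)
})

test_that("the MC estimator converges in the run count", {
  set.seed(10)
  sl <- list(ssb_series("A", stats::rnorm(20, 0, 0.07), prop_se = 0.08,
                        reference_delta = 0))
  lo <- monte_carlo_sd(sl, runs = 1e5, seed = 2)$pooled
  hi <- monte_carlo_sd(sl, runs = 1e6, seed = 2)$pooled
  expect_lt(abs(lo - hi) / hi, 0.005)
})

test_that("missing propagated errors are reported with the observation", {
  s <- ssb_series("A", c(0.1, 0.2), prop_se = 0.05, reference_delta = 0)
  s$deltas$prop_se[2] <- NA_real_
  expect_error(monte_carlo_sd(list(s), runs = 10), "seq_index 1")
})

test_that("build_report assembles per-sample rows, a joint row and dominance flags", {
  counts <- c(A = 12L, B = 9L)
  sl <- make_campaign(counts, sd = 0.07, prop_se = 0.02, seed = 21)
  rep <- build_report(sl, runs = 2000, seed = 4)
  t <- rep$table
  expect_equal(nrow(t), 3L)
  expect_identical(t$label[3L], "jointly")
  expect_equal(t$n[3L], sum(counts))
  expect_equal(t$u, stats::qnorm(0.975) * t$sd_delta)
  expect_equal(t$u_mc, stats::qnorm(0.975) * t$sd_delta_mc)
  expect_true(all(t$sd_delta_mc >= t$sd_delta))
  # small errors relative to spread: reproducibility dominates
  expect_true(all(t$dominance == "reproducibility-dominated"))

  # tight repeatability with large per-delta errors flips the flag
  # (SD ratio > 3, the pattern of a low-precision absolute-ratio sample)
  x <- seq(-1, 1, length.out = 9)
  x <- x / stats::sd(x) * 0.04  # spread pinned at exactly 0.04
  tight <- list(ssb_series("SCo-like", x, prop_se = 0.15,
                           reference_delta = 0))
  rep2 <- build_report(tight, runs = 2000, seed = 5)
  expect_gt(rep2$table$sd_delta_mc[1] / rep2$table$sd_delta[1], 3)
  expect_identical(unique(rep2$table$dominance),
                   "measurement-precision-dominated")
})

test_that("degenerate all-zero series produce zero uncertainties and NA tests", {
  sl <- list(ssb_series("Z", rep(-0.5, 5), prop_se = 0,
                        reference_delta = -0.5))
  rep <- build_report(sl, runs = 100)
  t <- rep$table
  expect_identical(t$sd_delta, rep(0, 2))
  expect_identical(t$u, rep(0, 2))
  expect_identical(t$u_mc, rep(0, 2))
  expect_true(all(is.na(t$shapiro_p)))
  expect_true(all(t$dominance == "reproducibility-dominated"))
})

test_that("duplicate sample labels are rejected", {
  sl <- list(ssb_series("A", c(0, 0.1), 0.01, reference_delta = 0),
             ssb_series("A", c(0.2, 0.3), 0.01, reference_delta = 0))
  expect_error(build_report(sl, runs = 10), "duplicate")
})

test_that("report statistics are scale-equivariant", {
  sl <- make_campaign(c(A = 15L), sd = 0.07, prop_se = 0.05, seed = 31)
  c_scale <- 2.5
  sc <- lapply(sl, function(s) {
    ssb_series(s$label, c_scale * s$deltas$delta_permil,
               c_scale * s$deltas$prop_se,
               reference_delta = c_scale * s$reference_delta)
  })
  r1 <- build_report(sl, runs = 1000, seed = 6)$table
  r2 <- build_report(sc, runs = 1000, seed = 6)$table
  for (col in c("deviation_avg", "sd_delta", "sd_delta_mc", "u", "u_mc"))
    expect_equal(r2[[col]], c_scale * r1[[col]], tolerance = 1e-12)
})
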