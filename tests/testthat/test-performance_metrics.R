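test_that("compute_cv matches hand-computed values and flags degenerate input", {
  expect_equal(compute_cv(c(9, 10, 11)), 10)  # SD 1, mean 10
  expect_warning(cv0 <- compute_cv(c(10, 10, 10)), "zero-variance")
  expect_identical(cv0, 0)
  expect_error(compute_cv(c(10)), "at least 2")
  expect_error(compute_cv(c(-5, -6, -7)), "positive")
})

test_that("compute_cv recovers a simulated true CV within sampling error", {
  # chi-square interval oracle: 99% interval for the sample SD at n = 360
  n <- 360
  true_cv <- 4
  bounds <- true_cv * sqrt(qchisq(c(0.005, 0.995), df = n - 1) / (n - 1))
  set.seed(42)
  x <- rnorm(n, mean = 100, sd = 4)
  cv_hat <- compute_cv(x)
  expect_gt(cv_hat, bounds[1] * 0.99)  # mean_hat jitter is ~0.2%
  expect_lt(cv_hat, bounds[2] * 1.01)
  expect_gt(cv_hat, 3.6)
  expect_lt(cv_hat, 4.4)
})

test_that("compute_bias implements both summary conventions", {
  expect_equal(compute_bias(rep(10, 5), 10)$bias_percent, 0)
  b <- compute_bias(c(10.2, 10.1, 10.3, 10.2, 10.2), 10)
  expect_equal(b$bias_percent, 2, tolerance = 1e-12)
  expect_equal(b$per_replicate_bias_percent, c(2, 1, 3, 2, 2))

  # alternating offsets document the convention gap
  reps <- 10 * (1 + c(2, -2, 2, -2, 2) / 100)
  expect_equal(compute_bias(reps, 10, "mean_then_abs")$bias_percent, 0.4)
  expect_equal(compute_bias(reps, 10, "abs_then_mean")$bias_percent, 2.0)
  expect_error(compute_bias(c(10, 10), 0), "positive")
})

test_that("sigma_metric follows (TEa - |bias|)/CV without clamping", {
  expect_equal(sigma_metric(20, 0, 20 / 6), 6)
  # inputs reconstructed from a published sigma/QGI pair (urea, TEa 21)
  expect_equal(sigma_metric(21, 1.20, 3.48), 5.69, tolerance = 0.01 / 5.69)
  expect_equal(sigma_metric(20, 25, 5), -1)
  expect_equal(sigma_metric(20, -4, 4), 4)  # |bias| convention
  expect_warning(s <- sigma_metric(20, 1, 0), "infinite")
  expect_identical(s, Inf)
})

test_that("sigma_to_dpm uses the one-sided 1.5-shift normal tail", {
  expect_equal(round(sigma_to_dpm(6), 1), 3.4)
  expect_equal(sigma_to_dpm(1.5), 5e5)
  # erf oracle: 1e6 * (1 - erf(3/sqrt(2)))/2 = 1349.898
  expect_equal(sigma_to_dpm(4.5), 1350, tolerance = 1 / 1350)
})

test_that("qgi is bias/(1.5 CV) and demands a positive CV", {
  expect_equal(qgi(0, 5), 0)
  expect_equal(qgi(3, 2), 1)
  expect_equal(qgi(1.20, 3.48), 0.23, tolerance = 0.005 / 0.23)
  expect_error(qgi(1, 0), "positive")
})

test_that("improvement classification is exhaustive with inclusive middle band", {
  expect_equal(classify_improvement(5.69, 0.23), "imprecision")
  expect_equal(classify_improvement(5.66, 1.27), "trueness")
  expect_equal(classify_improvement(5.94, 0.85), "both")
  expect_equal(classify_improvement(7.2, NA), "none")
  # boundaries belong to the middle class
  expect_equal(classify_improvement(c(5, 5), c(0.8, 1.2)), c("both", "both"))
  expect_error(classify_improvement(5, NA), "QGI")
  expect_equal(improvement_label(c("both", "trueness", "imprecision", "none")),
               c("Imprecision and trueness", "Trueness", "Imprecision",
                 "None"))
  # exhaustive and mutually exclusive over a qgi sweep
  sweep <- classify_improvement(rep(3, 401), seq(0, 4, by = 0.01))
  expect_true(all(sweep %in% c("imprecision", "trueness", "both")))
})

test_that("metrics are scale invariant and satisfy the sigma/QGI identity", {
  set.seed(101)
  for (i in 1:25) {
    vals <- rnorm(30, mean = 50, sd = 2)
    reps <- rnorm(5, mean = 51, sd = 1)
    tgt <- 50
    scale <- exp(runif(1, -3, 3))
    expect_equal(compute_cv(vals * scale), compute_cv(vals))
    expect_equal(compute_bias(reps * scale, tgt * scale)$bias_percent,
                 compute_bias(reps, tgt)$bias_percent)
    cv <- compute_cv(vals)
    bias <- compute_bias(reps, tgt)$bias_percent
    tea <- runif(1, 10, 40)
    # qgi * 1.5 * cv + sigma * cv == tea
    expect_equal(qgi(bias, cv) * 1.5 * cv + sigma_metric(tea, bias, cv) * cv,
                 tea, tolerance = 1e-9)
  }
})

test_that("sigma decreases in bias and CV; DPM decreases in sigma", {
  set.seed(7)
  tea <- runif(50, 15, 45)
  bias <- runif(50, 0, 5)
  cv <- runif(50, 0.5, 6)
  expect_true(all(sigma_metric(tea, bias + 0.5, cv) <
                    sigma_metric(tea, bias, cv)))
  expect_true(all(sigma_metric(tea, bias, cv * 1.1) <
                    sigma_metric(tea, bias, cv)))
  s <- sort(runif(50, -1, 12))
  expect_true(all(diff(sigma_to_dpm(s)) < 0))
})

test_that("performance_table joins keys, computes derived columns, skips orphans", {
  iqc <- read_iqc(iqc_fixture_small())
  # EQA for three of the four keys only
  eqa <- read_eqa(write_eqa_fixture(c(
    sprintf("Lab A,K,level1,%d,25.%d,25", 1:5, c(1, 2, 1, 3, 2)),
    sprintf("Lab A,K,level2,%d,55.%d,55", 1:5, c(1, 2, 1, 3, 2)),
    sprintf("Lab B,K,level1,%d,25.%d,25", 1:5, c(0, 1, 0, 2, 1))
  )))
  m <- performance_table(iqc, eqa)
  expect_equal(nrow(m), 3)
  expect_equal(nrow(attr(m, "skipped_keys")), 1)
  expect_equal(attr(m, "skipped_keys")$missing, "eqa")
  # columns re-derivable from each other
  expect_equal(m$sigma, (m$tea - m$bias) / m$cv)
  expect_equal(as.character(m$zone), as.character(sigma_band(m$sigma)))
  expect_equal(m$improvement, classify_improvement(m$sigma, m$qgi))
  expect_true(all(is.na(m$qgi[m$sigma >= 6])))
})
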