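test_that("significance classification uses strict inequalities at the null", {
  recs <- tibble::tibble(lower = c(1.01, 0.4, 0.8, 1.0, 0.7),
                         upper = c(2.3, 0.99, 1.2, 1.5, 1.0))
  out <- classify_significance(recs)
  expect_equal(out$significance,
               c("sig_above", "sig_below", "nonsig", "nonsig", "nonsig"))
})

test_that("ecdf follows the textbook definition with ties collapsed", {
  curve <- ci_ecdf(c(0.5, 1.0, 2.0))
  expect_equal(eval_ecdf(curve, 1.0), 2 / 3)
  expect_equal(eval_ecdf(curve, 0.49), 0)
  expect_equal(tail(curve$cum_prop, 1), 1)

  tied <- ci_ecdf(c(1.0, 1.0, 1.0))
  expect_equal(nrow(tied), 1)
  expect_equal(tied$cum_prop, 1)
  expect_error(ci_ecdf(numeric(0)), "non-empty")
})

test_that("ecdf agrees with stats::ecdf and converges to the true CDF", {
  withr::with_seed(17, {
    x <- runif(300)
    curve <- ci_ecdf(x)
    at <- seq(0, 1, by = 0.01)
    expect_equal(eval_ecdf(curve, at), unname(stats::ecdf(x)(at)))
    # Glivenko-Cantelli: sup-distance to the uniform CDF shrinks with n
    sup_dist <- function(n) {
      u <- runif(n)
      max(abs(eval_ecdf(ci_ecdf(u), at) - at))
    }
    expect_lt(sup_dist(1e4), sup_dist(1e2))
  })
})

test_that("jump excess equals a direct count and is zero away from the null", {
  expect_equal(jump_statistic(c(2, 3, 0.2, 4), "lower_limits")$excess, 0)
  js <- jump_statistic(c(rep(1.01, 90), rep(0.99, 10)), "lower_limits")
  expect_equal(js$excess, 0.8)
  # mirrored sign convention for upper limits
  ju <- jump_statistic(c(rep(0.99, 90), rep(1.01, 10)), "upper_limits")
  expect_equal(ju$excess, 0.8)
  # boundary: a limit exactly at the null is in neither window
  expect_equal(jump_statistic(c(1, 1, 1), "lower_limits")$excess, 0)
})

test_that("diagnostics match brute-force references on random inputs", {
  withr::with_seed(23, {
    for (trial in 1:200) {
      n <- sample(1:100, 1)
      x <- round(exp(rnorm(n, 0, 0.7)), sample(1:3, 1))
      t0 <- runif(1, 0, 3)
      expect_equal(eval_ecdf(ci_ecdf(x), t0), bf_ecdf_at(x, t0))
      side <- sample(c("lower_limits", "upper_limits"), 1)
      eps <- runif(1, 0.01, 0.2)
      expect_equal(jump_statistic(x, side, epsilon = eps)$excess,
                   bf_jump(x, side, eps = eps))
      expect_equal(ci_histogram(x)$count, bf_hist(x))
    }
  })
})

test_that("histogram bins are half-open, anchored, and range-restricted", {
  h <- ci_histogram(c(0.95, 1.04, 1.05))
  expect_equal(h$count[abs(h$bin_start - 0.95) < 1e-9], 2)
  expect_equal(h$count[abs(h$bin_start - 1.05) < 1e-9], 1)
  expect_equal(sum(h$count), 3)
  # out-of-range values are excluded from the counts
  h2 <- ci_histogram(c(0.1, 5, 0.95))
  expect_equal(sum(h2$count), 1)
  expect_true(all(ci_histogram(numeric(0))$count == 0))
  # bin edges do not suffer from floating-point anchor arithmetic
  h3 <- ci_histogram(c(0.35, 0.45))
  expect_equal(h3$count[abs(h3$bin_start - 0.35) < 1e-9], 1)
  expect_equal(h3$count[abs(h3$bin_start - 0.45) < 1e-9], 1)
})

test_that("period bins tile the year range from the anchor", {
  recs <- tibble::tibble(year = c(1976, 1980, 1981, 2016, 2019))
  out <- bin_by_period(recs)
  expect_equal(out$period,
               c("1976-1980", "1976-1980", "1981-1985", "2016-2020",
                 "2016-2020"))
  expect_equal(out$period_end - out$period_start, rep(4L, 5))
  expect_message(
    out2 <- bin_by_period(tibble::tibble(year = c(1990, NA))),
    "without a year")
  expect_equal(nrow(out2), 1)
})

test_that("significant share decomposes into the two limit ECDFs at the null", {
  withr::with_seed(41, {
    recs <- generate_unbiased_corpus(sim_config(n_studies = 2000))$records
    cls <- classify_significance(recs)
    prop_sig <- mean(cls$significance != "nonsig")
    p_upper_below <- mean(recs$upper < 1)
    p_lower_above <- 1 - eval_ecdf(ci_ecdf(recs$lower), 1)
    expect_equal(prop_sig, p_upper_below + p_lower_above)
  })
})

test_that("curve and histogram plots build and write files", {
  recs <- generate_unbiased_corpus(sim_config(n_studies = 300, seed = 2))$records
  p <- plot_curves(recs)
  expect_s3_class(p, "ggplot")
  f <- tempfile(fileext = ".pdf")
  plot_curves(recs, file = f)
  expect_true(file.size(f) > 0)
  f2 <- tempfile(fileext = ".pdf")
  plot_histograms(recs, file = f2)
  expect_true(file.size(f2) > 0)
  # by-period overlay
  recs$year <- sample(1976:2019, nrow(recs), replace = TRUE)
  p2 <- plot_curves(bin_by_period(recs), by = "period")
  expect_s3_class(p2, "ggplot")
  # ecdf autoplot
  expect_s3_class(ggplot2::autoplot(ci_ecdf(recs$lower)), "ggplot")
})
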