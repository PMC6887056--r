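test_that("Wald records shrink onto the true ratio as the SE vanishes", {
  withr::with_seed(1, {
    recs <- simulate_study(log(1.5), se = rep(1e-8, 50))
    expect_true(all(abs(recs$point_estimate - 1.5) < 1e-6))
    expect_true(all(recs$upper - recs$lower < 1e-6))
    # strict ordering before any rounding
    recs2 <- simulate_study(0, se = runif(200, 0.02, 0.5))
    expect_true(all(recs2$lower < recs2$point_estimate))
    expect_true(all(recs2$point_estimate < recs2$upper))
  })
})

test_that("null studies are significant at the nominal rate", {
  withr::with_seed(7, {
    recs <- simulate_study(0, se = exp(runif(4e4, log(0.02), log(0.5))))
    sig <- mean(recs$lower > 1 | recs$upper < 1)
    expect_lt(abs(sig - 0.05), 3 * sqrt(0.05 * 0.95 / 4e4))
  })
})

test_that("one analysis look reproduces the plain Wald simulation draw-for-draw", {
  se <- exp(seq(log(0.02), log(0.5), length.out = 100))
  a <- withr::with_seed(5, simulate_study(0, se))
  b <- withr::with_seed(5, apply_p_hacking(0, se, k_looks = 1))
  expect_equal(a$point_estimate, b$point_estimate)
  expect_equal(a$lower, b$lower)
  expect_false(any(b$was_hacked))
})

test_that("repeated looks inflate the significant fraction to 1-(1-a)^k", {
  withr::with_seed(11, {
    n <- 3e4
    recs <- apply_p_hacking(0, se = rep(0.1, n), k_looks = 5)
    sig <- mean(recs$lower > 1 | recs$upper < 1)
    target <- 1 - 0.95^5
    expect_lt(abs(sig - target), 3 * sqrt(target * (1 - target) / n))
    expect_true(any(recs$was_hacked))
    expect_true(all(recs$n_looks_used <= 5))
  })
})

test_that("publication bias keeps all significant and thins the rest", {
  withr::with_seed(13, {
    recs <- simulate_study(0, se = exp(runif(2e4, log(0.02), log(0.5))))
    sig <- recs$lower > 1 | recs$upper < 1
    all_kept <- apply_publication_bias(recs, retention = 1)
    expect_equal(nrow(all_kept), nrow(recs))
    only_sig <- apply_publication_bias(recs, retention = 0)
    expect_equal(nrow(only_sig), sum(sig))
    expect_true(all(only_sig$lower > 1 | only_sig$upper < 1))
    # closed form: share significant after thinning nonsignificant by half
    kept <- apply_publication_bias(recs, retention = 0.5)
    share <- mean(kept$lower > 1 | kept$upper < 1)
    expected <- 0.05 / (0.05 + 0.95 * 0.5)
    expect_lt(abs(share - expected), 0.02)
  })
})

test_that("unbiased corpus recovers the configured effects", {
  pure_null <- generate_unbiased_corpus(
    sim_config(n_studies = 2e4, prop_positive = 0, seed = 19))
  sig <- classify_significance(pure_null$records)
  expect_lt(abs(mean(sig$significance != "nonsig") - 0.05),
            3 * sqrt(0.05 * 0.95 / 2e4))
  positives <- generate_unbiased_corpus(
    sim_config(n_studies = 5e3, prop_positive = 1, seed = 19))
  expect_lt(abs(median(positives$records$point_estimate) - 1.5), 0.02)
  expect_true(all(positives$truth$true_log_ratio == log(1.5)))
  expect_false(any(positives$truth$was_hacked))
  expect_true(all(positives$truth$survived_publication))
})

test_that("biased generator with bias disabled equals the unbiased generator", {
  cfg <- sim_config(n_studies = 500, p_hack_looks = 1, pub_bias_retention = 1,
                    seed = 23)
  expect_equal(generate_biased_corpus(cfg)$records,
               generate_unbiased_corpus(cfg)$records)
  # and a fixed seed makes generation reproducible
  expect_equal(generate_unbiased_corpus(cfg)$records,
               generate_unbiased_corpus(cfg)$records)
})

test_that("jump excess grows with looks and with publication-bias strength", {
  excess <- function(looks, retention) {
    corpus <- generate_biased_corpus(
      sim_config(n_studies = 8e3, p_hack_looks = looks,
                 pub_bias_retention = retention, seed = 29))
    jump_statistic(corpus$records$lower, "lower_limits")$excess
  }
  by_looks <- c(excess(1, 0.5), excess(3, 0.5), excess(6, 0.5))
  expect_true(all(diff(by_looks) > 0))
  by_retention <- c(excess(4, 1), excess(4, 0.5), excess(4, 0.2))
  expect_true(all(diff(by_retention) > 0))
})

test_that("ground truth has one entry per simulated study", {
  corpus <- generate_biased_corpus(
    sim_config(n_studies = 300, p_hack_looks = 3, pub_bias_retention = 0.4,
               seed = 31))
  expect_equal(nrow(corpus$truth), 300)
  expect_equal(nrow(corpus$records), sum(corpus$truth$survived_publication))
  expect_true(all(corpus$records$study_id %in% corpus$truth$study_id))
  g <- glance(corpus)
  expect_equal(g$n_published, nrow(corpus$records))
})

test_that("rendering embeds the rounded values verbatim", {
  rec <- tibble::tibble(estimate_type = "OR", point_estimate = 1.5,
                        lower = 1.2, upper = 1.9, ci_level = 95)
  doc <- withr::with_seed(1, render_abstract(rec, "paren_to"))
  expect_match(doc$text, "OR 1.50 (95% CI 1.20 to 1.90)", fixed = TRUE)
  expect_true(doc$year >= 1976 && doc$year <= 2019)
  expect_error(render_abstract(rec, "no_such_template"), "unknown template")
  # a template omitting the level parses back with level unknown
  doc2 <- withr::with_seed(1, render_abstract(rec, "bracket_hyphen"))
  parsed <- parse_document(doc2$text)
  expect_true(is.na(parsed$ci_level))
  expect_equal(parsed$point_estimate, 1.5)
})

test_that("end-to-end extraction of a rendered corpus loses no records", {
  corpus <- generate_biased_corpus(
    sim_config(n_studies = 250, p_hack_looks = 5, pub_bias_retention = 0.3,
               seed = 37))
  rend <- render_corpus(corpus, seed = 38)
  parsed <- parse_documents(rend$documents)
  report <- apply_qc(parsed)
  expect_equal(nrow(report$retained), nrow(corpus$records))
  joined <- dplyr::inner_join(report$retained, rend$mapping, by = "doc_id") |>
    dplyr::inner_join(corpus$records, by = "study_id", suffix = c("", ".sim"))
  expect_equal(nrow(joined), nrow(corpus$records))
  expect_equal(joined$point_estimate, round(joined$point_estimate.sim, 2))
  expect_equal(joined$lower, round(joined$lower.sim, 2))
  expect_equal(joined$upper, round(joined$upper.sim, 2))
})
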