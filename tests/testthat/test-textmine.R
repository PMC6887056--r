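test_that("direct template parses recover estimate, limits and level", {
  rec <- parse_document("OR 1.50 (95% CI 1.20 to 1.90)")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$estimate_type, "OR")
  expect_equal(rec$point_estimate, 1.50)
  expect_equal(rec$lower, 1.20)
  expect_equal(rec$upper, 1.90)
  expect_equal(rec$ci_level, 95)
  expect_equal(rec$flags, "")

  rec2 <- parse_document("RR = 2.0 [1.1–3.6]")
  expect_equal(rec2$estimate_type, "RR")
  expect_equal(c(rec2$point_estimate, rec2$lower, rec2$upper), c(2.0, 1.1, 3.6))
  expect_true(is.na(rec2$ci_level))
})

test_that("text without a ratio confidence interval yields no records", {
  expect_equal(nrow(parse_document("The mean age was 52.3 (SD 4.1) years.")), 0)
  expect_equal(nrow(parse_document("a hazard ratio of 1.5 was observed")), 0)
  expect_equal(nrow(parse_document("No numbers at all here.")), 0)
  # difference-scale intervals with negative limits are out of scope
  expect_equal(nrow(parse_document("difference -0.5 (95% CI -1.2 to 0.2)")), 0)
})

test_that("malformed document input signals an error", {
  expect_error(parse_document(""), "non-empty")
  expect_error(parse_document(NA_character_), "non-empty")
  expect_error(parse_documents(tibble::tibble(doc_id = "a")), "doc_id")
})

test_that("numeric tokens are parsed exactly as printed", {
  expect_equal(parse_number(c("1.20", "0.85", "12")), c(1.20, 0.85, 12))
  expect_true(is.na(parse_number("1,204")))
  expect_true(is.na(parse_number("1.2.3")))
  expect_true(is.na(parse_number("-1.2")))
})

test_that("confidence level is detected when stated and unknown otherwise", {
  expect_equal(detect_ci_level("... (95% CI 1.2 to 1.9)"), 95)
  expect_equal(detect_ci_level("... (99% CI 1.1 to 2.2)"), 99)
  expect_equal(detect_ci_level("... (90% confidence interval 1.1 to 2.2)"), 90)
  expect_true(is.na(detect_ci_level("... (CI 1.2 to 1.9)")))
  expect_true(is.na(detect_ci_level("no level here at all")))
})

test_that("estimate types map from abbreviations and spelled-out names", {
  expect_equal(detect_estimate_type("adjusted hazard ratio 0.85"), "HR")
  expect_equal(detect_estimate_type("RR = 2.0"), "RR")
  expect_equal(detect_estimate_type("aOR"), "OR")
  expect_equal(detect_estimate_type("the incidence rate ratio was"), "IRR")
  expect_equal(detect_estimate_type("relative risk of"), "RR")
  expect_equal(detect_estimate_type("prevalence ratio"), "PR")
  expect_equal(detect_estimate_type("estimate 1.3"), "unknown")
  # nearest token to the interval wins
  expect_equal(detect_estimate_type("the OR was similar; hazard ratio"), "HR")
})

test_that("reversed printed limits are swapped and flagged", {
  rec <- parse_document("OR 1.50 (95% CI 1.90 to 1.20)")
  expect_equal(rec$lower, 1.20)
  expect_equal(rec$upper, 1.90)
  expect_equal(rec$flags, "reordered")
  expect_true(all(rec$upper >= rec$lower))
})

test_that("multiple intervals give ordered, non-overlapping spans", {
  txt <- "HR 0.85; 95% CI 0.75 to 0.97, and OR 1.2 (95% CI: 1.0, 1.4) too"
  rec <- parse_document(txt)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$estimate_type, c("HR", "OR"))
  expect_true(all(diff(rec$span_start) > 0))
  expect_true(all(rec$span_end[-nrow(rec)] < rec$span_start[-1]))
})

test_that("round-trip over the template catalogue recovers every record", {
  records <- random_records(12, seed = 42)
  corp <- render_catalogue_corpus(records, seed = 7)
  parsed <- parse_documents(corp$documents)
  # recall and precision both 100%: exactly one record per document
  expect_equal(nrow(parsed), nrow(corp$documents))
  expect_equal(parsed$doc_id, corp$expected$doc_id)
  expect_equal(parsed$estimate_type, corp$expected$estimate_type)
  expect_equal(parsed$point_estimate, corp$expected$point_estimate)
  expect_equal(parsed$lower, corp$expected$lower)
  expect_equal(parsed$upper, corp$expected$upper)
  expect_equal(parsed$ci_level, corp$expected$ci_level)
})

test_that("re-parsing the matched span substring yields the same record", {
  records <- random_records(4, seed = 5)
  corp <- render_catalogue_corpus(records, seed = 9)
  parsed <- parse_documents(corp$documents)
  for (i in seq_len(nrow(parsed))) {
    txt <- corp$documents$text[match(parsed$doc_id[i], corp$documents$doc_id)]
    frag <- substr(txt, parsed$span_start[i], parsed$span_end[i])
    again <- parse_document(frag)
    expect_equal(nrow(again), 1)
    expect_equal(again$point_estimate, parsed$point_estimate[i])
    expect_equal(again$lower, parsed$lower[i])
    expect_equal(again$upper, parsed$upper[i])
    expect_equal(again$estimate_type, parsed$estimate_type[i])
  }
})

test_that("grammar families can be disabled", {
  g <- grammar_config(families = "paren")
  expect_equal(nrow(parse_document("RR 2.0 [1.1-3.6]", grammar = g)), 0)
  expect_equal(nrow(parse_document("RR 2.0 (95% CI 1.1-3.6)", grammar = g)), 1)
})
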