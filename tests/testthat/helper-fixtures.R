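# Shared fixtures: random interval records, rendered corpora, and
# brute-force reference implementations of the diagnostics.

# a plausible random interval record for every estimate type, 2 dp values
random_records <- function(n, seed = NULL, digits = 2) {
  draw <- function() {
    types <- c("OR", "HR", "RR", "IRR", "PR")
    est <- round(exp(rnorm(n, 0, 0.4)), digits)
    half <- round(exp(abs(rnorm(n, 0.3, 0.15))), digits) # width factor > 1
    tibble::tibble(
      estimate_type = sample(types, n, replace = TRUE),
      point_estimate = est,
      lower = round(est / half, digits),
      upper = round(est * half, digits),
      ci_level = sample(c(90, 95, 99), n, replace = TRUE))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# render each record under each template in turn -> documents + expected
render_catalogue_corpus <- function(records, seed = 1) {
  cat_tbl <- template_catalogue()
  grid <- tidyr::expand_grid(rec = seq_len(nrow(records)),
                             template_id = cat_tbl$template_id)
  withr::with_seed(seed, {
    docs <- purrr::pmap(list(grid$rec, grid$template_id, seq_len(nrow(grid))),
      function(i, tid, k) {
        render_abstract(records[i, ], tid, doc_id = sprintf("d%05d", k))
      }) |> purrr::list_rbind()
  })
  row <- cat_tbl[match(docs$template_id, cat_tbl$template_id), ]
  idx <- grid$rec
  expected <- tibble::tibble(
    doc_id = docs$doc_id,
    estimate_type = ifelse(row$type_style == "none", "unknown",
                           records$estimate_type[idx]),
    point_estimate = records$point_estimate[idx],
    lower = pmin(records$lower[idx], records$upper[idx]),
    upper = pmax(records$lower[idx], records$upper[idx]),
    ci_level = ifelse(row$has_level, records$ci_level[idx], NA_real_))
  list(documents = docs, expected = expected)
}

oracle_parse_documents <- function(docs) {
  purrr::pmap(list(docs$text, docs$doc_id, docs$year, docs$section),
              function(t, d, y, s) oracle_parse(t, d, y, s)) |>
    purrr::list_rbind()
}

# brute-force references, written as plain loops
bf_ecdf_at <- function(x, t) {
  hits <- 0
  for (v in x) if (v <= t) hits <- hits + 1
  hits / length(x)
}

bf_jump <- function(x, side, null_value = 1, eps = 0.05) {
  above <- 0; below <- 0
  for (v in x) {
    if (v > null_value && v <= null_value + eps) above <- above + 1
    if (v >= null_value - eps && v < null_value) below <- below + 1
  }
  if (side == "lower_limits") (above - below) / length(x)
  else (below - above) / length(x)
}

bf_hist <- function(x, binwidth = 0.1, range = c(0.25, 4)) {
  nbins <- ceiling((range[2] - range[1]) / binwidth + 1e-8)
  counts <- integer(nbins)
  for (v in x) {
    if (is.na(v) || v < range[1] || v > range[2]) next
    k <- 1
    while (!(v + 1e-9 >= range[1] + (k - 1) * binwidth &&
             v + 1e-9 < range[1] + k * binwidth) && k < nbins) {
      k <- k + 1
    }
    counts[k] <- counts[k] + 1
  }
  counts
}

# ten hand-built records: one zero-lower, one mean-outside, eight clean
qc_fixture <- function() {
  tibble::tibble(
    doc_id = paste0("d", 1:10),
    estimate_type = "OR",
    point_estimate = c(1.50, 1.10, 2.00, 0.80, 1.30, 2.00, 0.95, 1.00, 1.25, 3.10),
    lower =          c(1.20, 0.00, 1.50, 0.60, 1.10, 0.90, 0.80, 0.90, 1.25, 2.20),
    upper =          c(1.90, 1.30, 2.70, 1.05, 1.55, 1.80, 1.15, 1.10, 1.60, 4.30),
    ci_level = 95)
}
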