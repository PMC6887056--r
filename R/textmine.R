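# Extraction of ratio estimates with confidence intervals from free text.

#' Parse the numeric token of an estimate or interval limit
#'
#' Converts a printed decimal token to its exact numeric value. The numeric
#' sub-grammar is deliberately narrow: an optional decimal part separated by
#' a period. Tokens containing thousands separators, a comma decimal mark or
#' several periods do not belong to the grammar and are rejected, because
#' ratio estimates rarely exceed three digits and the ambiguity would cost
#' precision.
#'
#' @param token Character vector of printed numbers.
#' @return Numeric vector; `NA` for tokens outside the sub-grammar.
#' @examples
#' parse_number(c("1.20", "0.85", "12"))
#' parse_number("1,204") # rejected
#' @export
parse_number <- function(token) {
  stopifnot(is.character(token))
  ok <- stringr::str_detect(token, "^\\d+(?:\\.\\d+)?$")
  out <- rep(NA_real_, length(token))
  out[ok] <- as.numeric(token[ok])
  out
}

#' Detect the confidence level stated in context
#'
#' Scans a context string (the matched interval phrase plus a bounded window
#' before it) for a stated confidence level such as `"95% CI"` or
#' `"99% confidence interval"`. When several are present the one closest to
#' the interval (the last match) wins. Intervals whose level is not stated
#' are common in practice and are returned as unknown rather than dropped.
#'
#' @param context Character vector of context strings.
#' @return Numeric vector of levels in percent; `NA` when the level cannot
#'   be determined.
#' @examples
#' detect_ci_level("OR 1.5 (95% CI 1.2 to 1.9)")
#' detect_ci_level("OR 1.5 (CI 1.2 to 1.9)") # unknown
#' @export
detect_ci_level <- function(context) {
  stopifnot(is.character(context))
  re <- paste0("(\\d{1,2}(?:\\.\\d)?)\\s*%\\s*", .re_ciword)
  m <- stringr::str_match_all(context, re)
  vapply(m, function(g) {
    if (nrow(g) == 0) NA_real_ else as.numeric(g[nrow(g), 2])
  }, numeric(1))
}

# Internal: locate the estimate-type token nearest the end of `context`.
# Returns list(type, start, end) with type "unknown" when nothing matches.
.locate_estimate_type <- function(context) {
  best <- list(type = "unknown", start = NA_integer_, end = NA_integer_)
  for (type in names(.type_patterns)) {
    for (pat in .type_patterns[[type]]) {
      loc <- stringr::str_locate_all(context, pat)[[1]]
      if (nrow(loc) == 0) next
      cand <- loc[nrow(loc), ]
      if (is.na(best$end) || cand["end"] > best$end ||
          (cand["end"] == best$end && cand["start"] < best$start)) {
        best <- list(type = type, start = unname(cand["start"]),
                     end = unname(cand["end"]))
      }
    }
  }
  best
}

#' Detect the estimate type stated in context
#'
#' Maps abbreviations (`OR`, `HR`, `RR`, `IRR`, `PR`, optionally prefixed
#' with `a` for adjusted) and spelled-out names (`"odds ratio"`,
#' `"adjusted hazard ratio"`, `"relative risk"`, ...) to the estimate-type
#' enum. The token nearest the interval wins when several are present.
#'
#' @param context Character vector: the text preceding the interval.
#' @return Character vector with values in
#'   `c("OR", "HR", "RR", "IRR", "PR", "unknown")`.
#' @examples
#' detect_estimate_type("adjusted hazard ratio 0.85")
#' detect_estimate_type("RR = 2.0")
#' detect_estimate_type("estimate 1.3")
#' @export
detect_estimate_type <- function(context) {
  stopifnot(is.character(context))
  vapply(context, function(x) .locate_estimate_type(x)$type, character(1),
         USE.NAMES = FALSE)
}

# Internal: all raw candidate matches for one family in one text.
.family_candidates <- function(text, family) {
  re <- .family_regex(family)
  loc <- stringr::str_locate_all(text, re)[[1]]
  if (nrow(loc) == 0) {
    return(tibble(start = integer(), end = integer(), est = character(),
                  level = character(), lo = character(), hi = character()))
  }
  grp <- stringr::str_match_all(text, re)[[1]]
  tibble(start = as.integer(loc[, "start"]), end = as.integer(loc[, "end"]),
         est = grp[, 2], level = grp[, 3], lo = grp[, 4], hi = grp[, 5])
}

# Internal: resolve overlapping candidates, longest match wins; survivors in
# reading order.
.resolve_overlaps <- function(cand) {
  cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  taken_start <- integer(0)
  taken_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    overlaps <- any(cand$start[i] <= taken_end & cand$end[i] >= taken_start)
    if (!overlaps) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, cand$start[i])
      taken_end <- c(taken_end, cand$end[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

.empty_records <- function() {
  tibble(doc_id = character(), year = integer(), section = character(),
         estimate_type = character(), point_estimate = double(),
         lower = double(), upper = double(), ci_level = double(),
         span_start = integer(), span_end = integer(), flags = character())
}

#' Extract ratio confidence intervals from one document
#'
#' Scans the text of a document for ratio estimates reported with a
#' confidence interval, in any of the typeset forms of the template
#' catalogue, and returns one structured record per match. Text that does not
#' contain a ratio interval (a mean with an SD, a bare point estimate with no
#' interval, ...) yields no records. Numbers are taken exactly as printed.
#'
#' A matched interval printed with its limits reversed (`upper < lower`) is
#' kept with the limits swapped and the flag `reordered`, since orientation
#' is a typesetting artefact; downstream QC applies to the swapped values.
#'
#' @param text The document text (single string).
#' @param doc_id Document identifier carried into each record.
#' @param year Publication year (integer or `NA`).
#' @param section `"abstract"` or `"fulltext"`.
#' @param grammar A [grammar_config()].
#' @return A tibble of interval records with columns `doc_id`, `year`,
#'   `section`, `estimate_type`, `point_estimate`, `lower`, `upper`,
#'   `ci_level` (`NA` when not determinable), `span_start`, `span_end`
#'   (1-based inclusive character offsets into `text`), `flags`
#'   (`""` or `"reordered"`), ordered by `span_start` with non-overlapping
#'   spans.
#' @examples
#' parse_document("The pooled OR was 1.50 (95% CI 1.20 to 1.90).")
#' parse_document("The mean age was 52.3 (SD 4.1) years.") # no records
#' @export
parse_document <- function(text, doc_id = "doc1", year = NA_integer_,
                           section = "abstract",
                           grammar = grammar_config()) {
  if (!is.character(text) || length(text) != 1 || is.na(text) ||
      !nzchar(text)) {
    abort("`text` must be a single non-empty string.")
  }
  stopifnot(inherits(grammar, "grammar_config"))
  cand <- bind_rows(lapply(grammar$families, function(f) {
    .family_candidates(text, f)
  }))
  if (nrow(cand) == 0) return(.empty_records())
  cand <- .resolve_overlaps(cand)

  prev_end <- 0L
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ci <- cand[i, ]
    win_start <- max(prev_end + 1L, ci$start - grammar$window)
    window <- if (win_start <= ci$start - 1L) {
      substr(text, win_start, ci$start - 1L)
    } else ""
    type_loc <- .locate_estimate_type(window)

    span_start <- ci$start
    if (!identical(type_loc$type, "unknown")) {
      gap <- substr(window, type_loc$end + 1L, nchar(window))
      if (stringr::str_detect(gap, .re_connector_gap)) {
        span_start <- win_start + type_loc$start - 1L
      }
    }

    level <- if (!is.na(ci$level)) as.numeric(ci$level) else {
      detect_ci_level(window)
    }
    est <- parse_number(ci$est)
    lo <- parse_number(ci$lo)
    hi <- parse_number(ci$hi)
    flags <- ""
    if (!is.na(lo) && !is.na(hi) && lo > hi) {
      tmp <- lo; lo <- hi; hi <- tmp
      flags <- "reordered"
    }
    rows[[i]] <- tibble(
      doc_id = doc_id, year = as.integer(year), section = section,
      estimate_type = type_loc$type, point_estimate = est,
      lower = lo, upper = hi, ci_level = level,
      span_start = as.integer(span_start), span_end = ci$end, flags = flags)
    prev_end <- ci$end
  }
  bind_rows(rows)
}

#' Extract ratio confidence intervals from a corpus of documents
#'
#' Data-frame-first wrapper around [parse_document()]: one input row per
#' document, one output row per extracted interval.
#'
#' @param docs A data frame with columns `doc_id` and `text`; optional
#'   columns `year` and `section` are carried through (defaults `NA` and
#'   `"abstract"`).
#' @param grammar A [grammar_config()].
#' @return A tibble of interval records (see [parse_document()]).
#' @examples
#' docs <- tibble::tibble(
#'   doc_id = c("a", "b"),
#'   text = c("OR 1.50 (95% CI 1.20 to 1.90).", "No intervals here."))
#' parse_documents(docs)
#' @export
parse_documents <- function(docs, grammar = grammar_config()) {
  stopifnot(is.data.frame(docs))
  if (!all(c("doc_id", "text") %in% names(docs))) {
    abort("`docs` must have columns `doc_id` and `text`.")
  }
  if (nrow(docs) == 0) return(.empty_records())
  year <- if ("year" %in% names(docs)) docs$year else rep(NA_integer_, nrow(docs))
  section <- if ("section" %in% names(docs)) docs$section else "abstract"
  section <- rep_len(section, nrow(docs))
  purrr::pmap(
    list(docs$text, docs$doc_id, year, section),
    function(text, doc_id, yr, sec) {
      parse_document(text, doc_id = doc_id, year = yr, section = sec,
                     grammar = grammar)
    }
  ) |> purrr::list_rbind()
}
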