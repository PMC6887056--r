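# A second, intentionally simple interval extractor used to validate the
# main grammar. It scans numeric tokens and inspects the literal text
# between them instead of matching one template regex, so the two
# implementations share only the specification of what counts as a match.

.oracle_ci_words <- c("ci", "c.i.", "confidence interval",
                      "confidence intervals")

# spelled-out names checked lowercase; abbreviations checked as-is
.oracle_spelled <- c("incidence rate ratio" = "IRR",
                     "prevalence ratio" = "PR",
                     "odds ratio" = "OR",
                     "hazard ratio" = "HR",
                     "risk ratio" = "RR",
                     "relative risk" = "RR",
                     "rate ratio" = "RR")
.oracle_abbrev <- c(IRR = "IRR", aIRR = "IRR", PR = "PR", aPR = "PR",
                    OR = "OR", aOR = "OR", HR = "HR", aHR = "HR",
                    RR = "RR", aRR = "RR")

# last estimate-type token in `window`, by simple fixed-string search
.oracle_type <- function(window) {
  best <- list(type = "unknown", start = NA_integer_, end = NA_integer_)
  consider <- function(start, end, type) {
    if (is.na(start)) return()
    if (is.na(best$end) || end > best$end ||
        (end == best$end && start < best$start)) {
      best <<- list(type = type, start = start, end = end)
    }
  }
  low <- tolower(window)
  for (name in names(.oracle_spelled)) {
    hits <- gregexpr(name, low, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    for (h in hits) {
      e <- h + nchar(name) - 1L
      # word boundaries (allow trailing plural "s")
      before <- if (h > 1) substr(window, h - 1L, h - 1L) else " "
      after <- substr(window, e + 1L, e + 1L)
      if (after == "s") { e <- e + 1L; after <- substr(window, e + 1L, e + 1L) }
      if (!grepl("[A-Za-z0-9]", before) && !grepl("[A-Za-z0-9]", after)) {
        consider(h, e, .oracle_spelled[[name]])
      }
    }
  }
  for (abbr in names(.oracle_abbrev)) {
    hits <- gregexpr(abbr, window, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    for (h in hits) {
      e <- h + nchar(abbr) - 1L
      before <- if (h > 1) substr(window, h - 1L, h - 1L) else " "
      after <- if (e < nchar(window)) substr(window, e + 1L, e + 1L) else " "
      if (!grepl("[A-Za-z0-9]", before) && !grepl("[A-Za-z0-9]", after)) {
        consider(h, e, .oracle_abbrev[[abbr]])
      }
    }
  }
  best
}

# does `gap` consist only of connector filler ("of", "was", "=", ":", ",")?
.oracle_connector <- function(gap) {
  gap <- gsub("[=:,]", " ", gap)
  words <- strsplit(trimws(gap), "\\s+")[[1]]
  words <- words[nzchar(words)]
  all(tolower(words) %in% c("of", "was", "were", "is"))
}

# strip "NN %" level prefix from the start of a gap body; returns
# list(level, rest)
.oracle_strip_level <- function(body) {
  m <- regmatches(body, regexec("^(\\d{1,2}(?:\\.\\d)?)\\s*%\\s*(.*)$", body))[[1]]
  if (length(m) == 0) list(level = NA_real_, rest = body)
  else list(level = as.numeric(m[2]), rest = m[3])
}

.oracle_is_ci_word <- function(txt) {
  txt <- trimws(txt)
  txt <- sub("[:=]\\s*$", "", txt)
  txt <- tolower(gsub("\\s+", " ", trimws(txt)))
  txt %in% .oracle_ci_words
}

#' Validation parser: token-scan extraction of ratio confidence intervals
#'
#' An independent second implementation of the extraction contract, written
#' as a numeric-token scan with explicit inspection of the text between
#' tokens rather than as a template grammar. On the supported template
#' catalogue it must agree record-for-record with [parse_document()]; it
#' exists to validate the main parser and is not meant for production use.
#'
#' @inheritParams parse_document
#' @return A tibble of interval records with the same columns as
#'   [parse_document()].
#' @examples
#' oracle_parse("The pooled OR was 1.50 (95% CI 1.20 to 1.90).")
#' @export
oracle_parse <- function(text, doc_id = "doc1", year = NA_integer_,
                         section = "abstract", window = 60) {
  if (!is.character(text) || length(text) != 1 || is.na(text) ||
      !nzchar(text)) {
    abort("`text` must be a single non-empty string.")
  }
  loc <- gregexpr("\\d+(?:\\.\\d+)?", text, perl = TRUE)[[1]]
  if (loc[1] == -1) return(.empty_records())
  starts <- as.integer(loc)
  ends <- starts + attr(loc, "match.length") - 1L
  toks <- substring(text, starts, ends)
  n <- length(toks)
  # a token immediately followed (after spaces) by "%" is a level, not a value
  after <- substring(text, ends + 1L)
  is_pct <- grepl("^\\s*%", after)

  rows <- list()
  prev_end <- 0L
  j <- 1L
  while (j <= n) {
    if (is_pct[j] || starts[j] <= prev_end) { j <- j + 1L; next }
    # candidate estimate at j; the interval limits are the next two value
    # tokens
    vals <- which(!is_pct & starts > ends[j])
    vals <- vals[vals > j]
    if (length(vals) < 2) break
    jl <- vals[1]; ju <- vals[2]
    est_pre <- if (starts[j] > 1) substr(text, starts[j] - 1L, starts[j] - 1L) else ""
    bad_pre <- est_pre %in% c(".", ",", "-", "–", "−") ||
      grepl("[0-9]", est_pre)

    ok <- FALSE
    level <- NA_real_
    span_end <- NA_integer_
    if (!bad_pre) {
      gap1 <- substr(text, ends[j] + 1L, starts[jl] - 1L)
      g1 <- trimws(gap1)
      opener <- substr(g1, 1, 1)
      body <- trimws(substring(g1, 2))
      if (opener %in% c("(", "[", ";", ",")) {
        lv <- .oracle_strip_level(body)
        level <- lv$level
        rest <- lv$rest
        ci_ok <- .oracle_is_ci_word(rest)
        no_ci_ok <- opener == "[" && !nzchar(trimws(rest))
        if (ci_ok || no_ci_ok) {
          gap2 <- trimws(substr(text, ends[jl] + 1L, starts[ju] - 1L))
          seps <- if (opener %in% c(";", ",")) c("to", "-", "–", "−")
                  else c("to", "-", "–", "−", ",")
          if (gap2 %in% seps) {
            tail_txt <- substring(text, ends[ju] + 1L)
            if (opener == "(") {
              m <- regexpr("^\\s*\\)", tail_txt)
              if (m == 1) { span_end <- ends[ju] + attr(m, "match.length"); ok <- TRUE }
            } else if (opener == "[") {
              m <- regexpr("^\\s*\\]", tail_txt)
              if (m == 1) { span_end <- ends[ju] + attr(m, "match.length"); ok <- TRUE }
            } else {
              if (!grepl("^\\.?[0-9]", tail_txt)) { span_end <- ends[ju]; ok <- TRUE }
            }
          }
        }
      }
    }
    if (!ok) { j <- j + 1L; next }

    win_start <- max(prev_end + 1L, starts[j] - window)
    win <- if (win_start <= starts[j] - 1L) {
      substr(text, win_start, starts[j] - 1L)
    } else ""
    tl <- .oracle_type(win)
    span_start <- starts[j]
    if (!identical(tl$type, "unknown") &&
        .oracle_connector(substr(win, tl$end + 1L, nchar(win)))) {
      span_start <- win_start + tl$start - 1L
    }
    if (is.na(level)) {
      # fallback: nearest "NN% <CI word>" in the window
      m <- gregexpr("(\\d{1,2}(?:\\.\\d)?)\\s*%\\s*", win, perl = TRUE)[[1]]
      if (m[1] != -1) {
        for (k in rev(seq_along(m))) {
          after_lvl <- substring(win, as.integer(m)[k] + attr(m, "match.length")[k])
          word <- sub("^([A-Za-z.]+(?:\\s+[A-Za-z.]+)?).*$", "\\1", after_lvl)
          if (.oracle_is_ci_word(word) ||
              .oracle_is_ci_word(sub("^([A-Za-z.]+).*$", "\\1", after_lvl))) {
            lvtok <- regmatches(win, m)[[1]][k]
            level <- as.numeric(sub("\\s*%.*$", "", lvtok))
            break
          }
        }
      }
    }
    est <- as.numeric(toks[j]); lo <- as.numeric(toks[jl]); hi <- as.numeric(toks[ju])
    flags <- ""
    if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp; flags <- "reordered" }
    rows[[length(rows) + 1L]] <- tibble(
      doc_id = doc_id, year = as.integer(year), section = section,
      estimate_type = tl$type, point_estimate = est, lower = lo, upper = hi,
      ci_level = level, span_start = as.integer(span_start),
      span_end = as.integer(span_end), flags = flags)
    prev_end <- span_end
    nxt <- which(starts > span_end)
    j <- if (length(nxt)) nxt[1] else n + 1L
  }
  if (length(rows) == 0) .empty_records() else bind_rows(rows)
}
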