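# Grammar configuration and the template catalogue shared by the parser and
# the synthetic-literature renderer.

#' Grammar configuration for interval extraction
#'
#' Controls which template families the parser scans for and how much
#' preceding context is inspected when resolving the estimate type and the
#' confidence level of a match.
#'
#' Three template families cover the common typeset forms of a ratio estimate
#' with its confidence interval:
#'
#' * `paren`: `"OR 1.50 (95% CI 1.20 to 1.90)"` and its dash/comma/colon
#'   variants;
#' * `bracket`: `"RR = 2.0 [1.1-3.6]"`, with or without an explicit CI label;
#' * `inline`: `"HR 0.85; 95% CI 0.75 to 0.97"` (also with a comma in place
#'   of the semicolon).
#'
#' @param families Character vector of enabled template families, a subset of
#'   `c("paren", "bracket", "inline")`.
#' @param window Integer, number of characters of context before a matched
#'   interval that are scanned for the estimate type (e.g. "hazard ratio",
#'   "aOR") and, as a fallback, the confidence level. Bounded so behaviour is
#'   deterministic.
#'
#' @return A list of class `grammar_config`.
#' @examples
#' grammar_config()
#' grammar_config(families = c("paren", "inline"), window = 40)
#' @export
grammar_config <- function(families = c("paren", "bracket", "inline"),
                           window = 60) {
  families <- match.arg(families, c("paren", "bracket", "inline"),
                        several.ok = TRUE)
  stopifnot(is.numeric(window), length(window) == 1, window >= 0)
  structure(list(families = families, window = as.integer(window)),
            class = "grammar_config")
}

# Numeric sub-grammar: plain decimals only. Thousands separators and
# comma-as-decimal are rejected by construction (see parse_number()).
.re_num <- "\\d+(?:\\.\\d+)?"
# An estimate must not continue a larger token: no digit, decimal point,
# thousands comma, hyphen/dash/minus immediately before it.
.re_est_guard <- "(?<![0-9.,–−-])"
.re_level <- "(?:(\\d{1,2}(?:\\.\\d)?)\\s*%\\s*)?"
.re_ciword <- "(?:CI\\b|C\\.I\\.|[Cc]onfidence\\s+[Ii]ntervals?\\b)"
.re_sep_wide <- "(?:to|[–−,-])" # to, hyphen, en dash, minus, comma
.re_sep_narrow <- "(?:to|[–−-])" # no comma (comma opens the inline family)

.family_regex <- function(family) {
  switch(family,
    paren = paste0(
      .re_est_guard, "(", .re_num, ")\\s*\\(\\s*", .re_level, .re_ciword,
      "\\s*[:=]?\\s*(", .re_num, ")\\s*", .re_sep_wide,
      "\\s*(", .re_num, ")\\s*\\)"),
    bracket = paste0(
      .re_est_guard, "(", .re_num, ")\\s*\\[\\s*(?:", .re_level, .re_ciword,
      "\\s*[:=]?\\s*)?(", .re_num, ")\\s*", .re_sep_wide,
      "\\s*(", .re_num, ")\\s*\\]"),
    inline = paste0(
      .re_est_guard, "(", .re_num, ")\\s*[;,]\\s*", .re_level, .re_ciword,
      "\\s*[:=]?\\s*(", .re_num, ")\\s*", .re_sep_narrow,
      "\\s*(", .re_num, ")(?!\\.?[0-9])"),
    abort(paste0("unknown template family: ", family))
  )
}

# Estimate-type dictionary. Abbreviations are matched case-sensitively
# (optionally prefixed "a" for adjusted); spelled-out names case-insensitively.
.type_patterns <- list(
  IRR = c("(?i)\\bincidence\\s+rate\\s+ratios?\\b", "\\ba?IRR\\b"),
  PR  = c("(?i)\\bprevalence\\s+ratios?\\b", "\\ba?PR\\b"),
  OR  = c("(?i)\\bodds\\s+ratios?\\b", "\\ba?OR\\b"),
  HR  = c("(?i)\\bhazard\\s+ratios?\\b", "\\ba?HR\\b"),
  RR  = c("(?i)\\brisk\\s+ratios?\\b", "(?i)\\brelative\\s+risks?\\b",
          "(?i)\\brate\\s+ratios?\\b", "\\ba?RR\\b")
)

# Text allowed between a type token and the estimate when the matched span is
# extended back to include the type token ("of", "was", "=", ":", ...).
.re_connector_gap <- "^[\\s=:,]*(?:(?i:of|was|were|is)[\\s=:,]+)*$"

#' Template catalogue for rendering and round-trip testing
#'
#' Enumerates the supported textual renderings of a ratio estimate with a
#' confidence interval. The same catalogue drives [render_abstract()] and
#' defines what [parse_document()] must recover, which makes extraction
#' recall directly testable.
#'
#' @return A tibble with one row per template: `template_id`, `family`
#'   (parser family that recognises it), `type_style` (how the estimate type
#'   is written: `"abbrev"`, `"abbrev_eq"`, `"spelled"`, `"spelled_of"`,
#'   `"adjusted"`, or `"none"`), `has_level` (whether the confidence level is
#'   printed), and `pattern`, a format string with placeholders `{type}`,
#'   `{est}`, `{level}`, `{lower}`, `{upper}`.
#' @examples
#' template_catalogue()
#' @export
template_catalogue <- function() {
  tribble(
    ~template_id,      ~family,   ~type_style, ~has_level, ~pattern,
    "paren_to",        "paren",   "abbrev",    TRUE,
      "{type} {est} ({level}% CI {lower} to {upper})",
    "paren_to_conf",   "paren",   "spelled_of", TRUE,
      "{type} of {est} ({level}% confidence interval {lower} to {upper})",
    "paren_endash",    "paren",   "spelled",   TRUE,
      "{type} {est} ({level}% CI {lower}–{upper})",
    "paren_hyphen",    "paren",   "abbrev_eq", TRUE,
      "{type} = {est} ({level}% CI {lower}-{upper})",
    "paren_comma",     "paren",   "adjusted",  TRUE,
      "{type} {est} ({level}% CI: {lower}, {upper})",
    "paren_nolevel",   "paren",   "abbrev",    FALSE,
      "{type} {est} (CI {lower} to {upper})",
    "bracket_hyphen",  "bracket", "abbrev_eq", FALSE,
      "{type} = {est} [{lower}-{upper}]",
    "bracket_endash",  "bracket", "abbrev",    FALSE,
      "{type} {est} [{lower}–{upper}]",
    "bracket_level",   "bracket", "spelled",   TRUE,
      "{type} {est} [{level}% CI {lower} to {upper}]",
    "semi_to",         "inline",  "abbrev",    TRUE,
      "{type} {est}; {level}% CI {lower} to {upper}",
    "comma_to",        "inline",  "spelled",   TRUE,
      "{type} {est}, {level}% CI {lower} to {upper}",
    "paren_plain",     "paren",   "none",      TRUE,
      "estimate {est} ({level}% CI {lower} to {upper})"
  )
}

# How each estimate type is written under each type_style.
.type_render <- function(type, style) {
  spelled <- c(OR = "odds ratio", HR = "hazard ratio", RR = "risk ratio",
               IRR = "incidence rate ratio", PR = "prevalence ratio")
  switch(style,
    abbrev    = type,
    abbrev_eq = type,
    spelled   = spelled[[type]],
    spelled_of = spelled[[type]],
    adjusted  = paste("adjusted", spelled[[type]]),
    none      = "",
    abort(paste0("unknown type_style: ", style))
  )
}
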