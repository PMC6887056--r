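# Rendering simulated interval records as abstract-like text.

.render_prefixes <- c(
  "Compared with controls, the ",
  "In the multivariable model, the ",
  "Overall, treatment was associated with an effect: ",
  "After adjustment for confounders, the association gave ",
  "The primary analysis showed "
)
.render_suffixes <- c(
  " in the study population.",
  " over the follow-up period.",
  ", which was consistent across subgroups.",
  " among participants.",
  "."
)

.fmt_num <- function(x, digits) sprintf("%.*f", digits, x)

#' Render one interval record as an abstract-like document
#'
#' Instantiates a template from [template_catalogue()] with the record's
#' values, rounded to `digits` decimal places (the printed precision), and
#' wraps the phrase in a short sentence. Rendering is deterministic given
#' the RNG state, and every rendered document is recoverable by
#' [parse_document()], which is what makes end-to-end extraction testable.
#'
#' @param record A one-row data frame with `point_estimate`, `lower`,
#'   `upper`, `ci_level` and `estimate_type`.
#' @param template_id A template id from [template_catalogue()].
#' @param doc_id Document id for the rendered document.
#' @param year Publication year to assign; `NA` draws one from 1976–2019.
#' @param section `"abstract"` or `"fulltext"`.
#' @param digits Printed decimal places (default 2).
#' @return A one-row tibble with columns `doc_id`, `year`, `section`,
#'   `text`, `template_id`.
#' @examples
#' rec <- tibble::tibble(estimate_type = "OR", point_estimate = 1.5,
#'                       lower = 1.2, upper = 1.9, ci_level = 95)
#' render_abstract(rec, "paren_to")$text
#' @export
render_abstract <- function(record, template_id, doc_id = "doc1",
                            year = NA_integer_, section = "abstract",
                            digits = 2) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  cat_tbl <- template_catalogue()
  row <- cat_tbl[cat_tbl$template_id == template_id, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown template_id: ", template_id))
  }
  type <- record$estimate_type
  if (row$type_style != "none" &&
      (is.na(type) || !type %in% names(.type_patterns))) {
    abort("record$estimate_type must be one of OR/HR/RR/IRR/PR for this template")
  }
  type_txt <- .type_render(type, row$type_style)
  level <- record$ci_level
  if (row$has_level && (is.null(level) || is.na(level))) {
    abort("template prints a confidence level but the record has none")
  }
  phrase <- row$pattern
  phrase <- stringr::str_replace(phrase, stringr::fixed("{type}"), type_txt)
  phrase <- stringr::str_replace(phrase, stringr::fixed("{est}"),
                                 .fmt_num(record$point_estimate, digits))
  phrase <- stringr::str_replace(phrase, stringr::fixed("{level}"),
                                 format(level))
  phrase <- stringr::str_replace(phrase, stringr::fixed("{lower}"),
                                 .fmt_num(record$lower, digits))
  phrase <- stringr::str_replace(phrase, stringr::fixed("{upper}"),
                                 .fmt_num(record$upper, digits))
  phrase <- stringr::str_squish(phrase)
  prefix <- sample(.render_prefixes, 1)
  suffix <- sample(.render_suffixes, 1)
  if (is.na(year)) year <- sample(1976:2019, 1)
  tibble(doc_id = doc_id, year = as.integer(year), section = section,
         text = paste0(prefix, phrase, suffix), template_id = template_id)
}

#' Render a synthetic corpus as documents
#'
#' Renders every published record of a [generate_unbiased_corpus()] /
#' [generate_biased_corpus()] result as one abstract-like document, cycling
#' through the template catalogue (or a chosen subset). Values are printed
#' rounded to the configuration's `rounding_digits`; parsing the documents
#' recovers the records up to that printed rounding.
#'
#' @param corpus A `synthetic_corpus`.
#' @param template_ids Templates to cycle through (default: all templates
#'   whose type style fits the records; templates that print a confidence
#'   level require `ci_level` to be known).
#' @param seed Optional integer seed for the sentence dressing and years.
#' @return A list with `documents` (tibble: `doc_id`, `year`, `section`,
#'   `text`, `template_id`) and `mapping` (tibble: `doc_id`, `study_id`).
#' @export
render_corpus <- function(corpus, template_ids = NULL, seed = NULL) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (is.null(template_ids)) template_ids <- template_catalogue()$template_id
  recs <- corpus$records
  n <- nrow(recs)
  digits <- corpus$config$rounding_digits
  render_all <- function() {
    tmpl <- rep_len(template_ids, n)
    docs <- vector("list", n)
    for (i in seq_len(n)) {
      docs[[i]] <- render_abstract(recs[i, ], tmpl[i],
                                   doc_id = paste0("doc_", recs$study_id[i]),
                                   digits = digits)
    }
    purrr::list_rbind(docs)
  }
  documents <- if (!is.null(seed)) withr::with_seed(seed, render_all())
               else render_all()
  list(documents = documents,
       mapping = tibble(doc_id = documents$doc_id, study_id = recs$study_id))
}
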