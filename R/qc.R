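# Quality-control exclusions applied to extracted interval records.

#' Rule: exclude intervals whose printed lower limit is zero
#'
#' A ratio confidence interval cannot have a lower limit of exactly zero;
#' when one is printed it is taken to be an author error and the record is
#' excluded. The test is on the exactly parsed printed value (0, 0.0 and
#' 0.00 are all zero), not on a floating tolerance.
#'
#' @param lower Numeric vector of lower limits.
#' @return Logical vector, `TRUE` where the record should be excluded.
#' @examples
#' filter_zero_lower(c(0, 0.01, 1.20))
#' @export
filter_zero_lower <- function(lower) {
  stopifnot(is.numeric(lower))
  !is.na(lower) & lower == 0
}

#' Rule: exclude intervals that do not contain their point estimate
#'
#' When the reported point estimate falls outside its own confidence
#' interval, the interval or the estimate (or both) must be wrong, and the
#' record is excluded. Containment is inclusive of both limits: an estimate
#' printed equal to a limit is a legitimate rounding outcome and is kept.
#'
#' @param point_estimate,lower,upper Numeric vectors.
#' @return Logical vector, `TRUE` where the record should be excluded.
#' @examples
#' filter_mean_outside(2.0, 0.9, 1.8) # TRUE
#' filter_mean_outside(1.2, 1.2, 1.9) # FALSE (inclusive boundary)
#' @export
filter_mean_outside <- function(point_estimate, lower, upper) {
  stopifnot(is.numeric(point_estimate), is.numeric(lower), is.numeric(upper))
  !is.na(point_estimate) & !is.na(lower) & !is.na(upper) &
    (point_estimate < lower | point_estimate > upper)
}

.qc_reasons <- c("zero_lower", "mean_outside", "nonpositive_value",
                 "malformed")

#' Apply the quality-control exclusions to a record table
#'
#' Applies the exclusion rules in a fixed order — `zero_lower`, then
#' `mean_outside`, then `nonpositive_value` (a non-positive upper limit or
#' point estimate, impossible for a ratio), then `malformed` (missing or
#' non-finite values) — and counts each excluded record under the first rule
#' it violates. Retained records all satisfy
#' `0 < lower <= point_estimate <= upper`.
#'
#' @param records A tibble of interval records with at least the columns
#'   `point_estimate`, `lower`, `upper` (as produced by [parse_documents()]).
#' @return An object of class `qc_report`: a list with elements `retained`
#'   (tibble), `excluded` (tibble with an extra `reason` column), `counts`
#'   (named integer vector over all reasons), and `input_count`. Has
#'   [tidy()] and [glance()] methods.
#' @examples
#' recs <- tibble::tibble(point_estimate = c(1.5, 2.0, 1.2),
#'                        lower = c(1.2, 0.9, 0), upper = c(1.9, 1.8, 1.5))
#' apply_qc(recs)
#' @export
apply_qc <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("point_estimate", "lower", "upper")
  if (!all(needed %in% names(records))) {
    abort("`records` must have columns point_estimate, lower and upper.")
  }
  records <- as_tibble(records)
  n <- nrow(records)
  if (n == 0) {
    return(structure(
      list(retained = records,
           excluded = mutate(records, reason = character(0)),
           counts = setNames(integer(length(.qc_reasons)), .qc_reasons),
           input_count = 0L),
      class = "qc_report"))
  }
  bad_value <- !is.finite(records$point_estimate) |
    !is.finite(records$lower) | !is.finite(records$upper)
  reason <- rep(NA_character_, n)
  zl <- !bad_value & filter_zero_lower(records$lower)
  reason[zl] <- "zero_lower"
  mo <- is.na(reason) & !bad_value &
    filter_mean_outside(records$point_estimate, records$lower, records$upper)
  reason[mo] <- "mean_outside"
  np <- is.na(reason) & !bad_value &
    (records$upper <= 0 | records$point_estimate <= 0 | records$lower < 0)
  reason[np] <- "nonpositive_value"
  reason[is.na(reason) & bad_value] <- "malformed"

  keep <- is.na(reason)
  counts <- vapply(.qc_reasons, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  structure(
    list(retained = records[keep, , drop = FALSE],
         excluded = mutate(records[!keep, , drop = FALSE],
                           reason = reason[!keep]),
         counts = counts,
         input_count = n),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$input_count, " records: ",
      nrow(x$retained), " retained, ", nrow(x$excluded), " excluded\n",
      sep = "")
  for (r in names(x$counts)) {
    if (x$counts[[r]] > 0) {
      cat(sprintf("  %-18s %d (%.1f%%)\n", r, x$counts[[r]],
                  100 * x$counts[[r]] / x$input_count))
    }
  }
  invisible(x)
}

#' Tidy a QC report into per-rule exclusion counts
#'
#' @param x A `qc_report` from [apply_qc()].
#' @param ... Unused.
#' @return A tibble with columns `reason`, `n`, `proportion` (of the input).
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  tibble(reason = names(x$counts), n = as.integer(x$counts),
         proportion = if (x$input_count > 0) {
           as.integer(x$counts) / x$input_count
         } else rep(0, length(x$counts)))
}

#' One-row summary of a QC report
#'
#' @param x A `qc_report` from [apply_qc()].
#' @param ... Unused.
#' @return A one-row tibble: `input_count`, `retained`, `excluded`,
#'   `prop_excluded`.
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble(input_count = x$input_count, retained = nrow(x$retained),
         excluded = nrow(x$excluded),
         prop_excluded = if (x$input_count > 0) {
           nrow(x$excluded) / x$input_count
         } else 0)
}

#' Impute a default confidence level where none was stated
#'
#' Records whose confidence level could not be determined from the text are
#' retained with an unknown level. For the distribution diagnostics they are
#' treated as 95% intervals (the overwhelmingly common case); this helper
#' makes that imputation explicit and flags it.
#'
#' @param records A tibble of interval records with a `ci_level` column.
#' @param level Level in percent to impute (default 95).
#' @return `records` with `ci_level` filled in and the flag `level_imputed`
#'   appended to `flags` on affected rows.
#' @export
impute_ci_level <- function(records, level = 95) {
  stopifnot(is.data.frame(records), "ci_level" %in% names(records))
  miss <- is.na(records$ci_level)
  records$ci_level[miss] <- level
  if ("flags" %in% names(records)) {
    records$flags[miss] <- ifelse(nzchar(records$flags[miss]),
                                  paste0(records$flags[miss], ";level_imputed"),
                                  "level_imputed")
  }
  records
}
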