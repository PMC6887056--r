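# Distribution diagnostics for interval limits around the null value 1.

#' Classify the statistical significance implied by an interval
#'
#' For a ratio estimate the null value is 1: a lower limit above 1 means a
#' statistically significant increase (`sig_above`), an upper limit below 1 a
#' significant decrease (`sig_below`). Inequalities are strict, so an
#' interval touching the null value exactly is `nonsig`.
#'
#' @param records A tibble with columns `lower` and `upper`.
#' @param null_value The null value on the ratio scale (default 1).
#' @return `records` with an added character column `significance` in
#'   `c("sig_above", "sig_below", "nonsig")`.
#' @examples
#' classify_significance(tibble::tibble(lower = c(1.01, 0.4, 0.8, 1.0),
#'                                      upper = c(2.3, 0.99, 1.2, 1.5)))
#' @export
classify_significance <- function(records, null_value = 1) {
  stopifnot(is.data.frame(records),
            all(c("lower", "upper") %in% names(records)))
  mutate(records, significance = case_when(
    .data$lower > null_value ~ "sig_above",
    .data$upper < null_value ~ "sig_below",
    TRUE ~ "nonsig"))
}

#' Empirical cumulative distribution of interval limits
#'
#' Standard right-continuous ECDF (proportion of values `<= x`) with ties
#' collapsed to a single step. This is the primary summary of the limit
#' distribution: it needs no tuning parameter and makes a discontinuity at
#' the null value visible as a vertical jump.
#'
#' @param limits Numeric vector of limit values (ratio scale), non-empty and
#'   finite.
#' @return A tibble of class `ecdf_curve` with columns `value` (ascending
#'   unique values) and `cum_prop` (cumulative proportions ending at 1), and
#'   attribute `n` (sample size). Has an [ggplot2::autoplot()] method.
#' @examples
#' ci_ecdf(c(0.5, 1.0, 2.0))
#' @export
ci_ecdf <- function(limits) {
  if (!is.numeric(limits) || length(limits) == 0) {
    abort("`limits` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(limits))) abort("`limits` must be finite.")
  tab <- table(limits)
  vals <- as.numeric(names(tab))
  out <- tibble(value = vals,
                cum_prop = cumsum(as.integer(tab)) / length(limits))
  attr(out, "n") <- length(limits)
  class(out) <- c("ecdf_curve", class(out))
  out
}

#' Evaluate an ECDF curve at arbitrary points
#'
#' @param curve An `ecdf_curve` from [ci_ecdf()].
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of cumulative proportions `P(value <= x)`.
#' @export
eval_ecdf <- function(curve, x) {
  stopifnot(inherits(curve, "ecdf_curve"))
  idx <- findInterval(x, curve$value)
  c(0, curve$cum_prop)[idx + 1]
}

#' Jump statistic: excess of just-significant interval limits at the null
#'
#' A purely descriptive measure of the surplus of interval limits just
#' inside the statistically significant side of the null value, relative to
#' the mirror window on the other side. For lower limits the significant
#' side is above the null:
#' `excess = P(limit in (1, 1 + eps]) - P(limit in [1 - eps, 1))`;
#' for upper limits the significant side is below the null and the sign is
#' mirrored, so a glut of just-significant results is always a positive
#' excess. No p-value is attached: the statistic quantifies the visual
#' discontinuity of the cumulative distribution, it is not a test.
#'
#' @param limits Numeric vector of limit values, non-empty.
#' @param side `"lower_limits"` or `"upper_limits"`: which limit the values
#'   are.
#' @param null_value Null value on the ratio scale (default 1).
#' @param epsilon Window half-width in ratio units (default 0.05).
#' @return A one-row tibble of class `jump_statistic`: `side`, `epsilon`,
#'   `excess`, `n`, `p_significant_side`, `p_mirror_side` (the two window
#'   masses) and `mc_se`, the Monte-Carlo standard error of `excess`.
#' @examples
#' jump_statistic(c(rep(1.01, 90), rep(0.99, 10)), "lower_limits")
#' @export
jump_statistic <- function(limits, side = c("lower_limits", "upper_limits"),
                           null_value = 1, epsilon = 0.05) {
  side <- match.arg(side)
  if (!is.numeric(limits) || length(limits) == 0) {
    abort("`limits` must be a non-empty numeric vector.")
  }
  stopifnot(epsilon > 0)
  n <- length(limits)
  above <- mean(limits > null_value & limits <= null_value + epsilon)
  below <- mean(limits >= null_value - epsilon & limits < null_value)
  if (side == "lower_limits") {
    sig <- above; mirror <- below
  } else {
    sig <- below; mirror <- above
  }
  excess <- sig - mirror
  out <- tibble(side = side, epsilon = epsilon, excess = excess, n = n,
                p_significant_side = sig, p_mirror_side = mirror,
                mc_se = sqrt(max(sig + mirror - excess^2, 0) / n))
  class(out) <- c("jump_statistic", class(out))
  out
}

#' Assign records to fixed-width publication-year periods
#'
#' Bins records into consecutive periods (default 5 years) anchored at a
#' fixed first year, e.g. 1976–1980, 1981–1985, ... The final period may be
#' partial and is reported as-is. Records without a year are dropped with a
#' message giving the count.
#'
#' @param records A tibble with a `year` column.
#' @param width Period width in years (default 5).
#' @param anchor_year First year of the first period (default 1976).
#' @return `records` (rows with known year) with added columns
#'   `period_start`, `period_end` (inclusive) and `period` (label such as
#'   `"1976-1980"`).
#' @examples
#' bin_by_period(tibble::tibble(year = c(1976, 1980, 1981, 2019)))
#' @export
bin_by_period <- function(records, width = 5, anchor_year = 1976) {
  stopifnot(is.data.frame(records), "year" %in% names(records),
            width >= 1)
  missing_year <- is.na(records$year)
  if (any(missing_year)) {
    message(sum(missing_year), " record(s) without a year dropped from period binning")
    records <- records[!missing_year, , drop = FALSE]
  }
  idx <- floor((records$year - anchor_year) / width)
  records$period_start <- as.integer(anchor_year + idx * width)
  records$period_end <- as.integer(records$period_start + width - 1)
  records$period <- paste0(records$period_start, "-", records$period_end)
  records
}

#' Histogram of interval limits on a restricted ratio axis
#'
#' Fixed-binwidth histogram used as a supplementary view of the limit
#' distribution. Bins are half-open `[a, a + w)` anchored at the lower end
#' of the range; values outside the range are excluded, mirroring the
#' restriction of the plots to ratios between 0.25 and 4.
#'
#' @param limits Numeric vector of limit values.
#' @param binwidth Bin width in ratio units (default 0.1).
#' @param range Two-element numeric, values outside are excluded
#'   (default `c(0.25, 4)`, inclusive).
#' @return A tibble with columns `bin_start`, `bin_end`, `count`; counts sum
#'   to the number of in-range values.
#' @examples
#' ci_histogram(c(0.95, 1.04, 1.05))
#' @export
ci_histogram <- function(limits, binwidth = 0.1, range = c(0.25, 4)) {
  stopifnot(is.numeric(limits), binwidth > 0, length(range) == 2,
            range[1] < range[2])
  x <- limits[is.finite(limits) & limits >= range[1] & limits <= range[2]]
  nbins <- ceiling((range[2] - range[1]) / binwidth + 1e-8)
  # tolerance shields bin assignment from floating-point representation of
  # the anchor arithmetic (e.g. (0.35 - 0.25)/0.1 < 1)
  idx <- pmin(floor((x - range[1]) / binwidth + 1e-8), nbins - 1)
  counts <- tabulate(idx + 1L, nbins)
  tibble(bin_start = range[1] + (seq_len(nbins) - 1) * binwidth,
         bin_end = range[1] + seq_len(nbins) * binwidth,
         count = counts)
}

#' Limit-distribution curves for a set of interval records
#'
#' Convenience wrapper producing the tidy curve table behind the cumulative
#' distribution figures: one ECDF per side (lower and upper limits), and
#' optionally per group (e.g. section or period).
#'
#' @param records A tibble with `lower` and `upper` columns.
#' @param by Optional name of a grouping column (e.g. `"period"` after
#'   [bin_by_period()], or `"section"`).
#' @return A tibble with columns `side`, the grouping column (if any),
#'   `value`, `cum_prop`.
#' @export
limit_ecdf_curves <- function(records, by = NULL) {
  stopifnot(is.data.frame(records),
            all(c("lower", "upper") %in% names(records)))
  long <- tidyr::pivot_longer(
    records, c("lower", "upper"), names_to = "side", values_to = "value") |>
    mutate(side = paste0(.data$side, "_limits"))
  grouping <- c("side", by)
  long |>
    group_by(across(all_of(grouping))) |>
    reframe({
      curve <- ci_ecdf(.data$value)
      tibble(value = curve$value, cum_prop = curve$cum_prop)
    })
}
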