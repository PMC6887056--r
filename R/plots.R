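# Figures: cumulative distributions and histograms of interval limits.

#' @importFrom ggplot2 ggplot aes geom_step geom_vline geom_col facet_wrap
#'   coord_cartesian labs theme_minimal autoplot ggsave
NULL

#' Plot cumulative distributions of interval limits
#'
#' One panel per side (lower and upper limits), a vertical reference line at
#' the null value, x-axis restricted to the stated ratio range (the data are
#' not truncated, only the axis). With a grouping column (e.g. `period`) the
#' curves are overlaid and coloured by group, as in the by-period view.
#'
#' @param records A tibble with `lower` and `upper` columns (e.g. the
#'   retained records of a [apply_qc()] report).
#' @param by Optional grouping column name, e.g. `"period"` after
#'   [bin_by_period()].
#' @param range x-axis range on the ratio scale (default `c(0.25, 4)`).
#' @param null_line Null value marked with a vertical line (default 1).
#' @param file Optional path; when given the figure is also written there
#'   (format from the extension, e.g. `.pdf` or `.png`).
#' @return The ggplot object, invisibly when `file` is given.
#' @export
plot_curves <- function(records, by = NULL, range = c(0.25, 4),
                        null_line = 1, file = NULL) {
  curves <- limit_ecdf_curves(records, by = by)
  p <- ggplot(curves, aes(x = .data$value, y = .data$cum_prop)) +
    (if (is.null(by)) geom_step(linewidth = 0.4)
     else geom_step(aes(colour = factor(.data[[by]])), linewidth = 0.4)) +
    geom_vline(xintercept = null_line, linetype = "dashed",
               colour = "grey40") +
    facet_wrap(~side) +
    coord_cartesian(xlim = range) +
    labs(x = "Interval limit (ratio scale)",
         y = "Cumulative proportion", colour = by) +
    theme_minimal()
  if (!is.null(file)) {
    ggsave(file, p, width = 8, height = 4)
    return(invisible(p))
  }
  p
}

#' Plot histograms of interval limits
#'
#' Supplementary fixed-binwidth view of the limit distribution on the
#' restricted ratio axis.
#'
#' @inheritParams plot_curves
#' @param binwidth Bin width in ratio units (default 0.1).
#' @return The ggplot object, invisibly when `file` is given.
#' @export
plot_histograms <- function(records, binwidth = 0.1, range = c(0.25, 4),
                            null_line = 1, file = NULL) {
  stopifnot(is.data.frame(records),
            all(c("lower", "upper") %in% names(records)))
  hists <- bind_rows(
    mutate(ci_histogram(records$lower, binwidth, range),
           side = "lower_limits"),
    mutate(ci_histogram(records$upper, binwidth, range),
           side = "upper_limits"))
  p <- ggplot(hists, aes(x = .data$bin_start + binwidth / 2,
                         y = .data$count)) +
    geom_col(width = binwidth, fill = "grey55") +
    geom_vline(xintercept = null_line, linetype = "dashed",
               colour = "grey30") +
    facet_wrap(~side) +
    coord_cartesian(xlim = range) +
    labs(x = "Interval limit (ratio scale)", y = "Count") +
    theme_minimal()
  if (!is.null(file)) {
    ggsave(file, p, width = 8, height = 4)
    return(invisible(p))
  }
  p
}

#' @describeIn ci_ecdf Autoplot method: step plot of the curve with a
#'   reference line at 1.
#' @param object An `ecdf_curve`.
#' @param ... Unused.
#' @method autoplot ecdf_curve
#' @export
autoplot.ecdf_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$value, y = .data$cum_prop)) +
    geom_step() +
    geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    labs(x = "Interval limit (ratio scale)", y = "Cumulative proportion") +
    theme_minimal()
}
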