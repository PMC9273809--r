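#' Plot anchor-group mean changes with confidence intervals
#'
#' Point-and-interval display of the mean target change per anchor-change
#' category, one panel per anchor — the standard way to eyeball where the
#' one-category improvement mean sits relative to candidate thresholds.
#'
#' @param group_summaries A tibble from [summarize_groups()] or the
#'   `group_summaries` element of an [run_pipeline()] report.
#' @return A ggplot object.
#' @export
plot_group_means <- function(group_summaries) {
  ggplot2::ggplot(
    group_summaries,
    ggplot2::aes(x = factor(.data$category), y = .data$mean)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::facet_wrap(~anchor) +
    ggplot2::labs(
      x = "anchor change category (positive = improvement)",
      y = "mean QLDS change (95% CI)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot stratified ECDF responder curves
#'
#' Step curves of the empirical CDF of target change, one per anchor-change
#' category; separation between the curves supports the anchor's grouping.
#'
#' @param cdf A list from [stratified_cdfs()].
#' @return A ggplot object.
#' @export
plot_cdf_curves <- function(cdf) {
  curves <- if (is.data.frame(cdf)) cdf else cdf$curves
  ggplot2::ggplot(
    curves,
    ggplot2::aes(x = .data$value, y = .data$proportion,
                 colour = factor(.data$category))
  ) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(
      x = "QLDS change from baseline",
      y = "cumulative proportion",
      colour = "anchor change\ncategory"
    ) +
    ggplot2::theme_minimal()
}

#' Plot triangulated threshold candidates
#'
#' Dot plot of every candidate threshold by provenance, with the pooled
#' median and the recommended integer threshold marked.
#'
#' @param x An `mct_triangulation` from [triangulate()].
#' @return A ggplot object.
#' @export
plot_candidates <- function(x) {
  stopifnot(inherits(x, "mct_triangulation"))
  df <- x$candidates
  df$label <- ifelse(is.na(df$anchor), df$source, df$anchor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$label)) +
    ggplot2::geom_vline(xintercept = x$median, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = x$recommended, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "candidate threshold (QLDS change)", y = NULL,
      subtitle = sprintf("median %.2f (solid), recommended %d (dashed)",
                         x$median, x$recommended)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot mct_triangulation
#' @export
autoplot.mct_triangulation <- function(object, ...) plot_candidates(object)

#' @method autoplot mct_report
#' @export
autoplot.mct_report <- function(object, ...) plot_group_means(object$group_summaries)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
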