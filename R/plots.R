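#' Plot a cumulative fiber-intensity curve
#'
#' The S-curve of cumulative percent of fibers against per-fiber mean
#' dystrophin intensity. A steeper slope means more homogeneous expression;
#' an overall increase in dystrophin shifts the curve right.
#'
#' @param object A `cumulative_curve` from [cumulative_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cumulative_curve
#' @export
autoplot.cumulative_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$percent)) +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::labs(x = "Mean dystrophin intensity per fiber (au)",
                  y = "Cumulative percent of fibers") +
    ggplot2::theme_minimal()
}

#' Histogram of per-fiber mean dystrophin intensity
#'
#' Freedman-Diaconis bin width by default (override with `binwidth`), since
#' the informative feature is the distribution shape, not a fixed bin count.
#'
#' @param metrics Per-fiber metrics tibble (needs `dys_mean`).
#' @param binwidth Optional bin width (au).
#' @return A ggplot.
#' @export
plot_fiber_histogram <- function(metrics, binwidth = NULL) {
  x <- metrics$dys_mean
  if (is.null(binwidth)) {
    fd <- 2 * stats::IQR(x) / length(x)^(1 / 3)
    binwidth <- if (fd > 0) fd else NULL
  }
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$dys_mean)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "Mean dystrophin intensity per fiber (au)",
                  y = "Number of fibers") +
    ggplot2::theme_minimal()
}

#' Overlay pre/post cumulative curves
#'
#' @param pre_values,post_values Per-fiber mean intensities of the two
#'   visits (au).
#' @return A ggplot with one S-curve per visit.
#' @export
plot_visit_curves <- function(pre_values, post_values) {
  d <- bind_rows(
    cumulative_distribution(pre_values) |> mutate(visit = "pre"),
    cumulative_distribution(post_values) |> mutate(visit = "post")
  ) |> mutate(visit = factor(.data$visit, levels = c("pre", "post")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$percent,
                                  colour = .data$visit)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Mean dystrophin intensity per fiber (au)",
                  y = "Cumulative percent of fibers", colour = "Visit") +
    ggplot2::theme_minimal()
}
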