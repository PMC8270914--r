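# Optional ggplot2 figures; the package only Suggests ggplot2.

#' Plot coverage curves
#'
#' @param curves data frame with columns `S`, `Pi` and optionally `subset`
#'   and `metric` (as written by [run_pipeline()] to `coverage.csv`).
#' @return a ggplot object.
#' @export
plot_coverage_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_rr("ggplot2 is required for plotting")
  if (is.null(curves$subset)) curves$subset <- "all"
  if (is.null(curves$metric)) curves$metric <- "ud"
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$S, y = .data$Pi,
                                       colour = .data$metric,
                                       linetype = .data$subset)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "protected reef slope S (km2)",
                  y = expression(Pi(S)),
                  title = "MPA ability to fully cover shark home range") +
    ggplot2::theme_minimal()
}

#' Plot a cumulative home-range curve with its bootstrap band
#'
#' @param curve a [cumulative_curve()] object.
#' @return a ggplot object.
#' @export
plot_cumulative_curve <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_rr("ggplot2 is required for plotting")
  d <- data.frame(x = curve$values, y = curve$fraction,
                  lo = curve$lower, hi = curve$upper)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "UD (km2 of reef slope)",
                  y = "cumulative fraction of sharks") +
    ggplot2::theme_minimal()
}
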