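# ggplot2 views of the evaluation harness results.

#' Plot sensitivity (or FDR) over the coverage grid
#'
#' One line per normal-genome coverage, tumor coverage on the x axis — the
#' standard view of how sequencing throughput in either sample buys
#' detection performance.
#'
#' @param object A [coverage_grid()] result.
#' @param metric `"sensitivity"` or `"fdr"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coverage_grid <- function(object, metric = c("sensitivity", "fdr"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$coverage_tumor, y = .data[[metric]],
      colour = factor(.data$coverage_normal),
      group = factor(.data$coverage_normal)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2", breaks = unique(object$coverage_tumor)) +
    ggplot2::labs(
      x = "tumor coverage (x)", y = metric, colour = "normal coverage (x)",
      title = sprintf("Somatic detection %s by coverage", metric)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.coverage_grid
#' @export
plot_coverage_grid <- function(object, metric = c("sensitivity", "fdr"), ...) {
  autoplot.coverage_grid(object, metric, ...)
}

#' Plot sensitivity across tumor purities
#'
#' @param object A [purity_sweep()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.purity_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$purity, y = .data$sensitivity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(
      x = "tumor purity", y = "sensitivity",
      title = "Somatic detection sensitivity by tumor purity"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.purity_sweep
#' @export
plot_purity_sweep <- function(object, ...) autoplot.purity_sweep(object, ...)
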