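#' Heatmap of threshold-averaged global reliability by strategy and metric
#'
#' @param rel_global Tibble from [reliability_global()].
#' @return A ggplot object.
#' @export
plot_reliability_global <- function(rel_global) {
  df <- dplyr::filter(rel_global, .data$density == "mean")
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$metric, fill = .data$icc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$icc)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(
      x = "processing strategy", y = NULL, fill = "ICC(A,1)",
      title = "Threshold-averaged test-retest reliability of global metrics"
    ) +
    ggplot2::theme_minimal()
}

#' ICC as a function of network density
#'
#' One line per processing strategy, faceted by metric.
#'
#' @param rel_global Tibble from [reliability_global()].
#' @return A ggplot object.
#' @export
plot_icc_by_density <- function(rel_global) {
  df <- dplyr::filter(rel_global, .data$density != "mean")
  df$density <- as.numeric(df$density)
  ggplot2::ggplot(df, ggplot2::aes(.data$density, .data$icc, colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(
      x = "network density", y = "ICC(A,1)", colour = "strategy",
      title = "Reliability across the proportional-threshold sweep"
    ) +
    ggplot2::theme_minimal()
}

#' Distribution of nodal reliabilities by strategy
#'
#' @param rel_nodal Tibble from [reliability_nodal()].
#' @return A ggplot object (boxplots faceted by nodal metric).
#' @export
plot_reliability_nodal <- function(rel_nodal) {
  ggplot2::ggplot(rel_nodal, ggplot2::aes(.data$method, .data$icc)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(
      x = "processing strategy", y = "ICC(A,1) of AUC over densities",
      title = "Nodal test-retest reliability"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.reliability_study <- function(object, type = c("global", "density", "nodal"), ...) {
  type <- match.arg(type)
  switch(type,
    global = plot_reliability_global(object$reliability_global),
    density = plot_icc_by_density(object$reliability_global),
    nodal = plot_reliability_nodal(object$reliability_nodal)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
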