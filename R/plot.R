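#' Plot a coverage track
#'
#' Strand-resolved per-position read depth, optionally on a logarithmic
#' scale as customary for mitochondrial transcriptome coverage plots.
#'
#' @param object A [coverage_track()] result.
#' @param log_scale Plot depth on a log10 axis (positions with zero depth
#'   are dropped from the log plot).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uindel_coverage <- function(object, log_scale = TRUE, ...) {
  long <- tidyr::pivot_longer(object, c("sense", "antisense"),
                              names_to = "strand", values_to = "depth")
  if (log_scale) long <- dplyr::filter(long, .data$depth > 0)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$position,
                                          y = .data$depth,
                                          fill = .data$strand)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~strand, ncol = 1) +
    ggplot2::labs(x = "position (nt)", y = "read depth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a misediting summary
#'
#' Read-class composition per editing domain (reference / main pathway /
#' alternative), mirroring the per-domain pie-chart style summaries of
#' alternative editing as stacked bars.
#'
#' @param object A [misediting_summary()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uindel_misediting <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$by_domain,
    c("n_reference", "n_main", "n_alternative"),
    names_to = "class", values_to = "n_reads",
    names_prefix = "n_")
  long$class <- factor(long$class,
                       levels = c("reference", "main", "alternative"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$domain),
                                     y = .data$n_reads,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "editing domain", y = "reads", fill = "read class") +
    ggplot2::theme_minimal()
}
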