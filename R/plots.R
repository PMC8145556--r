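# ggplot2 views of benchmark and QC results.

#' Heatmap of benchmark sensitivity/specificity
#'
#' One tile per metric and group, faceted by contamination kind, so the
#' detection profile of every metric can be read at a glance.
#'
#' @param sens output of [sensitivity_table()].
#' @return a ggplot object.
#' @export
plot_sensitivity <- function(sens) {
  ggplot2::ggplot(sens, ggplot2::aes(x = .data$group, y = .data$metric,
                                     fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "white", mid = "orange",
                                  high = "#4f9bd5", midpoint = 0.5,
                                  limits = c(0, 1), name = NULL) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$kind), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Metric distributions of a panel run against thresholds
#'
#' @param metric_table output of [run_panel()].
#' @param metric metric column to plot.
#' @param thresholds optional threshold tibble; species ranges are drawn as
#'   dashed lines.
#' @return a ggplot object.
#' @export
plot_panel_metric <- function(metric_table, metric, thresholds = NULL) {
  p <- ggplot2::ggplot(metric_table,
                       ggplot2::aes(x = factor(.data$ratio),
                                    y = .data[[metric]],
                                    colour = .data$subject,
                                    shape = .data$kind)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::labs(x = "mixing ratio", y = metric) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    thr <- dplyr::filter(thresholds, .data$rank == "species",
                         .data$metric == !!metric)
    if (nrow(thr)) {
      thr_long <- tidyr::pivot_longer(thr, c("low", "high"),
                                      names_to = "bound", values_to = "y")
      thr_long <- dplyr::filter(thr_long, !is.na(.data$y))
      p <- p + ggplot2::geom_hline(
        data = thr_long,
        ggplot2::aes(yintercept = .data$y, colour = .data$taxon),
        linetype = "dashed", alpha = 0.7)
    }
  }
  p
}

#' @export
autoplot.qc_report <- function(object, ...) {
  d <- tidy(object)
  d$status <- factor(d$status, levels = c("pass", "warn", "fail", "not-assessed"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = 1, fill = .data$status)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_manual(values = c(pass = "#66bb6a", warn = "#ffa726",
                                          fail = "#ef5350",
                                          `not-assessed` = "grey80"),
                               drop = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(title = sprintf("%s: %s", object$sample$name,
                                  object$sample$assessment$verdict),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
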