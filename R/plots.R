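#' Plot a labeled RR stream
#'
#' The classic rhythm-monitor view: RR interval against time, one dot
#' per beat, colored by the per-beat diagnosis (probable AF red, normal
#' blue, unclassified non-AF yellow, warm-up grey).
#'
#' @param object An `rr_labels` tibble from [classify_stream()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rr_labels <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_ms / 1000,
                                       y = .data$rr_ms,
                                       colour = .data$label)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = label_colors, drop = FALSE) +
    ggplot2::labs(x = "time (s)", y = "RR interval (ms)",
                  colour = "diagnosis") +
    ggplot2::theme_minimal()
}

#' Plot an RR series
#'
#' @param object An [rr_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rr_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_ms / 1000,
                                       y = .data$rr_ms)) +
    ggplot2::geom_point(size = 0.8, colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "RR interval (ms)") +
    ggplot2::theme_minimal()
}

#' Plot diagnostic metrics with their confidence intervals
#'
#' @param object A `diagnostic_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diagnostic_metrics <- function(object, ...) {
  df <- tidy(object)
  df$what <- paste(df$metric, df$flutter_handling, sep = "\n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$what, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "estimate (95% CI)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a contingency table
#'
#' @param object An `af_contingency`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.af_contingency <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey70", high = "firebrick") +
    ggplot2::theme_minimal()
}
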