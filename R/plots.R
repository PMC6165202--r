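# ggplot2 views of the result objects.

#' Heatmap of an ERD/ERS map
#'
#' Time-frequency heatmap of percent power change (blue = ERD, red = ERS),
#' with the task onset marked.
#'
#' @param object An `erders_map`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.erders_map <- function(object, ...) {
  df <- tidyr::expand_grid(freq = object$freqs, time = object$times)
  df$value <- as.vector(t(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "ERD/ERS (%)") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)",
                  title = object$label) +
    ggplot2::theme_minimal()
}

#' @export
plot.erders_map <- function(x, ...) print(autoplot.erders_map(x, ...))

#' Fold-accuracy distribution of a cross-validation result
#'
#' @param object An `eeg_cv`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.eeg_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$rep), y = .data$accuracy)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = object$mean, colour = "#b2182b") +
    ggplot2::labs(x = "Repetition", y = "Fold accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Per-ROI accuracy or SNR summary plot
#'
#' Point-and-error-bar summary of a per-subject, per-ROI measure.
#'
#' @param data Tibble with columns `roi` and the measure.
#' @param measure Column name to plot (`"mean_acc"` or `"snr_db"`).
#' @param ref Optional horizontal reference line (e.g. 70 for the binary
#'   communication threshold).
#' @return A ggplot.
#' @export
plot_roi_summary <- function(data, measure = "mean_acc", ref = NULL) {
  sm <- dplyr::summarise(
    dplyr::group_by(data, .data$roi),
    m = mean(.data[[measure]]), s = stats::sd(.data[[measure]]),
    .groups = "drop"
  )
  p <- ggplot2::ggplot(sm, ggplot2::aes(x = .data$roi, y = .data$m)) +
    ggplot2::geom_col(fill = "grey80", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$s,
                                        ymax = .data$m + .data$s),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = measure) +
    ggplot2::theme_minimal()
  if (!is.null(ref)) p <- p + ggplot2::geom_hline(yintercept = ref,
                                                  linetype = "dashed")
  p
}
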