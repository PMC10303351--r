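# ggplot2 visualisations: spectra, phantom scenes, score plots and the
# per-stage metrics.

#' Plot artery/vein reflectance spectra
#'
#' @param spectra Tibble from [av_spectra()].
#' @return A ggplot.
#' @export
plot_spectra <- function(spectra) {
  long <- tidyr::pivot_longer(spectra, cols = c("artery", "vein", "background"),
                              names_to = "class", values_to = "reflectance")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$reflectance,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(artery = "red", vein = "blue",
                                            background = "grey40")) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance") +
    ggplot2::theme_minimal()
}

#' @rdname plot_spectra
#' @param object,... Autoplot arguments.
#' @export
autoplot.phantom_scene <- function(object, ...) {
  img <- object$image
  df <- expand.grid(row = seq_len(nrow(img[, , 1])),
                    col = seq_len(ncol(img[, , 1])))
  df$fill <- grDevices::rgb(img[, , 1][as.matrix(df)],
                            img[, , 2][as.matrix(df)],
                            img[, , 3][as.matrix(df)])
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Principal-component score plot of classified vessel pixels
#'
#' Reproduces the per-stage score plot: normalized component 1 on the
#' x-axis against component 2, arteries in red, veins in blue, with the
#' decision threshold as a vertical line.
#'
#' @param scores Tibble from [classify_pixels()] (columns `s1`, `s2`,
#'   `label`).
#' @param model Optional `av_score_model` supplying the threshold line.
#' @return A ggplot.
#' @export
plot_score_plot <- function(scores, model = NULL) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(.data$s1, .data$s2,
                                            colour = .data$label)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(artery = "red", vein = "blue")) +
    ggplot2::labs(x = "normalized PC1 score", y = "normalized PC2 score") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    p <- p + ggplot2::geom_vline(xintercept = model$threshold,
                                 linetype = "dashed")
  }
  p
}

#' @export
autoplot.av_score_model <- function(object, ...) {
  df <- tidy.av_score_model(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$loading,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "loading") +
    ggplot2::theme_minimal()
}

#' Per-stage metrics plot
#'
#' @param metrics Tibble from [metrics_table()] or [run_av_experiment()].
#' @return A ggplot of sensitivity/precision/F1 by stage and class.
#' @export
plot_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(
    dplyr::select(metrics, "stage", "class", "sensitivity", "precision", "f1"),
    cols = c("sensitivity", "precision", "f1"),
    names_to = "metric", values_to = "value")
  long$stage <- factor(long$stage, levels = severity_levels()$stage)
  ggplot2::ggplot(long, ggplot2::aes(.data$stage, .data$value,
                                     group = .data$class,
                                     colour = .data$class)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_colour_manual(values = c(artery = "red", vein = "blue")) +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal()
}
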