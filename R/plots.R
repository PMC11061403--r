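#' Plot a power spectrum
#'
#' Log-power line plot; add `bands = TRUE` to shade the 8-30 Hz sensorimotor
#' band used by the fitting and classification defaults.
#'
#' @param object a [power_spectrum()].
#' @param bands shade the mu/beta band.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot power_spectrum
#' @export
autoplot.power_spectrum <- function(object, bands = TRUE, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$frequency_hz, y = .data$power))
  if (bands)
    p <- p + ggplot2::annotate("rect", xmin = 8, xmax = 30, ymin = 0,
                               ymax = Inf, alpha = 0.08, fill = "steelblue")
  p + ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power (arb.)")
}

#' Plot benchmark improvements
#'
#' Per-strategy mean accuracy improvement over the small-set baseline, with
#' the full-set reference as a dashed line.
#'
#' @param object an `mi_benchmark` from [run_benchmark()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mi_benchmark
#' @export
autoplot.mi_benchmark <- function(object, ...) {
  rep <- object$report
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$strategy,
                                    y = .data$ac_augmented)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$ac_small_mean,
                        linetype = "solid") +
    ggplot2::geom_hline(yintercept = object$ac_full_mean,
                        linetype = "dashed") +
    ggplot2::coord_cartesian(
      ylim = c(0.4, max(c(rep$ac_augmented, object$ac_full_mean)) + 0.05)) +
    ggplot2::labs(x = NULL, y = "Balanced accuracy",
                  caption = "solid line: small-set baseline; dashed: full set") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Feature-space scatter of real and artificial epochs
#'
#' Two chosen feature columns against each other, colored by condition and
#' shaped by origin; the visual check that augmentation preserves linear
#' separability between conditions.
#'
#' @param f a feature tibble (e.g. from [assemble_training_features()]).
#' @param x,y feature column names; default the first two.
#' @return A ggplot object.
#' @export
plot_feature_space <- function(f, x = NULL, y = NULL) {
  cols <- feature_cols(f)
  if (is.null(x)) x <- cols[1]
  if (is.null(y)) y <- cols[2]
  ggplot2::ggplot(f, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                  colour = .data$condition,
                                  shape = .data$origin)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "condition", shape = "origin")
}
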