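# ggplot2 visualizations for fits and evaluations.

#' Plot training history
#'
#' @param object an `ss_fit`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.ss_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  h <- h[is.finite(h$loss), ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot uncertainty-sorted rolling error curves
#'
#' One panel per parameter class: rolling MAE and rolling 95th-percentile
#' error as the bootstrap uncertainty increases.
#'
#' @param object an `ss_eval`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.ss_eval <- function(object, ...) {
  r <- tidyr::pivot_longer(object$rolling,
                           c("rolling_mae", "rolling_q95"),
                           names_to = "statistic", values_to = "error")
  ggplot2::ggplot(r, ggplot2::aes(x = .data$mean_uncertainty,
                                  y = .data$error,
                                  color = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "uncertainty (rolling mean)", y = "error",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot predicted vs reference values per parameter class
#'
#' @param eval an `ss_eval`
#' @return a ggplot
#' @export
plot_prediction_scatter <- function(eval) {
  ggplot2::ggplot(eval$errors,
                  ggplot2::aes(x = .data$reference, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "reference", y = "predicted") +
    ggplot2::theme_minimal()
}
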