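# ggplot2 views of the package's result objects

#' Plot a threshold sweep
#'
#' Accuracy, escalation fraction and mean cost (relative to its maximum)
#' as functions of the routing threshold.
#'
#' @param object A `tau_sweep` from [sweep_tau()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tau_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$relative_cost <- df$mean_cost_macs / max(df$mean_cost_macs)
  long <- tidyr::pivot_longer(
    df[, c("tau", "accuracy", "escalation_fraction", "relative_cost")],
    -"tau", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tau, y = .data$value,
                                     color = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(tau), y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-class ROC curves of an evaluation report
#'
#' @param object An `eval_report` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               color = factor(.data$class))) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  color = "class") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a training loss history
#'
#' @param object A `stream_fit` from [train_stream()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stream_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}
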