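# broom-style tidiers for the package's result objects

#' Tidy a cost report into its per-layer table
#'
#' @param x A `cost_report` from [count_macs()].
#' @param ... Unused.
#' @return Tibble with `layer_name`, `macs`, `params`.
#' @export
tidy.cost_report <- function(x, ...) x$layers

#' @rdname tidy.cost_report
#' @export
glance.cost_report <- function(x, ...) {
  tibble::tibble(model = x$model, resolution = x$resolution,
                 convention = x$convention, total_macs = x$total_macs,
                 total_params = x$total_params)
}

#' Tidy an evaluation report into per-class AUCs
#'
#' @param x An `eval_report` from [evaluate_predictions()].
#' @param ... Unused.
#' @return Tibble with `class` and `auc`.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(class = as.integer(names(x$per_class_auc)),
                 auc = unname(x$per_class_auc))
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, average_auc = x$average_auc,
                 n_samples = x$n_samples)
}

#' Tidy a trained stream's loss history
#'
#' @param x A `stream_fit` from [train_stream()].
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `loss`, `accuracy`).
#' @export
tidy.stream_fit <- function(x, ...) x$history

#' @rdname tidy.stream_fit
#' @export
glance.stream_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h),
                 final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
                 final_accuracy = if (nrow(h)) h$accuracy[nrow(h)] else NA_real_)
}

#' Export a training history as CSV
#'
#' @param fit A `stream_fit` (or any object whose [tidy()] is the history).
#' @param path Output CSV.
#' @param split Label recorded in the `split` column.
#' @export
write_history_csv <- function(fit, path, split = "train") {
  h <- tidy(fit)
  h$split <- split
  readr::write_csv(h[, c("epoch", "split", "loss", "accuracy")], path)
  invisible(path)
}
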