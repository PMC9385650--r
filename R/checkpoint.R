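#' Save or load a cascade model checkpoint
#'
#' The checkpoint is a single self-describing RDS file holding both stream
#' specs and parameters, the feature reuse links, the router and
#' normalization settings, an optional training config and history, and a
#' format version.  Reloading reproduces predictions bit-identically
#' within one environment.
#'
#' @param model A [cascade_model()].
#' @param path Checkpoint file path.
#' @param train_config Optional [train_config()] to embed.
#' @param history Optional training history tibble to embed.
#' @export
save_checkpoint <- function(model, path, train_config = NULL,
                            history = NULL) {
  obj <- list(format = "cascadenet-checkpoint", version = 1L,
              small = model$small, large = model$large,
              frm_links = model$frm_links, router = model$router,
              normalize = model$normalize,
              train_config = train_config,
              history = history %||% attr(model, "history"))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns the restored [cascade_model()].
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cascadenet-checkpoint")) {
    abort(sprintf("'%s' is not a cascadenet checkpoint.", path))
  }
  model <- cascade_model(obj$small, obj$large, obj$frm_links, obj$router,
                         normalize = obj$normalize)
  attr(model, "history") <- obj$history
  attr(model, "train_config") <- obj$train_config
  model
}
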