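#' Confidence-routing configuration
#'
#' A sample exits at the small stream iff the maximum of its softmax
#' probability vector is strictly greater than `tau`; otherwise it is
#' escalated to the large stream.
#'
#' @param tau Confidence threshold in `[0, 1]`.
#' @return A `router_config` object.
#' @export
router_config <- function(tau = 0.8) {
  tau <- as.numeric(tau)
  if (is.na(tau) || tau < 0 || tau > 1) abort("`tau` must lie in [0, 1].")
  structure(list(tau = tau, comparison = "greater"), class = "router_config")
}

#' Route one probability vector
#'
#' @param p Normalized probability vector (or `n x N` matrix of column
#'   vectors).
#' @param router A [router_config()].
#' @return `"exit"` or `"escalate"` (vector for matrix input).
#' @export
#' @examples
#' route(c(0.9, 0.05, 0.05), router_config(0.8))
route <- function(p, router = router_config()) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 1)
  sums <- colSums(p)
  if (any(abs(sums - 1) > 1e-4) || any(p < 0)) {
    abort("`p` must be a normalized probability vector (|sum - 1| <= 1e-4).")
  }
  ifelse(apply(p, 2, max) > router$tau, "exit", "escalate")
}

#' Assemble a two-stream cascade model
#'
#' @param small,large `conv_stream`s with equal stage counts; the small
#'   stream must run at the lower resolution.
#' @param frm_links List of [frm_params()], one per stage (defaults to
#'   zero-initialized links, which make the large path identical to the
#'   standalone large stream).  Individual entries may be `NULL` to attach
#'   reuse modules at a subset of stage indices only.
#' @param router A [router_config()].
#' @param normalize Per-channel `list(mean, sd)` applied to inputs after
#'   resizing (must match what the streams were trained with).
#' @return A `cascade_model` object.
#' @export
cascade_model <- function(small, large, frm_links = NULL,
                          router = router_config(),
                          normalize = imagenet_normalize()) {
  if (!inherits(small, "conv_stream") || !inherits(large, "conv_stream")) {
    abort("`small` and `large` must be conv_streams.")
  }
  if (length(small$spec$stages) != length(large$spec$stages)) {
    abort(sprintf("stage counts differ: small has %d, large has %d.",
                  length(small$spec$stages), length(large$spec$stages)))
  }
  if (small$spec$input_resolution >= large$spec$input_resolution) {
    abort("the small stream must use a lower input resolution than the large stream.")
  }
  if (is.null(frm_links)) frm_links <- init_frm_links(small$spec, large$spec)
  if (length(frm_links) != length(small$spec$stages)) {
    abort(sprintf("need one frm link per stage (%d), got %d.",
                  length(small$spec$stages), length(frm_links)))
  }
  res_l <- stage_resolutions(large$spec)
  for (i in seq_along(frm_links)) {
    lk <- frm_links[[i]]
    if (is.null(lk)) next
    if (nrow(lk$weight) != large$spec$stages[[i]]$out_channels ||
        ncol(lk$weight) != small$spec$stages[[i]]$out_channels ||
        lk$target_height != res_l[i]) {
      abort(sprintf("frm link %d does not match the linked stage shapes.", i))
    }
  }
  structure(list(small = small, large = large, frm_links = frm_links,
                 router = router,
                 resolutions = c(small = small$spec$input_resolution,
                                 large = large$spec$input_resolution),
                 normalize = normalize),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("<cascade_model> %dpx '%s' -> tau %.2f -> %dpx '%s' (+%d FRM links)\n",
              x$resolutions["small"], x$small$spec$name, x$router$tau,
              x$resolutions["large"], x$large$spec$name, length(x$frm_links)))
  invisible(x)
}

# resize a list of native-resolution images to `res` and normalize;
# returns a (3, res, res, N) array
preprocess_batch <- function(images, res, normalize) {
  x <- as_batch(lapply(images, resize_bilinear, height = res, width = res))
  normalize_batch(x, normalize)
}

cascade_costs <- function(model) {
  list(
    c_small = count_macs(model$small$spec)$total_macs,
    c_large = count_macs(model$large$spec)$total_macs,
    c_frm = frm_cost(model$frm_links))
}

# run the two streams once over a dataset; returns per-sample small/large
# probabilities (large with FRM fusion from the cached small taps)
cascade_scores <- function(model, images) {
  xs <- preprocess_batch(images, model$resolutions["small"], model$normalize)
  small_out <- forward_with_taps(model$small, xs)
  xl <- preprocess_batch(images, model$resolutions["large"], model$normalize)
  fuse <- purrr::map2(model$frm_links, small_out$taps, function(lk, tp) {
    if (is.null(lk)) NULL else frm_apply(lk, tp)
  })
  large_out <- forward_with_taps(model$large, xl, fuse = fuse)
  list(p_small = small_out$probabilities, p_large = large_out$probabilities)
}

#' Run cascade inference over a dataset
#'
#' Every sample is resized to the small resolution and scored by the small
#' stream.  Samples whose maximum small-stream probability exceeds the
#' router threshold exit there; the rest are re-encoded from the original
#' image at the large resolution and scored by the FRM-augmented large
#' stream, which fuses the small stream's cached per-stage taps (the small
#' stream runs exactly once per sample).  Escalated samples always take the
#' large stream's label, even when its confidence is lower.
#'
#' @param model A [cascade_model()].
#' @param data A tibble with an `image` list-column of `(3, H, W)` arrays
#'   (e.g. from [generate_dataset()]), or a bare list of such arrays.
#' @return A tibble of per-sample decisions: `sample_id`, `exit`
#'   (`"small"`/`"large"`), `label` (0-based), `confidence` (max
#'   probability at the exit point), `cost_macs` (attributed
#'   multiply-accumulates, standard convention), and list-columns
#'   `p_small`, `p_large` (`NULL` when the sample exited early) and `probs`
#'   (the final probability vector used for evaluation).  The per-stream
#'   costs are attached as the `"costs"` attribute.
#' @export
cascade_predict <- function(model, data) {
  if (!inherits(model, "cascade_model")) abort("`model` must be a cascade_model.")
  images <- if (is.data.frame(data)) data$image else data
  if (length(images) == 0) abort("`data` contains no images.")
  ids <- if (is.data.frame(data) && "sample_id" %in% names(data)) {
    data$sample_id
  } else {
    sprintf("s%04d", seq_along(images))
  }
  xs <- preprocess_batch(images, model$resolutions["small"], model$normalize)
  small_out <- forward_with_taps(model$small, xs)
  p_small <- small_out$probabilities
  verdict <- route(p_small, model$router)
  esc <- which(verdict == "escalate")
  costs <- cascade_costs(model)

  n <- length(images)
  label <- argmax0(p_small)
  confidence <- apply(p_small, 2, max)
  cost_macs <- rep(costs$c_small, n)
  p_large_col <- vector("list", n)
  if (length(esc) > 0) {
    xl <- preprocess_batch(images[esc], model$resolutions["large"],
                           model$normalize)
    taps_sub <- lapply(small_out$taps, function(tp) {
      tp[, , , esc, drop = FALSE]
    })
    fuse <- purrr::map2(model$frm_links, taps_sub, function(lk, tp) {
      if (is.null(lk)) NULL else frm_apply(lk, tp)
    })
    large_out <- forward_with_taps(model$large, xl, fuse = fuse)
    p_large <- large_out$probabilities
    label[esc] <- argmax0(p_large)
    confidence[esc] <- apply(p_large, 2, max)
    cost_macs[esc] <- costs$c_small + costs$c_large + costs$c_frm
    for (j in seq_along(esc)) p_large_col[[esc[j]]] <- p_large[, j]
  }
  final <- lapply(seq_len(n), function(i) {
    if (is.null(p_large_col[[i]])) p_small[, i] else p_large_col[[i]]
  })
  out <- tibble::tibble(
    sample_id = ids,
    exit = ifelse(verdict == "exit", "small", "large"),
    label = as.integer(label),
    confidence = confidence,
    cost_macs = cost_macs,
    p_small = lapply(seq_len(n), function(i) p_small[, i]),
    p_large = p_large_col,
    probs = final)
  attr(out, "costs") <- costs
  out
}

#' Sweep the routing threshold over a grid
#'
#' Both streams are evaluated once; each threshold then only re-partitions
#' the cached probabilities, so the sweep is cheap.  Mean cost per sample
#' is the analytic `c_small + rho * (c_large + c_frm)` with `rho` the
#' observed escalation fraction at that threshold.
#'
#' @param model A [cascade_model()].
#' @param data A tibble with `image` and `label` columns.
#' @param tau_grid Thresholds in `[0, 1]`.
#' @return A `tau_sweep` tibble with columns `tau`, `accuracy`,
#'   `escalation_fraction`, `mean_cost_macs`.
#' @export
sweep_tau <- function(model, data, tau_grid = seq(0, 1, by = 0.05)) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("`data` must be a non-empty tibble with image and label columns.")
  }
  if (any(tau_grid < 0 | tau_grid > 1)) abort("`tau_grid` values must lie in [0, 1].")
  sc <- cascade_scores(model, data$image)
  conf_small <- apply(sc$p_small, 2, max)
  lab_small <- argmax0(sc$p_small)
  lab_large <- argmax0(sc$p_large)
  truth <- data$label
  costs <- cascade_costs(model)
  rows <- purrr::map(tau_grid, function(tau) {
    escalate <- conf_small <= tau
    lab <- ifelse(escalate, lab_large, lab_small)
    rho <- mean(escalate)
    tibble::tibble(
      tau = tau,
      accuracy = mean(lab == truth),
      escalation_fraction = rho,
      mean_cost_macs = expected_cascade_cost(costs$c_small, costs$c_large,
                                             costs$c_frm, rho))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tau_sweep", class(out))
  out
}

#' Export cascade decisions as CSV
#'
#' Writes the scalar columns (`sample_id`, `exit`, `label`, `confidence`,
#' `cost_macs`) of a [cascade_predict()] result.
#'
#' @param decisions Tibble from [cascade_predict()].
#' @param path Output file.
#' @export
write_decisions_csv <- function(decisions, path) {
  readr::write_csv(
    decisions[, c("sample_id", "exit", "label", "confidence", "cost_macs")],
    path)
  invisible(path)
}
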