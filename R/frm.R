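#' Feature reuse module parameters
#'
#' A feature reuse module (FRM) transfers the feature map tapped at stage
#' `block_index` of the small stream into the same-index stage of the large
#' stream: the tap is bilinearly upsampled to the large stream's spatial
#' size `(target_height, target_width)`, passed through a 1x1 convolution
#' (`weight`, `bias`) that aligns feature domains and channel counts, and
#' added pointwise to the large stream's stage output.
#'
#' @param block_index 1-based stage index the module is plugged into.
#' @param weight `(C_large x C_small)` matrix realizing the 1x1 convolution.
#' @param bias Optional length-`C_large` vector (defaults to zeros).
#' @param target_height,target_width Spatial size of the large stream's
#'   stage output, in pixels.
#' @return An `frm_params` object.
#' @export
frm_params <- function(block_index, weight, bias = NULL,
                       target_height, target_width) {
  weight <- as.matrix(weight)
  if (is.null(bias)) bias <- numeric(nrow(weight))
  if (length(bias) != nrow(weight)) {
    abort("`bias` length must equal nrow(weight) (the large-stream channels).")
  }
  if (target_height < 1 || target_width < 1) {
    abort("target size must be >= 1 pixel.")
  }
  structure(list(block_index = as.integer(block_index), weight = weight,
                 bias = as.numeric(bias),
                 target_height = as.integer(target_height),
                 target_width = as.integer(target_width)),
            class = "frm_params")
}

#' Zero-initialized feature reuse links between two stream specs
#'
#' One FRM per stage index.  Zero initialization makes the modules an exact
#' no-op, so a freshly linked cascade behaves identically to the standalone
#' large stream until fine-tuning moves the weights.
#'
#' @param small_spec,large_spec [stream_spec()]s with equal stage counts.
#' @return List of [frm_params()], one per stage.
#' @export
init_frm_links <- function(small_spec, large_spec) {
  if (length(small_spec$stages) != length(large_spec$stages)) {
    abort(sprintf("stage counts differ: small has %d, large has %d.",
                  length(small_spec$stages), length(large_spec$stages)))
  }
  res_l <- stage_resolutions(large_spec)
  purrr::map(seq_along(small_spec$stages), function(i) {
    cs <- small_spec$stages[[i]]$out_channels
    cl <- large_spec$stages[[i]]$out_channels
    frm_params(i, matrix(0, cl, cs), numeric(cl), res_l[i], res_l[i])
  })
}

#' Bilinearly upsample a feature map
#'
#' Half-pixel-center bilinear interpolation to `(target_height,
#' target_width)`; only upsampling (or the identity) is permitted here.
#'
#' @param f `(C, H, W)` or `(C, H, W, N)` array.
#' @param target_height,target_width Target spatial size, `>=` the source.
#' @return Array with the same channel (and batch) dimensions at the target
#'   spatial size.
#' @export
#' @examples
#' upsample_bilinear(array(1:8, c(2, 2, 2)), 4, 4)
upsample_bilinear <- function(f, target_height, target_width) {
  d <- dim(f)
  if (is.null(d) || !length(d) %in% c(3L, 4L)) {
    abort("`f` must be a (C,H,W) or (C,H,W,N) array.")
  }
  if (target_height < d[2] || target_width < d[3]) {
    abort(sprintf(
      "target %dx%d is smaller than the source %dx%d; only upsampling is supported.",
      target_height, target_width, d[2], d[3]))
  }
  resize_bilinear(f, target_height, target_width)
}

#' Align channels and feature domain with a 1x1 convolution
#'
#' Every output pixel is `weight %*% x + bias` applied to that pixel's
#' channel vector; spatial size is unchanged.
#'
#' @param f `(C_small, H, W)` or `(C_small, H, W, N)` array.
#' @param params An [frm_params()] whose `weight` has `C_small` columns.
#' @return Array with `C_large` channels.
#' @export
align_1x1 <- function(f, params) {
  d <- dim(f)
  if (ncol(params$weight) != d[1]) {
    abort(sprintf("channel mismatch: feature map has %d channels, 1x1 weight expects %d.",
                  d[1], ncol(params$weight)))
  }
  single <- length(d) == 3L
  x <- matrix(f, nrow = d[1])
  y <- params$weight %*% x + params$bias
  dim(y) <- c(nrow(params$weight), d[-1])
  if (single) dim(y) <- dim(y)[1:3]
  y
}

#' Fuse a reuse map into a large-stream feature map by pointwise addition
#'
#' @param f_l Large-stream stage output.
#' @param f_reuse Aligned reuse map of identical shape.
#' @return Elementwise sum, used as the input of the next large-stream
#'   block (or of the head, after the last block).
#' @export
frm_fuse <- function(f_l, f_reuse) {
  dl <- dim(f_l); dr <- dim(f_reuse)
  if (!identical(dl, dr)) {
    nm <- c("channels", "height", "width", "batch")
    bad <- which(dl != dr)[1]
    abort(sprintf("%s mismatch in frm_fuse: %d vs %d.",
                  nm[bad], dl[bad], dr[bad]))
  }
  f_l + f_reuse
}

# upsample + 1x1 alignment of one small-stream tap -> reuse map
frm_apply <- function(params, tap_small) {
  align_1x1(upsample_bilinear(tap_small, params$target_height,
                              params$target_width), params)
}
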