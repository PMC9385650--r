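#' Build a parameterized convolutional stream
#'
#' Instantiates the parameters of a [stream_spec()]: variance-scaling
#' (He-normal) initialization for convolution weights, unit-scale batch
#' normalization (gamma 1, beta 0, running mean 0 / variance 1), and a
#' zero-bias linear head.  Initialization is deterministic given `seed` and
#' does not disturb the caller's RNG state.
#'
#' @param spec A [stream_spec()].
#' @param seed Integer seed controlling parameter initialization.
#' @return A `conv_stream` object; run it with [forward_with_taps()].
#' @export
#' @examples
#' s <- build_stream(reference_specs()$tiny_small, seed = 1)
build_stream <- function(spec, seed = 1L) {
  if (!inherits(spec, "stream_spec")) abort("`spec` must be a stream_spec.")
  validate_stream_spec(spec)
  params <- with_seed(seed, init_params(spec))
  structure(list(spec = spec, params = params,
                 stats = init_stats(params), seed = as.integer(seed)),
            class = "conv_stream")
}

# conv + batch-norm parameter leaf: weight, gamma, beta
he_conv <- function(c_out, c_in, k) {
  w <- array(rnorm(c_out * c_in * k * k, sd = sqrt(2 / (c_in * k * k))),
             c(c_out, c_in, k, k))
  list(w = w, g = rep(1, c_out), beta = numeric(c_out))
}

init_params <- function(spec) {
  stem <- he_conv(spec$stem$out_channels, 3L, spec$stem$kernel)
  c_in <- spec$stem$out_channels
  stages <- vector("list", length(spec$stages))
  for (i in seq_along(spec$stages)) {
    st <- spec$stages[[i]]
    units <- vector("list", st$n_units)
    for (u in seq_len(st$n_units)) {
      stride <- if (u == 1L) st$stride else 1L
      needs_proj <- u == 1L && (stride != 1L || c_in != st$out_channels)
      if (st$kind == "basic") {
        units[[u]] <- list(
          conv1 = he_conv(st$out_channels, c_in, 3L),
          conv2 = he_conv(st$out_channels, st$out_channels, 3L),
          proj = if (needs_proj) he_conv(st$out_channels, c_in, 1L))
      } else {
        mid <- st$out_channels %/% 4L
        units[[u]] <- list(
          conv1 = he_conv(mid, c_in, 1L),
          conv2 = he_conv(mid, mid, 3L),
          conv3 = he_conv(st$out_channels, mid, 1L),
          proj = if (needs_proj) he_conv(st$out_channels, c_in, 1L))
      }
      c_in <- st$out_channels
    }
    stages[[i]] <- units
  }
  head_w <- matrix(rnorm(spec$num_classes * c_in, sd = sqrt(1 / c_in)),
                   spec$num_classes, c_in)
  list(stem = stem, stages = stages,
       head = list(w = head_w, b = numeric(spec$num_classes)))
}

# running batch-norm statistics, mirroring the conv leaves of `params`
init_stats <- function(params) {
  conv_stat <- function(leaf) {
    if (is.null(leaf)) return(NULL)
    list(mean = numeric(length(leaf$g)), var = rep(1, length(leaf$g)))
  }
  list(stem = conv_stat(params$stem),
       stages = lapply(params$stages, function(units) {
         lapply(units, function(pu) {
           out <- list(conv1 = conv_stat(pu$conv1),
                       conv2 = conv_stat(pu$conv2))
           if (!is.null(pu$conv3)) out$conv3 <- conv_stat(pu$conv3)
           out$proj <- conv_stat(pu$proj)
           out
         })
       }))
}

bn_momentum <- 0.1
bn_eps <- 1e-5

# conv -> batch norm; training mode standardizes by batch statistics and
# updates the running averages, eval mode uses the stored running values.
# `keep_patches` caches the im2col patch matrix for reuse in backward.
conv_bn_fwd <- function(x, leaf, stat, stride, pad, training,
                        keep_patches = FALSE, norm = "batch") {
  patches <- NULL
  if (keep_patches) {
    dw <- dim(leaf$w)
    fp <- cpp_conv2d_forward_f(x, as.integer(dim(x)), leaf$w,
                               dw[1], dw[3], as.integer(stride),
                               as.integer(pad))
    z <- fp$out
    patches <- fp$patches
  } else {
    z <- conv2d_fwd(x, leaf$w, NULL, stride, pad)
  }
  d <- dim(z)
  if (norm == "instance") {
    bn <- cpp_in_train_forward(z, d[1], d[2] * d[3], d[4], leaf$g,
                               leaf$beta, bn_eps)
    return(list(y = bn$y, xhat = bn$xhat, istd = bn$istd, stat = stat,
                in_dims = c(d[1], d[2] * d[3], d[4]), x_in = x,
                patches = patches, xdim = dim(x)))
  }
  if (training) {
    bn <- cpp_bn_train_forward(z, d[1], leaf$g, leaf$beta, bn_eps)
    stat$mean <- (1 - bn_momentum) * stat$mean + bn_momentum * bn$mean
    stat$var <- (1 - bn_momentum) * stat$var + bn_momentum * bn$var
    list(y = bn$y, xhat = bn$xhat, istd = bn$istd, stat = stat, x_in = x,
         patches = patches, xdim = dim(x))
  } else {
    scale <- leaf$g / sqrt(stat$var + bn_eps)
    shift <- leaf$beta - scale * stat$mean
    y <- array(scale * matrix(z, d[1]) + shift, d)
    list(y = y, stat = stat, x_in = x, patches = patches, xdim = dim(x))
  }
}

# backward through batch norm (batch-statistics mode) and the convolution
conv_bn_bwd <- function(cache, leaf, dy, stride, pad, want_dx = TRUE) {
  if (!is.null(cache$in_dims)) {
    id <- cache$in_dims
    bb <- cpp_in_backward(dy, id[1], id[2], id[3], leaf$g, cache$xhat,
                          cache$istd)
  } else {
    bb <- cpp_bn_backward(dy, dim(dy)[1], leaf$g, cache$xhat, cache$istd)
  }
  dz <- bb$dz
  if (!is.null(cache$patches)) {
    dw <- dim(leaf$w)
    cb <- cpp_conv2d_backward_f(cache$patches, as.integer(cache$xdim),
                                leaf$w, dw[1], dw[3], dz,
                                as.integer(stride), as.integer(pad),
                                want_dx)
  } else {
    cb <- conv2d_bwd(cache$x_in, leaf$w, dz, stride, pad, want_dx = want_dx)
  }
  list(dx = cb$dx, grads = list(w = cb$dw, g = bb$dg, beta = bb$dbeta))
}

unit_fwd <- function(x, pu, su, kind, stride, training,
                     keep_patches = FALSE, norm = "batch") {
  if (kind == "basic") {
    c1 <- conv_bn_fwd(x, pu$conv1, su$conv1, stride, 1L, training, keep_patches, norm)
    a1 <- relu_fwd(c1$y)
    c2 <- conv_bn_fwd(a1, pu$conv2, su$conv2, 1L, 1L, training, keep_patches, norm)
    if (is.null(pu$proj)) {
      sc <- x; cp <- NULL
    } else {
      cp <- conv_bn_fwd(x, pu$proj, su$proj, stride, 0L, training, keep_patches, norm)
      sc <- cp$y
    }
    out <- relu_fwd(c2$y + sc)
    list(out = out,
         cache = list(c1 = c1, a1 = a1, c2 = c2, cp = cp, out = out),
         stats = list(conv1 = c1$stat, conv2 = c2$stat,
                      proj = if (!is.null(cp)) cp$stat))
  } else {
    c1 <- conv_bn_fwd(x, pu$conv1, su$conv1, 1L, 0L, training, keep_patches, norm)
    a1 <- relu_fwd(c1$y)
    c2 <- conv_bn_fwd(a1, pu$conv2, su$conv2, stride, 1L, training, keep_patches, norm)
    a2 <- relu_fwd(c2$y)
    c3 <- conv_bn_fwd(a2, pu$conv3, su$conv3, 1L, 0L, training, keep_patches, norm)
    if (is.null(pu$proj)) {
      sc <- x; cp <- NULL
    } else {
      cp <- conv_bn_fwd(x, pu$proj, su$proj, stride, 0L, training, keep_patches, norm)
      sc <- cp$y
    }
    out <- relu_fwd(c3$y + sc)
    list(out = out,
         cache = list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3, cp = cp,
                      out = out),
         stats = list(conv1 = c1$stat, conv2 = c2$stat, conv3 = c3$stat,
                      proj = if (!is.null(cp)) cp$stat))
  }
}

unit_bwd <- function(cache, pu, kind, stride, gout) {
  g <- relu_bwd(gout, cache$out)
  if (kind == "basic") {
    cb2 <- conv_bn_bwd(cache$c2, pu$conv2, g, 1L, 1L)
    da1 <- relu_bwd(cb2$dx, cache$a1)
    cb1 <- conv_bn_bwd(cache$c1, pu$conv1, da1, stride, 1L)
    dx <- cb1$dx
    grads <- list(conv1 = cb1$grads, conv2 = cb2$grads, proj = NULL)
  } else {
    cb3 <- conv_bn_bwd(cache$c3, pu$conv3, g, 1L, 0L)
    da2 <- relu_bwd(cb3$dx, cache$a2)
    cb2 <- conv_bn_bwd(cache$c2, pu$conv2, da2, stride, 1L)
    da1 <- relu_bwd(cb2$dx, cache$a1)
    cb1 <- conv_bn_bwd(cache$c1, pu$conv1, da1, 1L, 0L)
    dx <- cb1$dx
    grads <- list(conv1 = cb1$grads, conv2 = cb2$grads, conv3 = cb3$grads,
                  proj = NULL)
  }
  if (is.null(pu$proj)) {
    dx <- dx + g
  } else {
    cbp <- conv_bn_bwd(cache$cp, pu$proj, g, stride, 0L)
    dx <- dx + cbp$dx
    grads$proj <- cbp$grads
  }
  list(dx = dx, grads = grads)
}

#' Run a stream on a batch of images, exposing per-stage feature taps
#'
#' Executes stem, residual stages and the pooled softmax head.  One feature
#' tap is returned per stage; class probabilities are the softmax of the
#' head logits.  `fuse`, used internally by cascades, supplies one reuse
#' feature map per stage that is added pointwise to the stage output before
#' it feeds the next stage (or the head, for the last stage).
#'
#' @param stream A `conv_stream` from [build_stream()].
#' @param images A `(3, H, W)` array, `(3, H, W, N)` array, or list of
#'   `(3, H, W)` arrays, with `H = W =` the spec's `input_resolution`.
#' @param keep_cache Keep intermediate activations (used for training).
#' @param fuse Optional list (one per stage) of reuse maps to add to the
#'   stage outputs, or `NULL` entries for stages without fusion.
#' @param training Use batch statistics in the normalization layers and
#'   return updated running statistics (training mode); the default eval
#'   mode uses the stored running statistics, so outputs are independent
#'   of batch composition.
#' @return List with `taps` (list of `(C, H, W, N)` arrays, one per stage),
#'   `logits` and `probabilities` (`num_classes x N` matrices), updated
#'   `stats` when `training`, and optionally `cache`.
#' @export
forward_with_taps <- function(stream, images, keep_cache = FALSE,
                              fuse = NULL, training = FALSE) {
  if (!inherits(stream, "conv_stream")) abort("`stream` must be a conv_stream.")
  spec <- stream$spec
  x <- as_batch(images)
  d <- dim(x)
  if (d[1] != 3L || d[2] != spec$input_resolution ||
      d[3] != spec$input_resolution) {
    abort(sprintf(
      "input shape mismatch for stream '%s': expected (3, %d, %d), received (%d, %d, %d).",
      spec$name, spec$input_resolution, spec$input_resolution,
      d[1], d[2], d[3]))
  }
  p <- stream$params
  stats <- stream$stats
  cache <- list()
  pad <- (spec$stem$kernel - 1L) %/% 2L
  norm <- spec$norm %||% "batch"
  cs <- conv_bn_fwd(x, p$stem, stats$stem, spec$stem$stride, pad,
                    training, keep_patches = FALSE, norm = norm)
  stats$stem <- cs$stat
  a <- relu_fwd(cs$y)
  cache$stem <- cs
  cache$stem_a <- a
  if (spec$stem$pool) {
    mp <- maxpool_fwd(a)
    cache$pool_idx <- mp$idx
    cache$pool_in_dim <- dim(a)
    a <- mp$out
  }
  taps <- vector("list", length(spec$stages))
  stage_caches <- vector("list", length(spec$stages))
  for (i in seq_along(spec$stages)) {
    st <- spec$stages[[i]]
    ucaches <- vector("list", st$n_units)
    for (u in seq_len(st$n_units)) {
      stride <- if (u == 1L) st$stride else 1L
      uf <- unit_fwd(a, p$stages[[i]][[u]], stats$stages[[i]][[u]],
                     st$kind, stride, training, keep_patches = keep_cache,
                     norm = norm)
      a <- uf$out
      stats$stages[[i]][[u]] <- uf$stats
      ucaches[[u]] <- if (keep_cache) uf$cache else NULL
    }
    taps[[i]] <- a
    if (!is.null(fuse) && !is.null(fuse[[i]])) {
      if (!identical(dim(fuse[[i]]), dim(a))) {
        abort(sprintf("fuse map %d has dim (%s), stage output is (%s).", i,
                      paste(dim(fuse[[i]]), collapse = ","),
                      paste(dim(a), collapse = ",")))
      }
      a <- a + fuse[[i]]
    }
    stage_caches[[i]] <- list(units = ucaches)
  }
  g <- gap_fwd(a)
  logits <- p$head$w %*% g + p$head$b
  out <- list(taps = taps, logits = logits, probabilities = softmax(logits))
  if (training) out$stats <- stats
  if (keep_cache) {
    cache$stages <- stage_caches
    cache$gap_in_dim <- dim(a)
    cache$gap <- g
    out$cache <- cache
  }
  out
}

# Backward pass through a stream (training-mode normalization assumed).
# `dlogits` is (num_classes x N); `tap_grads_in` optionally injects extra
# gradients at the post-fusion stage boundaries (used when fine-tuning
# propagates into the small stream through the reuse modules).  Returns
# parameter gradients mirroring the params structure and, when requested,
# the gradient at each stage boundary (which is also the gradient of any
# reuse map added there).
stream_backward <- function(stream, cache, dlogits, tap_grads_in = NULL,
                            want_tap_grads = FALSE) {
  spec <- stream$spec
  p <- stream$params
  g <- cache$gap
  grads <- list(head = list(w = dlogits %*% t(g), b = rowSums(dlogits)))
  dg <- t(p$head$w) %*% dlogits
  dx <- gap_bwd(dg, cache$gap_in_dim)
  K <- length(spec$stages)
  tap_grads <- vector("list", K)
  stage_grads <- vector("list", K)
  for (i in rev(seq_len(K))) {
    if (!is.null(tap_grads_in) && !is.null(tap_grads_in[[i]])) {
      dx <- dx + tap_grads_in[[i]]
    }
    tap_grads[[i]] <- dx
    st <- spec$stages[[i]]
    ugrads <- vector("list", st$n_units)
    for (u in rev(seq_len(st$n_units))) {
      stride <- if (u == 1L) st$stride else 1L
      ub <- unit_bwd(cache$stages[[i]]$units[[u]], p$stages[[i]][[u]],
                     st$kind, stride, dx)
      dx <- ub$dx
      ugrads[[u]] <- ub$grads
    }
    stage_grads[[i]] <- ugrads
  }
  if (spec$stem$pool) {
    dx <- maxpool_bwd(cache$pool_idx, dx, cache$pool_in_dim)
  }
  dx <- relu_bwd(dx, cache$stem_a)
  pad <- (spec$stem$kernel - 1L) %/% 2L
  cbs <- conv_bn_bwd(cache$stem, p$stem, dx, spec$stem$stride, pad,
                     want_dx = FALSE)
  grads$stem <- cbs$grads
  grads$stages <- stage_grads
  grads <- grads[c("stem", "stages", "head")]
  list(grads = grads, tap_grads = if (want_tap_grads) tap_grads)
}

#' @export
print.conv_stream <- function(x, ...) {
  cat(sprintf("<conv_stream '%s'> seed %d\n", x$spec$name, x$seed))
  print(x$spec)
  invisible(x)
}

#' Predict class labels with a single stream
#'
#' @param object A `conv_stream`.
#' @param images As in [forward_with_taps()]; images must already be at the
#'   stream's input resolution (and normalized the same way as training).
#' @param ... Unused.
#' @return A tibble with `label` (0-based class index, lowest index wins
#'   ties) and `confidence` (max softmax probability).
#' @export
predict.conv_stream <- function(object, images, ...) {
  out <- forward_with_taps(object, images)
  tibble::tibble(label = argmax0(out$probabilities),
                 confidence = apply(out$probabilities, 2, max))
}
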