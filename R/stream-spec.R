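#' Describe one residual stage of a convolutional stream
#'
#' A stage groups `n_units` residual units at a fixed channel width.  The
#' first unit of a stage applies the stage stride (and a 1x1 projection
#' shortcut when the spatial size or channel count changes); subsequent
#' units are stride-1 identity-shortcut units.
#'
#' @param kind `"basic"` (two 3x3 convolutions per unit) or `"bottleneck"`
#'   (1x1 reduce, 3x3, 1x1 expand; `out_channels` must be divisible by 4).
#' @param n_units Number of residual units in the stage (>= 1).
#' @param out_channels Output channel count of the stage (>= 1).
#' @param stride Spatial downsampling factor of the stage, 1 or 2.
#' @return A `block_spec` list.
#' @export
#' @examples
#' block_spec("basic", n_units = 2, out_channels = 64, stride = 1)
block_spec <- function(kind = c("basic", "bottleneck"), n_units,
                       out_channels, stride = 1L) {
  kind <- match.arg(kind)
  n_units <- as.integer(n_units)
  out_channels <- as.integer(out_channels)
  stride <- as.integer(stride)
  if (n_units < 1L) abort("`n_units` must be >= 1.")
  if (out_channels < 1L) abort("`out_channels` must be >= 1.")
  if (!stride %in% c(1L, 2L)) abort("`stride` must be 1 or 2.")
  if (kind == "bottleneck" && out_channels %% 4L != 0L) {
    abort("bottleneck stages need `out_channels` divisible by 4.")
  }
  structure(list(kind = kind, n_units = n_units,
                 out_channels = out_channels, stride = stride),
            class = "block_spec")
}

#' Describe the stem of a convolutional stream
#'
#' @param out_channels Stem output channels.
#' @param kernel Stem convolution kernel size (7 for the reference
#'   residual-network stem, 3 for tiny test streams).
#' @param stride Stem convolution stride.
#' @param pool Whether a 3x3 stride-2 max-pool follows the stem convolution.
#' @return A `stem_spec` list.
#' @export
stem_spec <- function(out_channels, kernel = 3L, stride = 1L, pool = FALSE) {
  if (!kernel %in% c(3L, 7L)) abort("stem `kernel` must be 3 or 7.")
  structure(list(out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel),
                 stride = as.integer(stride), pool = isTRUE(pool)),
            class = "stem_spec")
}

#' Describe a staged convolutional classification stream
#'
#' A stream is a stem, an ordered list of residual stages, and a head
#' (global average pooling followed by one linear layer with a softmax).
#' One feature tap is exposed per stage; taps are what the feature reuse
#' modules of a cascade consume.
#'
#' @param name Identifier for the stream.
#' @param input_resolution Square input size in pixels.
#' @param stem A [stem_spec()].
#' @param stages List of [block_spec()]s (non-empty).
#' @param num_classes Number of classes (>= 2).
#' @param norm Normalization layer after every convolution: `"batch"`
#'   (batch statistics while training, running statistics at eval — the
#'   published residual-network choice) or `"instance"` (per-sample,
#'   per-channel standardization; batch-size independent, and preferable
#'   when informative structure is localized and batches mix strata of
#'   very different contrast).
#' @return A `stream_spec` object.
#' @export
#' @examples
#' stream_spec("tiny", 32, stem_spec(8), list(block_spec("basic", 1, 16, 2)), 4)
stream_spec <- function(name, input_resolution, stem, stages, num_classes,
                        norm = c("batch", "instance")) {
  norm <- match.arg(norm)
  if (!inherits(stem, "stem_spec")) abort("`stem` must be a stem_spec.")
  if (length(stages) == 0) abort("`stages` must be non-empty.")
  if (!all(vapply(stages, inherits, logical(1), "block_spec"))) {
    abort("every element of `stages` must be a block_spec.")
  }
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L) abort("`num_classes` must be >= 2.")
  spec <- structure(list(name = name,
                         input_resolution = as.integer(input_resolution),
                         stem = stem, stages = stages,
                         num_classes = num_classes, norm = norm),
                    class = "stream_spec")
  validate_stream_spec(spec)
  spec
}

# Spatial size after each layer; errors name the offending stage when a
# stride chain exhausts the resolution.
stage_resolutions <- function(spec, resolution = spec$input_resolution) {
  conv_out <- function(h, k, s, p) (h + 2L * p - k) %/% s + 1L
  check_downsample <- function(h, where) {
    if (h < 2L) {
      abort(sprintf(
        "resolution %d leaves only %d pixel(s) entering %s of stream '%s'; a stride-2 layer cannot downsample it.",
        resolution, h, where, spec$name))
    }
  }
  h <- resolution
  if (spec$stem$stride > 1L) check_downsample(h, "the stem")
  h <- conv_out(h, spec$stem$kernel, spec$stem$stride,
                (spec$stem$kernel - 1L) %/% 2L)
  if (spec$stem$pool) {
    check_downsample(h, "the stem pool")
    h <- conv_out(h, 3L, 2L, 1L)
  }
  if (h < 1L) {
    abort(sprintf("resolution %d is exhausted by the stem of stream '%s'.",
                  resolution, spec$name))
  }
  out <- integer(length(spec$stages))
  for (i in seq_along(spec$stages)) {
    if (spec$stages[[i]]$stride > 1L) {
      check_downsample(h, sprintf("stage %d", i))
    }
    h <- conv_out(h, 3L, spec$stages[[i]]$stride, 1L)
    out[i] <- h
  }
  out
}

validate_stream_spec <- function(spec) {
  invisible(stage_resolutions(spec))
}

#' @export
print.stream_spec <- function(x, ...) {
  cat(sprintf("<stream_spec '%s'> %dpx, %d classes\n", x$name,
              x$input_resolution, x$num_classes))
  res <- stage_resolutions(x)
  cat(sprintf("  stem: %dx%d conv s%d -> %d ch%s\n", x$stem$kernel,
              x$stem$kernel, x$stem$stride, x$stem$out_channels,
              if (x$stem$pool) " + maxpool/2" else ""))
  for (i in seq_along(x$stages)) {
    s <- x$stages[[i]]
    cat(sprintf("  stage %d: %s x%d, %d ch, stride %d -> %dx%d\n", i, s$kind,
                s$n_units, s$out_channels, s$stride, res[i], res[i]))
  }
  invisible(x)
}

#' Named reference stream specifications
#'
#' Returns the standard 18-, 34- and 50-layer residual-network streams (the
#' published stage layouts, with 1000-class heads so their analytic costs
#' and parameter counts match the familiar published figures), plus a tiny
#' small/large pair sized for desk-scale experiments on the synthetic
#' lesion data.  The 18- and 34-layer streams have the same number of
#' stages (four), which is what lets feature reuse modules pair their
#' blocks index-by-index; the tiny pair shares its stage count too.
#'
#' @return Named list of [stream_spec()] objects: `resnet18` (224 px),
#'   `resnet34` (336 px), `resnet50` (336 px), `tiny_small` (24 px),
#'   `tiny_large` (96 px).
#' @export
#' @examples
#' names(reference_specs())
reference_specs <- function() {
  basic <- function(units, ch, st) {
    purrr::map2(units, seq_along(units), function(u, i) {
      block_spec("basic", u, ch[i], st[i])
    })
  }
  bottleneck <- function(units, ch, st) {
    purrr::map2(units, seq_along(units), function(u, i) {
      block_spec("bottleneck", u, ch[i], st[i])
    })
  }
  ref_stem <- stem_spec(64L, kernel = 7L, stride = 2L, pool = TRUE)
  list(
    resnet18 = stream_spec("resnet18", 224L, ref_stem,
                           basic(c(2, 2, 2, 2), c(64, 128, 256, 512),
                                 c(1, 2, 2, 2)), 1000L),
    resnet34 = stream_spec("resnet34", 336L, ref_stem,
                           basic(c(3, 4, 6, 3), c(64, 128, 256, 512),
                                 c(1, 2, 2, 2)), 1000L),
    resnet50 = stream_spec("resnet50", 336L, ref_stem,
                           bottleneck(c(3, 4, 6, 3),
                                      c(256, 512, 1024, 2048),
                                      c(1, 2, 2, 2)), 1000L),
    tiny_small = stream_spec("tiny_small", 24L, stem_spec(8L),
                             basic(c(1, 1), c(16, 32), c(2, 2)), 8L),
    tiny_large = stream_spec("tiny_large", 96L, stem_spec(8L),
                             basic(c(2, 1), c(16, 32), c(2, 2)), 8L,
                             norm = "instance")
  )
}

#' Write or read a stream specification as YAML
#'
#' @param spec A [stream_spec()].
#' @param path File path.
#' @return `stream_spec_from_yaml()` returns a [stream_spec()].
#' @export
stream_spec_to_yaml <- function(spec, path) {
  obj <- list(name = spec$name, input_resolution = spec$input_resolution,
              num_classes = spec$num_classes, norm = spec$norm,
              stem = unclass(spec$stem),
              stages = lapply(spec$stages, unclass))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname stream_spec_to_yaml
#' @export
stream_spec_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  stream_spec(obj$name, obj$input_resolution,
              stem_spec(obj$stem$out_channels, obj$stem$kernel,
                        obj$stem$stride, obj$stem$pool),
              lapply(obj$stages, function(s) {
                block_spec(s$kind, s$n_units, s$out_channels, s$stride)
              }),
              obj$num_classes, norm = obj$norm %||% "batch")
}
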