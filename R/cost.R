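#' Analytic per-layer multiply-accumulate and parameter counts
#'
#' Walks a stream spec layer by layer.  A `k x k` convolution taking
#' `C_in` to `C_out` channels over an `H_out x W_out` output grid
#' contributes `C_out * C_in * k^2 * H_out * W_out` multiply-accumulates;
#' a linear layer contributes `in * out`.  Elementwise, pooling and
#' normalization operations are excluded, and projection (downsample)
#' convolutions inside residual stages are counted.  The `"paper-half"`
#' convention reports half of every standard multiply-accumulate count —
#' it exists solely to reproduce published cost tables stated under that
#' convention and is labeled as such in reports.
#'
#' @param spec A [stream_spec()].
#' @param resolution Input resolution in pixels (defaults to the spec's).
#' @param convention `"standard-mac"` or `"paper-half"`.
#' @return A `cost_report`: list with `layers` (tibble of `layer_name`,
#'   `macs`, `params`), `total_macs`, `total_params`, `convention`,
#'   `resolution` and `model`.
#' @export
#' @examples
#' count_macs(reference_specs()$resnet18, convention = "paper-half")
count_macs <- function(spec, resolution = spec$input_resolution,
                       convention = c("standard-mac", "paper-half")) {
  convention <- match.arg(convention)
  conv_out <- function(h, k, s, p) (h + 2L * p - k) %/% s + 1L
  rows <- list()
  add <- function(name, c_out, c_in, k, h_out) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      layer_name = name,
      macs = as.numeric(c_out) * c_in * k^2 * h_out^2,
      params = as.numeric(c_out) * c_in * k^2 + c_out)
  }
  h <- conv_out(resolution, spec$stem$kernel, spec$stem$stride,
                (spec$stem$kernel - 1L) %/% 2L)
  add("stem.conv", spec$stem$out_channels, 3L, spec$stem$kernel, h)
  if (spec$stem$pool) h <- conv_out(h, 3L, 2L, 1L)
  if (h < 1L) abort("resolution is exhausted by the stem.")
  c_in <- spec$stem$out_channels
  for (i in seq_along(spec$stages)) {
    st <- spec$stages[[i]]
    for (u in seq_len(st$n_units)) {
      stride <- if (u == 1L) st$stride else 1L
      pre <- sprintf("stage%d.unit%d", i, u)
      if (st$kind == "basic") {
        h2 <- conv_out(h, 3L, stride, 1L)
        if (h2 < 1L) abort(sprintf("resolution exhausted at stage %d.", i))
        add(paste0(pre, ".conv1"), st$out_channels, c_in, 3L, h2)
        add(paste0(pre, ".conv2"), st$out_channels, st$out_channels, 3L, h2)
        if (u == 1L && (stride != 1L || c_in != st$out_channels)) {
          add(paste0(pre, ".proj"), st$out_channels, c_in, 1L, h2)
        }
      } else if (st$kind == "bottleneck") {
        mid <- st$out_channels %/% 4L
        add(paste0(pre, ".conv1"), mid, c_in, 1L, h)
        h2 <- conv_out(h, 3L, stride, 1L)
        if (h2 < 1L) abort(sprintf("resolution exhausted at stage %d.", i))
        add(paste0(pre, ".conv2"), mid, mid, 3L, h2)
        add(paste0(pre, ".conv3"), st$out_channels, mid, 1L, h2)
        if (u == 1L && (stride != 1L || c_in != st$out_channels)) {
          add(paste0(pre, ".proj"), st$out_channels, c_in, 1L, h2)
        }
      } else {
        abort(sprintf("unsupported layer kind '%s'.", st$kind))
      }
      h <- h2
      c_in <- st$out_channels
    }
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    layer_name = "head.fc",
    macs = as.numeric(c_in) * spec$num_classes,
    params = as.numeric(c_in) * spec$num_classes + spec$num_classes)
  layers <- dplyr::bind_rows(rows)
  if (convention == "paper-half") layers$macs <- layers$macs / 2
  structure(list(layers = layers, total_macs = sum(layers$macs),
                 total_params = sum(layers$params),
                 convention = convention,
                 resolution = as.integer(resolution), model = spec$name),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("<cost_report> %s @ %dpx [%s]: %.4g MACs, %.4g params\n",
              x$model, x$resolution, x$convention, x$total_macs,
              x$total_params))
  invisible(x)
}

#' Multiply-accumulate cost of a set of feature reuse links
#'
#' Counts the 1x1 alignment convolutions (`C_large * C_small * H' * W'` per
#' link, standard convention); upsampling and the pointwise addition are
#' excluded, consistent with [count_macs()].
#'
#' @param frm_links List of [frm_params()].
#' @return Total multiply-accumulate count.
#' @export
#' @examples
#' frm_cost(list(frm_params(1, matrix(0, 16, 8), NULL, 4, 4)))
frm_cost <- function(frm_links) {
  if (length(frm_links) == 0) return(0)
  sum(vapply(frm_links, function(lk) {
    if (is.null(lk)) return(0)
    as.numeric(nrow(lk$weight)) * ncol(lk$weight) *
      lk$target_height * lk$target_width
  }, numeric(1)))
}

#' Expected mean cascade cost per sample
#'
#' Every sample pays the small stream once; a fraction `rho` additionally
#' pays the large stream and the reuse links:
#' `c_small + rho * (c_large + c_frm)`.
#'
#' @param c_small,c_large,c_frm Per-sample costs of the small stream, the
#'   large stream and the feature reuse links.
#' @param rho Escalation fraction in `[0, 1]`.
#' @return Mean multiply-accumulate cost per sample.
#' @export
expected_cascade_cost <- function(c_small, c_large, c_frm, rho) {
  if (is.na(rho) || rho < 0 || rho > 1) abort("`rho` must lie in [0, 1].")
  c_small + rho * (c_large + c_frm)
}

#' Write a cost report as TSV plus a JSON summary
#'
#' @param report A `cost_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_cost_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) readr::write_tsv(report$layers, tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(model = report$model,
                              resolution = report$resolution,
                              convention = report$convention,
                              total_macs = report$total_macs),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
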