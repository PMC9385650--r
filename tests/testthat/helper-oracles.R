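# Independent oracles used across the suite: direct nested-loop convolution,
# operation enumeration for cost counting, pairwise-concordance AUC, and
# pointwise bilinear interpolation.

# direct per-pixel convolution of one (C,H,W) sample
oracle_conv <- function(x, w, b, stride, pad) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  co_n <- dim(w)[1]; k <- dim(w)[3]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  out <- array(0, c(co_n, Ho, Wo))
  for (co in 1:co_n) for (oy in 1:Ho) for (ox in 1:Wo) {
    acc <- b[co]
    for (ci in 1:C) for (ky in 1:k) for (kx in 1:k) {
      iy <- (oy - 1) * stride + ky - pad
      ix <- (ox - 1) * stride + kx - pad
      if (iy >= 1 && iy <= H && ix >= 1 && ix <= W) {
        acc <- acc + x[ci, iy, ix] * w[co, ci, ky, kx]
      }
    }
    out[co, oy, ox] <- acc
  }
  out
}

# brute-force multiply-accumulate enumeration for a stream spec: walks the
# same architecture but counts by iterating explicitly over every output
# element of every convolution and linear layer
oracle_count_macs <- function(spec, resolution = spec$input_resolution) {
  total <- 0
  count_conv <- function(c_in, c_out, k, h_in, stride, pad) {
    h_out <- (h_in + 2 * pad - k) %/% stride + 1
    for (co in seq_len(c_out)) for (oy in seq_len(h_out)) {
      for (ox in seq_len(h_out)) total <<- total + c_in * k * k
    }
    h_out
  }
  h <- count_conv(3, spec$stem$out_channels, spec$stem$kernel, resolution,
                  spec$stem$stride, (spec$stem$kernel - 1) %/% 2)
  if (spec$stem$pool) h <- (h + 2 - 3) %/% 2 + 1
  c_in <- spec$stem$out_channels
  for (st in spec$stages) {
    for (u in seq_len(st$n_units)) {
      stride <- if (u == 1) st$stride else 1
      if (st$kind == "basic") {
        h2 <- count_conv(c_in, st$out_channels, 3, h, stride, 1)
        count_conv(st$out_channels, st$out_channels, 3, h2, 1, 1)
        if (u == 1 && (stride != 1 || c_in != st$out_channels)) {
          count_conv(c_in, st$out_channels, 1, h, stride, 0)
        }
      } else {
        mid <- st$out_channels %/% 4
        count_conv(c_in, mid, 1, h, 1, 0)
        h2 <- count_conv(mid, mid, 3, h, stride, 1)
        count_conv(mid, st$out_channels, 1, h2, 1, 0)
        if (u == 1 && (stride != 1 || c_in != st$out_channels)) {
          count_conv(c_in, st$out_channels, 1, h, stride, 0)
        }
      }
      h <- h2
      c_in <- st$out_channels
    }
  }
  total <- total + c_in * spec$num_classes
  total
}

# rank-statistic AUC: concordant pairs plus half ties over all pos/neg pairs
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}

# pointwise half-pixel-center bilinear interpolation of a (H,W) matrix
oracle_bilinear <- function(m, H2, W2) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H2, W2)
  for (oy in 1:H2) for (ox in 1:W2) {
    sy <- min(max((oy - 0.5) * H / H2 - 0.5, 0), H - 1)
    sx <- min(max((ox - 0.5) * W / W2 - 0.5, 0), W - 1)
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
    wy <- sy - y0; wx <- sx - x0
    out[oy, ox] <- (1 - wy) * (1 - wx) * m[y0 + 1, x0 + 1] +
      (1 - wy) * wx * m[y0 + 1, x1 + 1] +
      wy * (1 - wx) * m[y1 + 1, x0 + 1] +
      wy * wx * m[y1 + 1, x1 + 1]
  }
  out
}

# assorted tiny specs used by the cost and stream tests
tiny_test_specs <- function() {
  list(
    one_stage = stream_spec("one_stage", 16, stem_spec(4),
                            list(block_spec("basic", 1, 8, 2)), 4),
    two_stage = stream_spec("two_stage", 16, stem_spec(4),
                            list(block_spec("basic", 1, 8, 2),
                                 block_spec("basic", 2, 8, 1)), 3),
    strided_stem = stream_spec("strided_stem", 32,
                               stem_spec(6, kernel = 7, stride = 2,
                                         pool = TRUE),
                               list(block_spec("basic", 1, 8, 1)), 2),
    bottleneck = stream_spec("bottleneck", 16, stem_spec(4),
                             list(block_spec("bottleneck", 2, 8, 2)), 5),
    mixed = stream_spec("mixed", 24, stem_spec(4),
                        list(block_spec("basic", 1, 8, 2),
                             block_spec("bottleneck", 1, 16, 2)), 6)
  )
}

tiny_pair <- function(seed_small = 1, seed_large = 2, num_classes = 8) {
  refs <- reference_specs()
  ss <- refs$tiny_small; ss$num_classes <- as.integer(num_classes)
  sl <- refs$tiny_large; sl$num_classes <- as.integer(num_classes)
  list(small = build_stream(ss, seed_small),
       large = build_stream(sl, seed_large))
}

# small random image batch in [0,1]
random_images <- function(n, size, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(runif(3 * size * size),
                                       c(3, size, size)))
}
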