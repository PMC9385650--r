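# Thin R wrappers over the compiled convolution/pooling kernels, plus the
# purely linear-algebra layers (ReLU, global average pooling, linear head,
# bilinear interpolation).  Feature maps are arrays with dim (C, H, W) for a
# single sample and (C, H, W, N) for a batch.

conv2d_fwd <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  d <- dim(w)
  bias <- if (is.null(b)) numeric(0) else as.numeric(b)
  cpp_conv2d_forward(x, as.integer(dim(x)), w, d[1], d[3], bias,
                     as.integer(stride), as.integer(pad))
}

conv2d_bwd <- function(x, w, gout, stride = 1L, pad = 0L, want_dx = TRUE) {
  d <- dim(w)
  cpp_conv2d_backward(x, as.integer(dim(x)), w, d[1], d[3], gout,
                      as.integer(stride), as.integer(pad), want_dx)
}

maxpool_fwd <- function(x, k = 3L, stride = 2L, pad = 1L) {
  cpp_maxpool_forward(x, as.integer(dim(x)), as.integer(k),
                      as.integer(stride), as.integer(pad))
}

maxpool_bwd <- function(idx, gout, xdim) {
  cpp_maxpool_backward(idx, gout, as.integer(xdim))
}

relu_fwd <- function(x) cpp_relu_forward(x)

# gradient through ReLU given the *output* y (y > 0 <=> input > 0)
relu_bwd <- function(g, y) cpp_relu_backward(g, y)

# (C, H, W, N) -> (C, N) channel means
gap_fwd <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3], d[4])
  out <- matrix(0, d[1], d[4])
  for (n in seq_len(d[4])) out[, n] <- rowMeans(x[, , n, drop = FALSE][, , 1])
  out
}

gap_bwd <- function(dg, xdim) {
  hw <- xdim[2] * xdim[3]
  dx <- array(0, xdim)
  for (n in seq_len(xdim[4])) dx[, , , n] <- dg[, n] / hw
  dx
}

# Half-pixel-center bilinear interpolation matrix mapping n_in samples to
# n_out samples along one axis; source coordinates are clamped at the edges.
interp_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (o in seq_len(n_out)) {
    src <- (o - 0.5) * scale - 0.5   # 0-based source coordinate
    src <- min(max(src, 0), n_in - 1)
    i0 <- floor(src)
    i1 <- min(i0 + 1, n_in - 1)
    w1 <- src - i0
    A[o, i0 + 1] <- A[o, i0 + 1] + (1 - w1)
    A[o, i1 + 1] <- A[o, i1 + 1] + w1
  }
  A
}

# Apply row/column interpolation matrices to a (C,H,W[,N]) array.
apply_interp <- function(x, Ah, Aw) {
  d <- dim(x)
  single <- length(d) == 3L
  if (single) dim(x) <- c(d, 1L)
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  H2 <- nrow(Ah); W2 <- nrow(Aw)
  y <- aperm(x, c(2, 1, 3, 4))               # (H, C, W, N)
  y <- Ah %*% matrix(y, H)                   # (H2, C*W*N)
  y <- array(y, c(H2, C, W, N))
  y <- aperm(y, c(3, 1, 2, 4))               # (W, H2, C, N)
  y <- Aw %*% matrix(y, W)                   # (W2, H2*C*N)
  y <- array(y, c(W2, H2, C, N))
  y <- aperm(y, c(3, 2, 1, 4))               # (C, H2, W2, N)
  if (single) dim(y) <- dim(y)[1:3]
  y
}

# Bilinear resize (up or down) of a (C,H,W[,N]) array with half-pixel centers.
resize_bilinear <- function(x, height, width) {
  d <- dim(x)
  if (d[2] == height && d[3] == width) return(x)
  apply_interp(x, interp_matrix(d[2], height), interp_matrix(d[3], width))
}

# Transpose map of resize_bilinear: pushes a gradient at (height2, width2)
# back to the (height, width) grid.
resize_bilinear_bwd <- function(g, height, width) {
  d <- dim(g)
  apply_interp(g, t(interp_matrix(height, d[2])), t(interp_matrix(width, d[3])))
}
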