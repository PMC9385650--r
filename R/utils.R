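# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Numerically stable softmax over the rows of a (n_classes x N) logit matrix.
softmax <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, ncol = 1)
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m, "-"))
  sweep(e, 2, colSums(e), "/")
}

# argmax with lowest-index tie-breaking, returning 0-based class indices
argmax0 <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 1)
  apply(p, 2, which.max) - 1L
}

as_batch <- function(images) {
  if (is.list(images)) {
    d <- dim(images[[1]])
    out <- array(0, c(d, length(images)))
    for (i in seq_along(images)) out[, , , i] <- images[[i]]
    out
  } else if (length(dim(images)) == 3L) {
    array(images, c(dim(images), 1L))
  } else images
}

# map2 over two parallel nested parameter lists, preserving structure;
# NULL leaves (absent projections/biases) stay NULL.
nmap2 <- function(a, b, f) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- nmap2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

nmap <- function(a, f) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- nmap(a[[i]], f)
    out
  } else f(a)
}

# flatten a nested parameter list into a flat numeric vector (for checksums)
param_vector <- function(params) {
  unlist(params, use.names = FALSE)
}
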