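test_that("tiny stream produces one tap per stage with normalized probabilities", {
  spec <- stream_spec("t", 32, stem_spec(8),
                      list(block_spec("basic", 1, 8, 1)), 4)
  st <- build_stream(spec, seed = 7)
  x <- array(runif(3 * 32 * 32 * 5), c(3, 32, 32, 5))
  out <- forward_with_taps(st, x)
  expect_length(out$taps, 1L)
  expect_equal(dim(out$taps[[1]]), c(8, 32, 32, 5))
  expect_equal(dim(out$probabilities), c(4, 5))
  expect_true(all(out$probabilities >= 0))
  expect_lt(max(abs(colSums(out$probabilities) - 1)), 1e-6)
})

test_that("identical spec and seed give identical parameters and outputs", {
  spec <- reference_specs()$tiny_small
  a <- build_stream(spec, seed = 42)
  b <- build_stream(spec, seed = 42)
  expect_identical(a$params, b$params)
  x <- array(runif(3 * 24 * 24 * 2), c(3, 24, 24, 2))
  expect_identical(forward_with_taps(a, x)$logits,
                   forward_with_taps(b, x)$logits)
  d <- build_stream(spec, seed = 43)
  expect_false(identical(a$params, d$params))
})

test_that("zeroed head yields uniform probabilities and softmax matches closed form", {
  spec <- stream_spec("t", 16, stem_spec(4),
                      list(block_spec("basic", 1, 8, 2)), 4)
  st <- build_stream(spec, seed = 1)
  st$params$head$w[] <- 0
  st$params$head$b[] <- 0
  out <- forward_with_taps(st, array(runif(3 * 16 * 16), c(3, 16, 16)))
  expect_equal(as.numeric(out$probabilities), rep(1 / 4, 4), tolerance = 1e-12)
  # softmax of logits [ln 2, 0] is [2/3, 1/3]
  expect_equal(as.numeric(cascadenet:::softmax(c(log(2), 0))),
               c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("convolution layers agree with the direct nested-loop oracle", {
  set.seed(5)
  configs <- list(list(C = 1, Co = 1, k = 3, H = 4, s = 1, p = 0),
                  list(C = 3, Co = 4, k = 3, H = 8, s = 2, p = 1),
                  list(C = 2, Co = 5, k = 1, H = 6, s = 1, p = 0),
                  list(C = 4, Co = 2, k = 7, H = 8, s = 2, p = 3))
  for (cf in configs) {
    x <- array(rnorm(cf$C * cf$H * cf$H), c(cf$C, cf$H, cf$H))
    w <- array(rnorm(cf$Co * cf$C * cf$k^2), c(cf$Co, cf$C, cf$k, cf$k))
    b <- rnorm(cf$Co)
    got <- cascadenet:::conv2d_fwd(array(x, c(dim(x), 1)), w, b, cf$s, cf$p)
    ref <- oracle_conv(x, w, b, cf$s, cf$p)
    expect_equal(dim(got), c(dim(ref), 1L))
    expect_lt(max(abs(as.numeric(got) - as.numeric(ref))), 1e-5)
  }
})

test_that("hand-set 3x3 convolution on a 4x4 input matches direct arithmetic", {
  x <- array(matrix(1:16, 4, 4), c(1, 4, 4))
  w <- array(0, c(1, 1, 3, 3))
  w[1, 1, 2, 2] <- 1   # identity kernel
  w[1, 1, 1, 1] <- -1
  got <- cascadenet:::conv2d_fwd(array(x, c(1, 4, 4, 1)), w, 0, 1L, 1L)
  ref <- oracle_conv(x, w, 0, 1, 1)
  expect_equal(got[, , , 1], array(ref[1, , ], c(4, 4)), tolerance = 1e-12)
})

test_that("backward pass matches numerical gradients end to end", {
  spec <- stream_spec("t", 12, stem_spec(4),
                      list(block_spec("basic", 1, 6, 2),
                           block_spec("bottleneck", 1, 8, 1)), 3)
  st <- build_stream(spec, seed = 3)
  set.seed(4)
  x <- array(runif(3 * 12 * 12 * 2), c(3, 12, 12, 2))
  y <- c(0L, 2L)
  ce <- function(stream) {
    o <- forward_with_taps(stream, x, training = TRUE)
    -mean(log(o$probabilities[cbind(y + 1, 1:2)]))
  }
  out <- forward_with_taps(st, x, keep_cache = TRUE, training = TRUE)
  dlog <- out$probabilities
  dlog[cbind(y + 1, 1:2)] <- dlog[cbind(y + 1, 1:2)] - 1
  dlog <- dlog / 2
  bw <- cascadenet:::stream_backward(st, out$cache, dlog)
  eps <- 1e-5
  probes <- list(
    list(get = function(p) p$stages[[1]][[1]]$conv1$w[3],
         set = function(p, v) { p$stages[[1]][[1]]$conv1$w[3] <- v; p },
         g = bw$grads$stages[[1]][[1]]$conv1$w[3]),
    list(get = function(p) p$stages[[2]][[1]]$conv2$w[5],
         set = function(p, v) { p$stages[[2]][[1]]$conv2$w[5] <- v; p },
         g = bw$grads$stages[[2]][[1]]$conv2$w[5]),
    list(get = function(p) p$stem$g[2],
         set = function(p, v) { p$stem$g[2] <- v; p },
         g = bw$grads$stem$g[2]),
    list(get = function(p) p$stages[[1]][[1]]$proj$beta[3],
         set = function(p, v) { p$stages[[1]][[1]]$proj$beta[3] <- v; p },
         g = bw$grads$stages[[1]][[1]]$proj$beta[3]),
    list(get = function(p) p$head$b[1],
         set = function(p, v) { p$head$b[1] <- v; p },
         g = bw$grads$head$b[1]))
  for (pr in probes) {
    v0 <- pr$get(st$params)
    up <- st; up$params <- pr$set(st$params, v0 + eps)
    dn <- st; dn$params <- pr$set(st$params, v0 - eps)
    expect_equal((ce(up) - ce(dn)) / (2 * eps), pr$g, tolerance = 1e-4)
  }
})

test_that("wrong input size and invalid specs raise informative errors", {
  st <- build_stream(reference_specs()$tiny_small, 1)
  expect_error(forward_with_taps(st, array(0, c(3, 32, 32, 1))),
               "expected \\(3, 24, 24\\)")
  expect_error(stream_spec("bad", 4, stem_spec(4, kernel = 7, stride = 2,
                                               pool = TRUE),
                           list(block_spec("basic", 1, 8, 2),
                                block_spec("basic", 1, 8, 2)), 2),
               "stage 1")
  expect_error(block_spec("basic", 0, 8, 1), "n_units")
  expect_error(block_spec("bottleneck", 1, 10, 1), "divisible by 4")
})

test_that("reference specs have matched stage counts and familiar parameter totals", {
  refs <- reference_specs()
  expect_length(refs$resnet18$stages, 4L)
  expect_length(refs$resnet34$stages, 4L)
  expect_identical(length(refs$tiny_small$stages),
                   length(refs$tiny_large$stages))
  # independent per-layer parameter summation for the 18-layer stream
  p_expected <- 0
  add_conv <- function(co, ci, k) co * ci * k * k + co
  p_expected <- p_expected + add_conv(64, 3, 7)
  ch <- c(64, 128, 256, 512); c_in <- 64
  for (i in 1:4) for (u in 1:2) {
    stride1 <- i > 1 && u == 1
    p_expected <- p_expected + add_conv(ch[i], c_in, 3) +
      add_conv(ch[i], ch[i], 3)
    if (u == 1 && c_in != ch[i]) p_expected <- p_expected + add_conv(ch[i], c_in, 1)
    c_in <- ch[i]
  }
  p_expected <- p_expected + 512 * 1000 + 1000
  cr <- count_macs(refs$resnet18)
  expect_equal(cr$total_params, p_expected)
  expect_equal(cr$total_params / 1e6, 11.7, tolerance = 0.01)
})

test_that("the 18-layer reference stream builds and runs at 224 pixels", {
  st <- build_stream(reference_specs()$resnet18, seed = 1)
  x <- array(runif(3 * 224 * 224), c(3, 224, 224, 1))
  out <- forward_with_taps(st, x)
  expect_length(out$taps, 4L)
  expect_equal(dim(out$taps[[4]]), c(512, 7, 7, 1))
  expect_lt(abs(sum(out$probabilities) - 1), 1e-6)
})

test_that("stream specs round-trip through YAML", {
  spec <- reference_specs()$tiny_large
  path <- withr::local_tempfile(fileext = ".yaml")
  stream_spec_to_yaml(spec, path)
  back <- stream_spec_from_yaml(path)
  expect_equal(unclass(back), unclass(spec))
})
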