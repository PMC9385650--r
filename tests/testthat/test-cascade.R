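test_that("routing follows the strict threshold rule", {
  r <- router_config(0.8)
  expect_equal(route(c(0.9, 0.05, 0.05), r), "exit")
  expect_equal(route(rep(1 / 8, 8), r), "escalate")
  expect_equal(route(c(0.8, 0.2), r), "escalate")   # strict greater-than
  # finite logits keep max softmax strictly below 1, so tau = 1 escalates
  p <- as.numeric(cascadenet:::softmax(c(50, 0, 0)))
  expect_equal(route(p, router_config(1)), "escalate")
  expect_error(route(c(0.5, 0.4), r), "normalized")
  expect_error(router_config(1.5), "tau")
})

test_that("threshold extremes pin the exit point and match standalone streams", {
  pair <- tiny_pair()
  imgs <- random_images(10, 96, seed = 21)
  data <- tibble::tibble(sample_id = sprintf("s%02d", 1:10), image = imgs)
  m0 <- cascade_model(pair$small, pair$large, router = router_config(0))
  dec0 <- cascade_predict(m0, data)
  expect_true(all(dec0$exit == "small"))
  xs <- cascadenet:::preprocess_batch(imgs, 24, m0$normalize)
  expect_identical(dec0$label, predict(pair$small, xs)$label)
  m1 <- cascade_model(pair$small, pair$large, router = router_config(1))
  dec1 <- cascade_predict(m1, data)
  expect_true(all(dec1$exit == "large"))
  # zero FRM: tau = 1 equals the standalone large stream (simple combination)
  xl <- cascadenet:::preprocess_batch(imgs, 96, m1$normalize)
  expect_identical(dec1$label, predict(pair$large, xl)$label)
})

test_that("cascade decisions match a step-by-step reference composition", {
  pair <- tiny_pair(seed_small = 5, seed_large = 6)
  spec <- synth_spec(n_images = 16, seed = 31)
  data <- generate_dataset(spec)
  links <- init_frm_links(pair$small$spec, pair$large$spec)
  for (i in seq_along(links)) {
    set.seed(100 + i)
    links[[i]]$weight[] <- rnorm(length(links[[i]]$weight), sd = 0.05)
  }
  model <- cascade_model(pair$small, pair$large, links,
                         router = router_config(0.8))
  dec <- cascade_predict(model, data)
  # reference: run route() and the two streams by hand, sample by sample
  for (i in seq_len(nrow(data))) {
    img <- data$image[[i]]
    xs <- cascadenet:::preprocess_batch(list(img), 24, model$normalize)
    s_out <- forward_with_taps(pair$small, xs)
    p_s <- as.numeric(s_out$probabilities)
    verdict <- route(p_s, model$router)
    if (verdict == "exit") {
      expect_equal(dec$exit[i], "small")
      expect_equal(dec$label[i], which.max(p_s) - 1L)
      expect_equal(dec$p_small[[i]], p_s, tolerance = 1e-12)
      expect_null(dec$p_large[[i]])
    } else {
      expect_equal(dec$exit[i], "large")
      xl <- cascadenet:::preprocess_batch(list(img), 96, model$normalize)
      fuse <- purrr::map2(links, s_out$taps,
                          function(lk, tp) {
                            frm_fuse(array(0, c(nrow(lk$weight),
                                                lk$target_height,
                                                lk$target_width, 1L)),
                                     align_1x1(upsample_bilinear(
                                       tp, lk$target_height,
                                       lk$target_width), lk))
                          })
      l_out <- forward_with_taps(pair$large, xl, fuse = fuse)
      p_l <- as.numeric(l_out$probabilities)
      expect_equal(dec$label[i], which.max(p_l) - 1L)
      expect_equal(dec$p_large[[i]], p_l, tolerance = 1e-10)
    }
  }
})

test_that("every sample gets exactly one decision and costs partition accordingly", {
  pair <- tiny_pair()
  data <- tibble::tibble(image = random_images(12, 96, seed = 41))
  model <- cascade_model(pair$small, pair$large, router = router_config(0.5))
  dec <- cascade_predict(model, data)
  expect_equal(nrow(dec), 12L)
  expect_equal(sum(dec$exit == "small") + sum(dec$exit == "large"), 12L)
  costs <- attr(dec, "costs")
  full <- costs$c_small + costs$c_large + costs$c_frm
  expect_true(all(dec$cost_macs[dec$exit == "small"] == costs$c_small))
  expect_true(all(dec$cost_macs[dec$exit == "large"] == full))
})

test_that("mean attributed cost equals the analytic expectation exactly", {
  pair <- tiny_pair(seed_small = 3, seed_large = 4)
  spec <- synth_spec(n_images = 24, seed = 51)
  data <- generate_dataset(spec)
  model <- cascade_model(pair$small, pair$large, router = router_config(0.4))
  dec <- cascade_predict(model, data)
  costs <- attr(dec, "costs")
  rho <- mean(dec$exit == "large")
  expect_identical(mean(dec$cost_macs),
                   expected_cascade_cost(costs$c_small, costs$c_large,
                                         costs$c_frm, rho))
})

test_that("escalation fraction and cost are non-decreasing over a threshold grid", {
  pair <- tiny_pair()
  spec <- synth_spec(n_images = 32, seed = 61)
  data <- generate_dataset(spec)
  model <- cascade_model(pair$small, pair$large)
  grid <- seq(0, 1, length.out = 21)
  sw <- sweep_tau(model, data, grid)
  expect_equal(nrow(sw), 21L)
  expect_equal(sw$escalation_fraction[1], 0)
  expect_equal(sw$escalation_fraction[21], 1)
  expect_true(all(diff(sw$escalation_fraction) >= 0))
  expect_true(all(diff(sw$mean_cost_macs) >= 0))
  expect_error(sweep_tau(model, data[0, ], grid), "non-empty")
  expect_error(sweep_tau(model, data, c(-0.1)), "0, 1")
})

test_that("decision CSV export keeps the scalar record per sample", {
  pair <- tiny_pair()
  data <- tibble::tibble(image = random_images(5, 96, seed = 71))
  dec <- cascade_predict(cascade_model(pair$small, pair$large), data)
  path <- withr::local_tempfile(fileext = ".csv")
  write_decisions_csv(dec, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back),
               c("sample_id", "exit", "label", "confidence", "cost_macs"))
  expect_equal(nrow(back), 5L)
})

test_that("mismatched stream pairs are rejected", {
  refs <- reference_specs()
  small <- build_stream(refs$tiny_small, 1)
  one_stage <- build_stream(stream_spec("x", 96, stem_spec(8),
                                        list(block_spec("basic", 1, 16, 2)),
                                        8), 1)
  expect_error(cascade_model(small, one_stage), "stage counts differ")
  large <- build_stream(refs$tiny_large, 1)
  expect_error(cascade_model(large, large), "lower input resolution")
})
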