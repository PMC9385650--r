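# quick two-class fixture: easy stratum only, so the color cue makes the
# task linearly separable at any resolution
separable_set <- function(n = 160, seed = 5) {
  spec <- synth_spec(n_classes = 2, image_size = 32, n_images = n,
                     easy_fraction = 1, lesion_radius = 3,
                     seed = seed)
  generate_dataset(spec)
}

tiny2 <- function() {
  stream_spec("tiny2", 16, stem_spec(8),
              list(block_spec("basic", 1, 16, 2)), 2)
}

test_that("augmentation is an involution under flips, affine under normalization, and deterministic", {
  img <- array(runif(3 * 8 * 8), c(3, 8, 8))
  expect_identical(cascadenet:::flip_h(cascadenet:::flip_h(img)), img)
  expect_identical(cascadenet:::flip_v(cascadenet:::flip_v(img)), img)
  norm <- list(mean = c(0.5, 0.4, 0.3), sd = c(0.2, 0.2, 0.1))
  const <- array(0.7, c(3, 6, 6))
  got <- cascadenet:::normalize_single(const, norm)
  for (c in 1:3) {
    expect_equal(unique(as.numeric(got[c, , ])),
                 (0.7 - norm$mean[c]) / norm$sd[c], tolerance = 1e-12)
  }
  cfg <- augmentation_config()
  set.seed(10); a <- augment_image(img, 6, cfg)
  set.seed(10); b <- augment_image(img, 6, cfg)
  expect_identical(a, b)
  expect_equal(dim(a), c(3, 6, 6))
  expect_error(augmentation_config(hflip_prob = 1.5), "probabilities")
  expect_error(augmentation_config(normalize = list(mean = rep(0, 3),
                                                    sd = c(1, 0, 1))),
               "sd")
})

test_that("zero epochs return the seed-initialized stream untouched", {
  d <- separable_set(16)
  cfg <- train_config(epochs_stage1 = 0, seed = 3)
  fit <- train_stream(tiny2(), d, cfg)
  expect_identical(fit$stream$params, build_stream(tiny2(), 3)$params)
  expect_equal(nrow(fit$history), 0L)
})

test_that("training is deterministic given data, config and seed", {
  d <- separable_set(32)
  cfg <- train_config(learning_rate = 1e-3, epochs_stage1 = 2, seed = 11)
  f1 <- train_stream(tiny2(), d, cfg)
  f2 <- train_stream(tiny2(), d, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$stream$params, f2$stream$params)
  expect_true(all(is.finite(f1$history$loss)))
})

test_that("a linearly separable two-class set is learned to near-oracle accuracy", {
  d <- separable_set(160)
  cfg <- train_config(learning_rate = 1e-3, epochs_stage1 = 12, seed = 0)
  fit <- train_stream(tiny2(), d, cfg)
  expect_equal(nrow(fit$history), 12L)
  expect_gte(utils::tail(fit$history$accuracy, 1), 0.95)
  expect_true(all(is.finite(fit$history$loss)))
  expect_lt(utils::tail(fit$history$loss, 1), fit$history$loss[1])
})

test_that("labels outside the class range name the offending sample", {
  d <- separable_set(16)
  d$label[3] <- 7L
  bad_id <- d$sample_id[3]
  expect_error(train_stream(tiny2(), d, train_config(epochs_stage1 = 1)),
               bad_id)
})

test_that("requesting pretrained initialization fails loudly", {
  d <- separable_set(16)
  cfg <- train_config(epochs_stage1 = 1, pretrained_init = TRUE)
  expect_error(train_stream(tiny2(), d, cfg), "pretrained")
})

test_that("fine-tuning freezes the small stream and starts from the zero-FRM identity", {
  spec <- synth_spec(n_classes = 4, image_size = 48, n_images = 32,
                     easy_fraction = 0.5, seed = 21)
  d <- generate_dataset(spec)
  small_spec <- stream_spec("s", 12, stem_spec(4),
                            list(block_spec("basic", 1, 8, 2)), 4)
  large_spec <- stream_spec("l", 48, stem_spec(4),
                            list(block_spec("basic", 1, 8, 2)), 4)
  cfg <- train_config(learning_rate = 1e-3, epochs_stage1 = 1,
                      epochs_stage2 = 2, seed = 4)
  fs <- train_stream(small_spec, d, cfg)
  fl <- train_stream(large_spec, d, cfg)
  checksum_before <- sum(abs(cascadenet:::param_vector(fs$stream$params)))
  # zero stage-2 epochs: cascade behaves exactly as the simple combination
  cfg0 <- cfg; cfg0$epochs_stage2 <- 0L
  m0 <- finetune_frm(fs, fl, d, cfg0)
  expect_true(all(vapply(m0$frm_links,
                         function(lk) all(lk$weight == 0) && all(lk$bias == 0),
                         logical(1))))
  expect_identical(m0$large$params, fl$stream$params)
  # real fine-tuning: small untouched, FRM weights move, loss finite
  m <- finetune_frm(fs, fl, d, cfg)
  checksum_after <- sum(abs(cascadenet:::param_vector(m$small$params)))
  expect_identical(checksum_before, checksum_after)
  expect_identical(m$small$params, fs$stream$params)
  expect_false(all(m$frm_links[[1]]$weight == 0))
  h <- attr(m, "history")
  expect_equal(nrow(h), 2L)
  expect_true(all(is.finite(h$loss)))
})

test_that("unfrozen fine-tuning updates the small stream through the reuse path", {
  spec <- synth_spec(n_classes = 2, image_size = 32, n_images = 16,
                     easy_fraction = 0.5, seed = 22)
  d <- generate_dataset(spec)
  small_spec <- stream_spec("s", 8, stem_spec(4),
                            list(block_spec("basic", 1, 4, 2)), 2)
  large_spec <- stream_spec("l", 32, stem_spec(4),
                            list(block_spec("basic", 1, 4, 2)), 2)
  # several fine-tuning batches are needed: gradients only reach the small
  # stream once the zero-initialized reuse weights have moved off zero
  cfg <- train_config(learning_rate = 1e-3, batch_size = 4,
                      epochs_stage1 = 1, epochs_stage2 = 3, seed = 5,
                      freeze_small_in_stage2 = FALSE)
  fs <- train_stream(small_spec, d, cfg)
  fl <- train_stream(large_spec, d, cfg)
  m <- finetune_frm(fs, fl, d, cfg)
  expect_false(identical(m$small$params, fs$stream$params))
})

test_that("checkpoints round-trip predictions bit-identically", {
  pair <- tiny_pair(seed_small = 8, seed_large = 9)
  model <- cascade_model(pair$small, pair$large,
                         router = router_config(0.6))
  data <- tibble::tibble(image = random_images(6, 96, seed = 81))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  d1 <- cascade_predict(model, data)
  d2 <- cascade_predict(back, data)
  expect_identical(d1$label, d2$label)
  expect_identical(d1$confidence, d2$confidence)
  expect_identical(d1$probs, d2$probs)
  bogus <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bogus)
  expect_error(load_checkpoint(bogus), "not a cascadenet checkpoint")
})
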