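test_that("generation is deterministic per seed and seeds differ", {
  spec <- synth_spec(n_images = 24, seed = 7)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a, b)
  c <- generate_dataset(synth_spec(n_images = 24, seed = 8))
  expect_false(identical(a$image, c$image))
  # caller's RNG stream is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); generate_dataset(spec); after <- runif(1)
  expect_identical(before, after)
})

test_that("classes are balanced and strata follow the easy fraction", {
  d <- generate_dataset(synth_spec(n_images = 80, seed = 1))
  expect_equal(as.numeric(table(d$label)), rep(10, 8))
  by_class <- table(d$label, d$stratum)
  expect_true(all(by_class[, "easy"] == 7))   # round(0.7 * 10)
  expect_true(all(by_class[, "hard"] == 3))
  d2 <- generate_dataset(synth_spec(n_images = 40, easy_fraction = 0.5,
                                    seed = 2))
  # 5 per class: the easy count per class must be within rounding of 2.5
  per_class_easy <- table(d2$label[d2$stratum == "easy"])
  expect_true(all(per_class_easy %in% c(2L, 3L)))
  expect_error(generate_dataset(synth_spec(n_images = 4)), "n_images")
  expect_error(synth_spec(lesion_radius = 20), "image_size / 8")
})

test_that("pixel values stay in range and images are not degenerate", {
  d <- generate_dataset(synth_spec(n_images = 16, seed = 3))
  for (img in d$image) {
    expect_true(all(img >= 0 & img <= 1))
    expect_gt(stats::sd(img), 0.01)
  }
  # hard samples carry a lesion center inside the image, easy ones do not
  expect_true(all(is.na(d$lesion_y[d$stratum == "easy"])))
  hard <- d$stratum == "hard"
  expect_true(all(d$lesion_y[hard] >= 1 & d$lesion_y[hard] <= 96))
})

test_that("the oracle classifier certifies the designed resolution gap", {
  spec <- synth_spec()
  full <- stratum_bayes_accuracy(spec, 96, n_mc = 150)
  expect_gte(full$accuracy[full$stratum == "easy"], 0.95)
  expect_gte(full$accuracy[full$stratum == "hard"], 0.9)
  low <- stratum_bayes_accuracy(spec, 24, n_mc = 150)
  expect_gte(low$accuracy[low$stratum == "easy"], 0.95)
  chance <- 1 / spec$n_classes
  expect_lte(low$accuracy[low$stratum == "hard"], chance + 0.1)
  # easy-vs-hard gap at the small stream's resolution
  expect_gte(low$accuracy[low$stratum == "easy"] -
               low$accuracy[low$stratum == "hard"], 0.5)
})

test_that("threefold downsampling keeps easy cues and destroys hard ones", {
  spec <- synth_spec()
  third <- stratum_bayes_accuracy(spec, 32, n_mc = 200)
  expect_gte(third$accuracy[third$stratum == "easy"], 0.95)
  expect_lte(third$accuracy[third$stratum == "hard"],
             1 / spec$n_classes + 0.1)
})

test_that("datasets round-trip through the PNG tree and manifest", {
  d <- generate_dataset(synth_spec(n_images = 16, seed = 5))
  root <- withr::local_tempdir()
  write_synth_dataset(d, root)
  man <- load_dataset(root)
  expect_equal(nrow(man), 16L)
  expect_equal(sort(unique(man$class)), sort(sprintf("class_%d", 0:7)))
  loaded <- load_images(man)
  # PNG quantizes to 8 bits; pixels must survive within that precision
  orig <- d$image[[which(d$sample_id == loaded$sample_id[1])]]
  expect_equal(loaded$image[[1]], orig, tolerance = 1 / 255)
})
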