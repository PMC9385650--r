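#' Specification of the synthetic small-lesion image generator
#'
#' The generator emulates the statistical structure a resolution-adaptive
#' cascade exploits, in two difficulty strata.  *Easy* samples carry a
#' global cue — a class-specific background hue under a random
#' low-frequency illumination field — that survives aggressive
#' downsampling.  *Hard* samples have class-uninformative neutral
#' backgrounds plus a single small lesion-like blob whose fine radial
#' texture encodes the class; the texture's cycle length sits just above
#' the pixel scale, so resizing below the lesion scale destroys it.  The
#' radial (ring) texture is deliberately invariant under horizontal and
#' vertical flips, so the training augmentations never change a sample's
#' class.  Cue parameters are exposed via the template-matching oracle
#' [stratum_bayes_accuracy()].
#'
#' @param n_classes Number of classes (default 8).
#' @param image_size Square image size in pixels (default 96).
#' @param n_images Number of images to generate.
#' @param easy_fraction Fraction of easy samples (default 0.7).
#' @param lesion_radius Blob radius in pixels, small relative to
#'   `image_size` (must be `< image_size / 8`).
#' @param background_noise_sigma Per-pixel Gaussian noise level.
#' @param seed Seed; identical specs generate bit-identical datasets.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(n_classes = 8L, image_size = 96L, n_images = 480L,
                       easy_fraction = 0.7, lesion_radius = 3,
                       background_noise_sigma = 0.05, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (easy_fraction < 0 || easy_fraction > 1) {
    abort("`easy_fraction` must lie in [0, 1].")
  }
  if (lesion_radius >= image_size / 8) {
    abort("`lesion_radius` must be < image_size / 8.")
  }
  structure(list(n_classes = n_classes, image_size = as.integer(image_size),
                 n_images = as.integer(n_images),
                 easy_fraction = easy_fraction,
                 lesion_radius = lesion_radius,
                 background_noise_sigma = background_noise_sigma,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Parametric class cues; these parameters define the oracle classifier.
synth_class_cues <- function(spec) {
  k <- seq_len(spec$n_classes)
  hue <- (k - 1) / spec$n_classes
  col <- grDevices::col2rgb(grDevices::hsv(hue, 0.55, 0.65)) / 255
  tibble::tibble(class = k - 1L,
                 bg_r = col[1, ], bg_g = col[2, ], bg_b = col[3, ],
                 phase = (k - 1) / spec$n_classes)
}

# fine radial texture cycle length (pixels); just above pixel scale so a
# resize below the lesion scale averages it away
lesion_cycle <- function(spec) max(1.5, spec$lesion_radius / 2)

synth_amplitude <- 0.35
hard_bg_level <- 0.45

# zero-disc-mean radial pattern around a (possibly subpixel) center;
# returns an (H x W) matrix to add to all three channels
lesion_pattern <- function(size_y, size_x, cy, cx, radius, cycle, phase) {
  d <- sqrt(outer((seq_len(size_y) - cy)^2, (seq_len(size_x) - cx)^2, "+"))
  wmask <- pmin(pmax(radius + 0.5 - d, 0), 1)
  gv <- cos(2 * pi * (d / cycle - phase))
  m <- sum(gv * wmask) / sum(wmask)
  synth_amplitude * (gv - m) * wmask
}

render_easy <- function(spec, cues, class) {
  s <- spec$image_size
  base <- c(cues$bg_r[class + 1L], cues$bg_g[class + 1L],
            cues$bg_b[class + 1L])
  fx <- runif(1, 0.5, 2); fy <- runif(1, 0.5, 2); ph <- runif(1, 0, 2 * pi)
  grid_y <- matrix(seq_len(s) / s, s, s)
  grid_x <- matrix(seq_len(s) / s, s, s, byrow = TRUE)
  field <- 1 + 0.2 * sin(2 * pi * (fx * grid_x + fy * grid_y) + ph)
  img <- array(0, c(3, s, s))
  for (c in 1:3) {
    img[c, , ] <- base[c] * field +
      rnorm(s * s, sd = spec$background_noise_sigma)
  }
  pmin(pmax(img, 0), 1)
}

render_hard <- function(spec, cues, class) {
  s <- spec$image_size
  r <- spec$lesion_radius
  margin <- ceiling(r + 2 + 0.06 * s)
  cy <- sample(seq(margin, s - margin), 1)
  cx <- sample(seq(margin, s - margin), 1)
  grid_y <- matrix(seq_len(s) / s, s, s)
  grid_x <- matrix(seq_len(s) / s, s, s, byrow = TRUE)
  slope <- runif(2, -0.1, 0.1)
  illum <- hard_bg_level * (1 + slope[1] * (grid_y - 0.5) +
                              slope[2] * (grid_x - 0.5))
  pat <- lesion_pattern(s, s, cy, cx, r, lesion_cycle(spec),
                        cues$phase[class + 1L])
  img <- array(0, c(3, s, s))
  for (c in 1:3) {
    img[c, , ] <- illum + pat + rnorm(s * s, sd = spec$background_noise_sigma)
  }
  list(image = pmin(pmax(img, 0), 1), cy = cy, cx = cx)
}

#' Generate a labeled synthetic dataset with easy/hard difficulty strata
#'
#' Classes are balanced within one sample; within each class, the easy
#' proportion matches `easy_fraction` within rounding.  Lesion centers are
#' placed inside a margin so random crops retain the lesion with high
#' probability.  Identical specs (including seed) generate bit-identical
#' datasets; the caller's RNG state is untouched.
#'
#' @param spec A [synth_spec()].
#' @return Tibble with `sample_id`, `image` (list of `(3, S, S)` arrays in
#'   `[0, 1]`), `label` (0-based), `stratum` (`"easy"`/`"hard"`), and the
#'   lesion center `lesion_y`, `lesion_x` (`NA` for easy samples).
#' @export
#' @examples
#' d <- generate_dataset(synth_spec(n_images = 16, seed = 1))
#' table(d$label, d$stratum)
generate_dataset <- function(spec) {
  if (spec$n_images < spec$n_classes) {
    abort("`n_images` must be >= `n_classes`.")
  }
  cues <- synth_class_cues(spec)
  label <- rep(seq_len(spec$n_classes) - 1L, length.out = spec$n_images)
  label <- sort(label)
  stratum <- unlist(lapply(split(label, label), function(g) {
    n_easy <- round(spec$easy_fraction * length(g))
    c(rep("easy", n_easy), rep("hard", length(g) - n_easy))
  }), use.names = FALSE)
  with_seed(spec$seed, {
    ord <- sample.int(spec$n_images)
    label <- label[ord]; stratum <- stratum[ord]
    rows <- vector("list", spec$n_images)
    for (i in seq_len(spec$n_images)) {
      if (stratum[i] == "easy") {
        img <- render_easy(spec, cues, label[i])
        rows[[i]] <- list(image = img, cy = NA_real_, cx = NA_real_)
      } else {
        rows[[i]] <- render_hard(spec, cues, label[i])
      }
    }
    tibble::tibble(
      sample_id = sprintf("s%05d", seq_len(spec$n_images)),
      image = lapply(rows, `[[`, "image"),
      label = label,
      stratum = stratum,
      lesion_y = vapply(rows, `[[`, numeric(1), "cy"),
      lesion_x = vapply(rows, `[[`, numeric(1), "cx"))
  })
}

# class template patch (zero-mean luminance) rendered at full resolution
# and resized by the same factor as the image under test
hard_templates <- function(spec, resolution) {
  r <- spec$lesion_radius
  p <- 2L * ceiling(r + 2) + 1L
  ctr <- (p + 1) / 2
  factor <- resolution / spec$image_size
  q <- max(3L, 2L * round((r + 2) * factor) + 1L)
  cues <- synth_class_cues(spec)
  lapply(seq_len(spec$n_classes), function(k) {
    pat <- lesion_pattern(p, p, ctr, ctr, r, lesion_cycle(spec),
                          cues$phase[k])
    tm <- resize_bilinear(array(pat, c(1, p, p)), q, q)[1, , ]
    tm <- tm - mean(tm)
    tm / sqrt(sum(tm^2) + 1e-12)
  })
}

# the generator's own nearest-template classifiers
oracle_classify_easy <- function(image, cues) {
  mu <- apply(image, 1, mean)
  dist2 <- (cues$bg_r - mu[1])^2 + (cues$bg_g - mu[2])^2 +
    (cues$bg_b - mu[3])^2
  cues$class[which.min(dist2)]
}

oracle_classify_hard <- function(image, cy, cx, spec, resolution, templates) {
  img <- resize_bilinear(image, resolution, resolution)
  lum <- (img[1, , ] + img[2, , ] + img[3, , ]) / 3
  factor <- resolution / spec$image_size
  q <- dim(templates[[1]])[1]
  hw <- (q - 1L) %/% 2L
  oy <- round((cy - 0.5) * factor + 0.5)
  ox <- round((cx - 0.5) * factor + 0.5)
  oy <- min(max(oy, hw + 1L), resolution - hw)
  ox <- min(max(ox, hw + 1L), resolution - hw)
  patch <- lum[(oy - hw):(oy + hw), (ox - hw):(ox + hw)]
  patch <- patch - mean(patch)
  scores <- vapply(templates, function(tm) sum(patch * tm), numeric(1))
  which.max(scores) - 1L
}

#' Oracle (template-matching) accuracy per stratum at a given resolution
#'
#' Monte-Carlo estimate of the accuracy achievable by a classifier built
#' from the generator's own cue parameters: nearest background color for
#' the easy stratum, normalized correlation of the lesion patch against
#' the class ring templates (at the known lesion location) for the hard
#' stratum.  This quantifies the designed resolution gap — near-ceiling on
#' both strata at full resolution, near chance on the hard stratum once
#' the image is resized below the lesion scale.
#'
#' @param spec A [synth_spec()].
#' @param resolution Evaluation resolution (`<= spec$image_size`).
#' @param n_mc Monte-Carlo samples per stratum.
#' @param seed RNG seed for the Monte-Carlo draw.
#' @return Tibble with `stratum`, `resolution`, `accuracy`, `n`.
#' @export
stratum_bayes_accuracy <- function(spec, resolution, n_mc = 200L,
                                   seed = spec$seed + 1000L) {
  if (resolution > spec$image_size) {
    abort("`resolution` must be <= the generated image size.")
  }
  cues <- synth_class_cues(spec)
  templates <- hard_templates(spec, resolution)
  with_seed(seed, {
    classes <- sample(spec$n_classes, n_mc, replace = TRUE) - 1L
    easy_ok <- vapply(classes, function(k) {
      img <- render_easy(spec, cues, k)
      img <- resize_bilinear(img, resolution, resolution)
      oracle_classify_easy(img, cues) == k
    }, logical(1))
    hard_ok <- vapply(classes, function(k) {
      hs <- render_hard(spec, cues, k)
      oracle_classify_hard(hs$image, hs$cy, hs$cx, spec, resolution,
                           templates) == k
    }, logical(1))
    tibble::tibble(stratum = c("easy", "hard"),
                   resolution = as.integer(resolution),
                   accuracy = c(mean(easy_ok), mean(hard_ok)),
                   n = as.integer(n_mc))
  })
}

#' Write a synthetic dataset as a class-per-directory PNG tree
#'
#' Creates `root/class_<label>/<sample_id>.png` plus `root/manifest.csv`
#' with `path,label,stratum` columns.
#'
#' @param dataset Tibble from [generate_dataset()].
#' @param root Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_synth_dataset <- function(dataset, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    cls <- sprintf("class_%d", dataset$label[i])
    dir.create(file.path(root, cls), showWarnings = FALSE)
    paths[i] <- file.path(cls, paste0(dataset$sample_id[i], ".png"))
    png::writePNG(aperm(dataset$image[[i]], c(2, 3, 1)),
                  file.path(root, paths[i]))
  }
  # manifest paths are root-relative so the tree is relocatable
  manifest <- tibble::tibble(path = paths,
                             label = sprintf("class_%d", dataset$label),
                             stratum = dataset$stratum)
  readr::write_csv(manifest, file.path(root, "manifest.csv"))
  invisible(manifest)
}
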