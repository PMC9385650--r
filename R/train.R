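#' Augmentation pipeline configuration
#'
#' The training-time pipeline applies horizontal flips, vertical flips and
#' random cropping at the native resolution, then resizes to the stream's
#' input resolution and normalizes per channel (normalization is always
#' last).
#'
#' @param hflip_prob,vflip_prob Flip probabilities in `[0, 1]`.
#' @param crop_scale Range of the crop area as a fraction of the image
#'   (`c(1, 1)` disables cropping).
#' @param normalize Either a per-channel `list(mean, sd)` (defaults to the
#'   widely used natural-image statistics) or the string `"per-image"`,
#'   which standardizes each image to zero mean and unit variance jointly
#'   over its three channels — this preserves color contrasts while
#'   equalizing overall image contrast, so low-contrast images are not
#'   drowned out by high-contrast ones.
#' @return An `augmentation_config` object.
#' @export
augmentation_config <- function(hflip_prob = 0.5, vflip_prob = 0.5,
                                crop_scale = c(0.8, 1.0),
                                normalize = imagenet_normalize()) {
  if (hflip_prob < 0 || hflip_prob > 1 || vflip_prob < 0 || vflip_prob > 1) {
    abort("flip probabilities must lie in [0, 1].")
  }
  if (length(crop_scale) != 2 || any(crop_scale <= 0) || any(crop_scale > 1) ||
      crop_scale[1] > crop_scale[2]) {
    abort("`crop_scale` must be an increasing pair in (0, 1].")
  }
  if (is.character(normalize)) {
    if (!identical(normalize, "per-image")) {
      abort("character `normalize` must be \"per-image\".")
    }
  } else if (any(normalize$sd <= 0)) {
    abort("normalization `sd` must be > 0 per channel.")
  }
  structure(list(hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 crop_scale = crop_scale, normalize = normalize),
            class = "augmentation_config")
}

#' Default per-channel normalization statistics
#' @return `list(mean, sd)` of length-3 numeric vectors.
#' @export
imagenet_normalize <- function() {
  list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))
}

normalize_batch <- function(x, normalize) {
  if (identical(normalize, "per-image")) {
    for (n in seq_len(dim(x)[4])) {
      v <- x[, , , n]
      x[, , , n] <- (v - mean(v)) / max(stats::sd(v), 1e-3)
    }
    return(x)
  }
  for (c in 1:3) {
    x[c, , , ] <- (x[c, , , ] - normalize$mean[c]) / normalize$sd[c]
  }
  x
}

normalize_single <- function(x, normalize) {
  if (identical(normalize, "per-image")) {
    return((x - mean(x)) / max(stats::sd(x), 1e-3))
  }
  for (c in 1:3) x[c, , ] <- (x[c, , ] - normalize$mean[c]) / normalize$sd[c]
  x
}

flip_h <- function(image) image[, , dim(image)[3]:1, drop = FALSE]
flip_v <- function(image) image[, dim(image)[2]:1, , drop = FALSE]

# random flips + random crop at native resolution; consumes the global RNG
augment_geom <- function(image, cfg) {
  if (runif(1) < cfg$hflip_prob) image <- flip_h(image)
  if (runif(1) < cfg$vflip_prob) image <- flip_v(image)
  d <- dim(image)
  if (cfg$crop_scale[1] < 1 || cfg$crop_scale[2] < 1) {
    area <- runif(1, cfg$crop_scale[1], cfg$crop_scale[2])
    side <- round(sqrt(area) * min(d[2], d[3]))
    if (side < 1) abort("degenerate crop: empty region.")
    top <- sample.int(d[2] - side + 1L, 1L)
    left <- sample.int(d[3] - side + 1L, 1L)
    image <- image[, top:(top + side - 1L), left:(left + side - 1L),
                   drop = FALSE]
  }
  image
}

#' Augment one image for training
#'
#' Random flips and crop (driven by the current RNG state), then resize to
#' the target resolution and normalize.  Use a fixed seed for reproducible
#' augmentation streams.
#'
#' @param image `(3, H, W)` array with values in `[0, 1]`.
#' @param resolution Target square resolution of the consuming stream.
#' @param cfg An [augmentation_config()].
#' @return Normalized `(3, resolution, resolution)` array.
#' @export
augment_image <- function(image, resolution, cfg = augmentation_config()) {
  g <- augment_geom(image, cfg)
  normalize_single(resize_bilinear(g, resolution, resolution), cfg$normalize)
}

#' Training configuration for the two-step protocol
#'
#' Stage 1 trains each stream independently with cross-entropy under Adam;
#' stage 2 fine-tunes the large stream together with the (zero-initialized)
#' feature reuse modules, with the small stream frozen by default.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs_stage1 Epochs of independent stream training.
#' @param epochs_stage2 Epochs of FRM fine-tuning.
#' @param seed Seed controlling initialization, shuffling and augmentation.
#' @param freeze_small_in_stage2 Keep the small stream's parameters fixed
#'   during fine-tuning (preserves its routing behavior between stages).
#' @param pretrained_init Reserved flag; no pretrained weights are shipped,
#'   so enabling it raises an error.
#' @param augmentation An [augmentation_config()].
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16L,
                         epochs_stage1 = 300L, epochs_stage2 = 50L,
                         seed = 1L, freeze_small_in_stage2 = TRUE,
                         pretrained_init = FALSE,
                         augmentation = augmentation_config()) {
  if (batch_size < 1) abort("`batch_size` must be >= 1.")
  if (epochs_stage1 < 0 || epochs_stage2 < 0) abort("epoch counts must be >= 0.")
  structure(list(learning_rate = learning_rate, optimizer = "adam",
                 batch_size = as.integer(batch_size),
                 epochs_stage1 = as.integer(epochs_stage1),
                 epochs_stage2 = as.integer(epochs_stage2),
                 seed = as.integer(seed), loss = "cross-entropy",
                 freeze_small_in_stage2 = isTRUE(freeze_small_in_stage2),
                 pretrained_init = isTRUE(pretrained_init),
                 augmentation = augmentation),
            class = "train_config")
}

# ---- flat-leaf helpers for the optimizer ----

flatten_leaves <- function(x) {
  if (is.null(x)) return(list())
  if (is.list(x)) {
    out <- list()
    for (el in x) out <- c(out, flatten_leaves(el))
    out
  } else {
    list(x)
  }
}

set_leaves <- function(template, values, counter = new.env()) {
  if (is.null(counter$i)) counter$i <- 0L
  rebuild <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) {
      out <- lapply(x, rebuild)
      names(out) <- names(x)
      out
    } else {
      counter$i <- counter$i + 1L
      values[[counter$i]]
    }
  }
  rebuild(template)
}

adam_init <- function(params) {
  leaves <- flatten_leaves(params)
  list(m = lapply(leaves, function(l) l * 0),
       v = lapply(leaves, function(l) l * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  p <- flatten_leaves(params)
  g <- flatten_leaves(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(p)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g[[i]]^2
    p[[i]] <- p[[i]] - lr * (state$m[[i]] / bc1) /
      (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = set_leaves(params, p), state = state)
}

cross_entropy <- function(probs, labels0) {
  idx <- cbind(labels0 + 1L, seq_along(labels0))
  -mean(log(pmax(probs[idx], 1e-12)))
}

check_labels <- function(train_set, n_classes) {
  lab <- train_set$label
  bad <- which(is.na(lab) | lab < 0 | lab >= n_classes | lab != floor(lab))
  if (length(bad) > 0) {
    id <- if ("sample_id" %in% names(train_set)) train_set$sample_id[bad[1]]
          else as.character(bad[1])
    abort(sprintf("label out of range [0, %d) for sample '%s'.", n_classes, id))
  }
}

#' Train a single stream with cross-entropy under Adam
#'
#' Stage 1 of the two-step protocol: the stream is trained independently on
#' augmented images at its own input resolution.  All randomness
#' (initialization, shuffling, augmentation) derives from `cfg$seed`, so
#' identical calls reproduce identical parameters and histories.
#'
#' @param spec A [stream_spec()].
#' @param train_set Tibble with an `image` list-column (native-resolution
#'   `(3, H, W)` arrays in `[0, 1]`) and an integer `label` column in
#'   `[0, num_classes)`.
#' @param cfg A [train_config()]; `epochs_stage1` epochs are run.
#' @return A `stream_fit`: list with `stream` (the trained `conv_stream`)
#'   and `history` (tibble of epoch, loss, accuracy on the training data).
#' @export
train_stream <- function(spec, train_set, cfg = train_config()) {
  if (!is.data.frame(train_set) || nrow(train_set) == 0) {
    abort("`train_set` must be a non-empty tibble with image and label columns.")
  }
  if (cfg$pretrained_init) {
    abort("`pretrained_init` is reserved: no pretrained weights are shipped.")
  }
  check_labels(train_set, spec$num_classes)
  stream <- build_stream(spec, cfg$seed)
  if (cfg$epochs_stage1 == 0L) {
    return(structure(list(stream = stream,
                          history = tibble::tibble(epoch = integer(),
                                                   loss = numeric(),
                                                   accuracy = numeric())),
                     class = "stream_fit"))
  }
  res <- with_seed(cfg$seed + 1L,
                   sgd_loop(stream, train_set, cfg, cfg$epochs_stage1))
  structure(res, class = "stream_fit")
}

sgd_loop <- function(stream, train_set, cfg, epochs) {
  n <- nrow(train_set)
  state <- adam_init(stream$params)
  history <- vector("list", epochs)
  res <- stream$spec$input_resolution
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    losses <- c(); correct <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      x <- as_batch(lapply(train_set$image[idx], augment_image,
                           resolution = res, cfg = cfg$augmentation))
      y <- train_set$label[idx]
      out <- forward_with_taps(stream, x, keep_cache = TRUE,
                               training = TRUE)
      stream$stats <- out$stats
      probs <- out$probabilities
      losses <- c(losses, cross_entropy(probs, y))
      correct <- correct + sum(argmax0(probs) == y)
      dlogits <- probs
      dlogits[cbind(y + 1L, seq_along(y))] <-
        dlogits[cbind(y + 1L, seq_along(y))] - 1
      dlogits <- dlogits / length(y)
      bw <- stream_backward(stream, out$cache, dlogits)
      upd <- adam_step(stream$params, bw$grads, state, cfg$learning_rate)
      stream$params <- upd$params
      state <- upd$state
    }
    history[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses),
                                    accuracy = correct / n)
  }
  list(stream = stream, history = dplyr::bind_rows(history))
}

as_stream <- function(x) {
  if (inherits(x, "stream_fit")) x$stream
  else if (inherits(x, "conv_stream")) x
  else abort("expected a conv_stream or stream_fit.")
}

#' Fine-tune the large stream with feature reuse modules attached
#'
#' Stage 2 of the two-step protocol.  The feature reuse 1x1 weights start
#' at zero, so the fused large stream begins exactly at the pretrained
#' large stream's behavior; gradients then move the large stream and the
#' FRM weights jointly.  With `freeze_small_in_stage2` (the default) the
#' small stream's parameters are bit-identical before and after.
#'
#' @param small,large Trained streams (`stream_fit` or `conv_stream`).
#' @param train_set As in [train_stream()], at native resolution.
#' @param cfg A [train_config()]; `epochs_stage2` epochs are run.
#' @param frm_links Optional initial links; defaults to zero-initialized
#'   [init_frm_links()].
#' @param router Router configuration stored in the returned model.
#' @return A [cascade_model()] with a `history` attribute (fine-tuning
#'   loss/accuracy per epoch).
#' @export
finetune_frm <- function(small, large, train_set, cfg = train_config(),
                         frm_links = NULL, router = router_config()) {
  small <- as_stream(small)
  large <- as_stream(large)
  if (length(small$spec$stages) != length(large$spec$stages)) {
    abort(sprintf("stage counts differ: small has %d, large has %d.",
                  length(small$spec$stages), length(large$spec$stages)))
  }
  check_labels(train_set, large$spec$num_classes)
  if (is.null(frm_links)) frm_links <- init_frm_links(small$spec, large$spec)
  norm <- cfg$augmentation$normalize
  history <- tibble::tibble(epoch = integer(), loss = numeric(),
                            accuracy = numeric())
  if (cfg$epochs_stage2 > 0L) {
    res <- with_seed(cfg$seed + 2L,
                     frm_loop(small, large, frm_links, train_set, cfg))
    large <- res$large
    small <- res$small
    frm_links <- res$frm_links
    history <- res$history
  }
  model <- cascade_model(small, large, frm_links, router, normalize = norm)
  attr(model, "history") <- history
  model
}

frm_loop <- function(small, large, frm_links, train_set, cfg) {
  n <- nrow(train_set)
  res_s <- small$spec$input_resolution
  res_l <- large$spec$input_resolution
  small_res_taps <- stage_resolutions(small$spec)
  norm <- cfg$augmentation$normalize
  frm_par <- lapply(frm_links, function(lk) list(w = lk$weight, b = lk$bias))
  state_large <- adam_init(large$params)
  state_frm <- adam_init(frm_par)
  state_small <- if (!cfg$freeze_small_in_stage2) adam_init(small$params)
  history <- vector("list", cfg$epochs_stage2)
  for (ep in seq_len(cfg$epochs_stage2)) {
    perm <- sample.int(n)
    losses <- c(); correct <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      geoms <- lapply(train_set$image[idx], augment_geom,
                      cfg = cfg$augmentation)
      xs <- as_batch(lapply(geoms, function(g) {
        normalize_single(resize_bilinear(g, res_s, res_s), norm)
      }))
      xl <- as_batch(lapply(geoms, function(g) {
        normalize_single(resize_bilinear(g, res_l, res_l), norm)
      }))
      y <- train_set$label[idx]
      keep_small <- !cfg$freeze_small_in_stage2
      s_out <- forward_with_taps(small, xs, keep_cache = keep_small,
                                 training = keep_small)
      if (keep_small) small$stats <- s_out$stats
      ups <- purrr::map2(s_out$taps, frm_links, function(tp, lk) {
        upsample_bilinear(tp, lk$target_height, lk$target_width)
      })
      fuse <- purrr::map2(ups, frm_par, function(u, fp) {
        d <- dim(u)
        y2 <- fp$w %*% matrix(u, nrow = d[1]) + fp$b
        array(y2, c(nrow(fp$w), d[-1]))
      })
      l_out <- forward_with_taps(large, xl, keep_cache = TRUE, fuse = fuse,
                                 training = TRUE)
      large$stats <- l_out$stats
      probs <- l_out$probabilities
      losses <- c(losses, cross_entropy(probs, y))
      correct <- correct + sum(argmax0(probs) == y)
      dlogits <- probs
      dlogits[cbind(y + 1L, seq_along(y))] <-
        dlogits[cbind(y + 1L, seq_along(y))] - 1
      dlogits <- dlogits / length(y)
      bw <- stream_backward(large, l_out$cache, dlogits,
                            want_tap_grads = TRUE)
      frm_grads <- vector("list", length(frm_par))
      small_tap_grads <- if (keep_small) vector("list", length(frm_par))
      for (i in seq_along(frm_par)) {
        gb <- bw$tap_grads[[i]]
        dg <- dim(gb)
        gmat <- matrix(gb, nrow = dg[1])
        umat <- matrix(ups[[i]], nrow = dim(ups[[i]])[1])
        frm_grads[[i]] <- list(w = gmat %*% t(umat), b = rowSums(gmat))
        if (keep_small) {
          du <- t(frm_par[[i]]$w) %*% gmat
          dim(du) <- c(ncol(frm_par[[i]]$w), dg[2], dg[3], dg[4])
          small_tap_grads[[i]] <- resize_bilinear_bwd(
            du, small_res_taps[i], small_res_taps[i])
        }
      }
      upd_l <- adam_step(large$params, bw$grads, state_large,
                         cfg$learning_rate)
      large$params <- upd_l$params; state_large <- upd_l$state
      upd_f <- adam_step(frm_par, frm_grads, state_frm, cfg$learning_rate)
      frm_par <- upd_f$params; state_frm <- upd_f$state
      if (keep_small) {
        zero_logits <- matrix(0, small$spec$num_classes, length(y))
        bws <- stream_backward(small, s_out$cache, zero_logits,
                               tap_grads_in = small_tap_grads)
        upd_s <- adam_step(small$params, bws$grads, state_small,
                           cfg$learning_rate)
        small$params <- upd_s$params; state_small <- upd_s$state
      }
    }
    history[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses),
                                    accuracy = correct / n)
  }
  frm_links <- purrr::map2(frm_links, frm_par, function(lk, fp) {
    frm_params(lk$block_index, fp$w, fp$b, lk$target_height, lk$target_width)
  })
  list(small = small, large = large, frm_links = frm_links,
       history = dplyr::bind_rows(history))
}

#' Desk-scale and paper-scale run profiles
#'
#' `desk_profile()` is the configuration the package's own tests exercise:
#' the tiny 24/96-pixel stream pair, short training (60 + 10 epochs at
#' learning rate 1e-3), and a 21-point threshold grid.  `paper_profile()`
#' mirrors the full published protocol (18- and 34-layer streams at
#' 224/336 pixels, 300 + 50 epochs, learning rate 1e-4, batch 16,
#' tau = 0.8) for users with a real dataset and the compute to match.
#'
#' @param num_classes Number of classes for the stream heads.
#' @return List with `small_spec`, `large_spec`, `train` (a
#'   [train_config()]), `router` and `tau_grid`.
#' @export
desk_profile <- function(num_classes = 8L) {
  refs <- reference_specs()
  small <- refs$tiny_small; small$num_classes <- as.integer(num_classes)
  large <- refs$tiny_large; large$num_classes <- as.integer(num_classes)
  list(small_spec = small, large_spec = large,
       train = train_config(learning_rate = 1e-3, batch_size = 16L,
                            epochs_stage1 = 60L, epochs_stage2 = 10L,
                            augmentation = augmentation_config(
                              crop_scale = c(1, 1),
                              normalize = "per-image")),
       router = router_config(0.8),
       tau_grid = seq(0, 1, by = 0.05))
}

#' @rdname desk_profile
#' @export
paper_profile <- function(num_classes = 8L) {
  refs <- reference_specs()
  small <- refs$resnet18; small$num_classes <- as.integer(num_classes)
  large <- refs$resnet34; large$num_classes <- as.integer(num_classes)
  list(small_spec = small, large_spec = large,
       train = train_config(learning_rate = 1e-4, batch_size = 16L,
                            epochs_stage1 = 300L, epochs_stage2 = 50L),
       router = router_config(0.8),
       tau_grid = seq(0, 1, by = 0.05))
}
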