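#' Load a labeled image dataset from a directory tree or CSV manifest
#'
#' A directory is read as class-per-subdirectory layout; a `.csv` path as a
#' manifest with header `path,label[,split][,stratum]` (relative paths are
#' resolved against the manifest's directory).  Rows are ordered
#' lexicographically by path and labels are encoded as a contiguous
#' 0-based index set, alphabetical by class name (C-locale radix order, so
#' mixed-case class names encode stably across platforms).
#'
#' @param path Dataset root directory or manifest CSV.
#' @return A manifest tibble: `path`, `class`, `label` (0-based integer),
#'   plus `split`/`stratum` when present in the manifest.
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) abort(sprintf("path '%s' does not exist.", path))
  if (dir.exists(path)) {
    classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE),
                    method = "radix")
    if (length(classes) == 0) abort("no class subdirectories found.")
    rows <- lapply(classes, function(cl) {
      files <- sort(list.files(file.path(path, cl),
                               pattern = "\\.(png|jpg|jpeg)$",
                               ignore.case = TRUE, full.names = TRUE),
                    method = "radix")
      tibble::tibble(path = files, class = cl)
    })
    man <- dplyr::bind_rows(rows)
  } else {
    raw <- readr::read_csv(path, show_col_types = FALSE)
    if (!all(c("path", "label") %in% names(raw))) {
      abort("manifest must have `path` and `label` columns.")
    }
    rel <- file.path(dirname(path), raw$path)
    man <- tibble::tibble(path = ifelse(file.exists(raw$path), raw$path, rel),
                          class = as.character(raw$label))
    if ("split" %in% names(raw)) man$split <- raw$split
    if ("stratum" %in% names(raw)) man$stratum <- raw$stratum
  }
  man <- man[order(man$path, method = "radix"), ]
  missing <- man$path[!file.exists(man$path)]
  if (length(missing) > 0) {
    abort(c("unreadable image paths; run aborted:",
            utils::head(missing, 10)))
  }
  levels <- sort(unique(man$class), method = "radix")
  man$label <- match(man$class, levels) - 1L
  man <- man[, c("path", "class", "label",
                 intersect(c("split", "stratum"), names(man)))]
  tibble::as_tibble(man)
}

#' Read one image file as a (3, H, W) array with values in `[0, 1]`
#'
#' PNG is read natively; JPEG requires the EBImage package.
#'
#' @param path Image file.
#' @return `(3, H, W)` numeric array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      abort("reading JPEG requires the EBImage package.")
    }
    a <- aperm(EBImage::imageData(EBImage::readImage(path)), c(2, 1, 3))
  } else {
    abort(sprintf("unsupported image format '%s'.", ext))
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  aperm(a, c(3, 1, 2))
}

#' Decode all images referenced by a manifest
#'
#' Adds an `image` list-column; decoding failures are collected and
#' reported together before aborting.
#'
#' @param manifest Tibble from [load_dataset()].
#' @return The manifest with an `image` list-column and a `sample_id`
#'   column (the file base name).
#' @export
load_images <- function(manifest) {
  imgs <- vector("list", nrow(manifest))
  bad <- character(0)
  for (i in seq_len(nrow(manifest))) {
    imgs[[i]] <- tryCatch(read_image(manifest$path[i]), error = function(e) {
      bad <<- c(bad, manifest$path[i])
      NULL
    })
  }
  if (length(bad) > 0) {
    abort(c("unreadable images; run aborted:", utils::head(bad, 10)))
  }
  manifest$image <- imgs
  manifest$sample_id <- tools::file_path_sans_ext(basename(manifest$path))
  manifest
}

#' Stratified train/test split
#'
#' Splits each class independently so per-class train proportions stay
#' within rounding of `train_fraction`; the two parts are disjoint and
#' exhaustive.
#'
#' @param manifest Tibble with a `label` column.
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed RNG seed (the caller's RNG state is untouched).
#' @return List with `train` and `test` tibbles.
#' @export
stratified_split <- function(manifest, train_fraction = 0.7, seed = 1L) {
  counts <- table(manifest$label)
  singles <- names(counts)[counts < 2]
  if (length(singles) > 0) {
    abort(sprintf("class(es) with fewer than 2 samples: %s.",
                  paste(singles, collapse = ", ")))
  }
  idx_train <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(manifest)), manifest$label),
                  function(ix) {
                    n_tr <- round(train_fraction * length(ix))
                    sample(ix, n_tr)
                  }), use.names = FALSE)
  })
  list(train = manifest[sort(idx_train), ],
       test = manifest[setdiff(seq_len(nrow(manifest)), idx_train), ])
}

#' Read a YAML run configuration
#'
#' Understands preset names (`"desk"` / `"paper"`) or inline stream specs,
#' a router threshold, training fields and a seed; unspecified fields fall
#' back to the preset defaults.
#'
#' @param path YAML file.
#' @return List with `small_spec`, `large_spec`, `train`, `router`,
#'   `tau_grid` and `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  preset <- cfg$preset %||% "desk"
  if (!preset %in% c("desk", "paper")) {
    abort(sprintf("unknown preset '%s' (use 'desk' or 'paper').", preset))
  }
  prof <- if (preset == "desk") desk_profile(cfg$num_classes %||% 8L)
          else paper_profile(cfg$num_classes %||% 8L)
  tr <- prof$train
  for (f in c("learning_rate", "batch_size", "epochs_stage1",
              "epochs_stage2", "seed")) {
    if (!is.null(cfg[[f]])) tr[[f]] <- cfg[[f]]
  }
  if (!is.null(cfg$tau)) prof$router <- router_config(cfg$tau)
  prof$train <- tr
  prof$seed <- cfg$seed %||% tr$seed
  prof
}
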