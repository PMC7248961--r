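#' Load a class-per-subdirectory image tree
#'
#' Reads a directory whose immediate subdirectories are the classes
#' (assigned 0-based ids in alphabetical order) and whose files are PNG or
#' TIFF rasters. Images are converted to the requested channel count and
#' intensities scaled to [0, 1]; unreadable files are skipped with a
#' warning and counted. When no predefined split exists a seeded stratified
#' train/test split with the given ratio is applied.
#'
#' @param root path to the dataset root.
#' @param channels 1 (grayscale, default) or 3 (RGB).
#' @param resize optional (H, W) to standardize image sizes at load time.
#' @param train_fraction stratified train share (default 0.8, i.e. the 4:1
#'   train:test ratio of a 2048:512 design).
#' @param seed split seed.
#' @return a `labeled_dataset` (see [generate_dataset()]) with an extra
#'   `n_skipped` element counting unreadable files.
#' @export
load_dataset <- function(root, channels = 1L, resize = NULL,
                         train_fraction = 0.8, seed = 1L) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) < 2) stop("need at least 2 class subdirectories")
  images <- list(); labels <- integer(0); skipped <- 0L
  for (ci in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[ci]), full.names = TRUE,
                             pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE))
    loaded <- 0L
    for (f in files) {
      img <- tryCatch(read_image(f), error = function(e) NULL)
      if (is.null(img)) {
        warning("skipping unreadable image: ", f, call. = FALSE)
        skipped <- skipped + 1L
        next
      }
      if (channels == 1L) img <- to_gray(img)
      if (channels == 3L && raster_dim(img)$c == 1) {
        img <- array(rep(img, 3), c(dim(img), 3))
      }
      if (!is.null(resize)) img <- resize_raster(img, resize[1], resize[2])
      images[[length(images) + 1]] <- img
      loaded <- loaded + 1L
      labels <- c(labels, ci - 1L)
    }
    if (loaded == 0L) stop("class '", classes[ci], "' has no decodable image")
  }
  split <- with_seed(seed, {
    train <- integer(0)
    for (ci in seq_along(classes) - 1L) {
      idx <- which(labels == ci)
      n_tr <- max(1L, round(length(idx) * train_fraction))
      train <- c(train, sample(idx, n_tr))
    }
    list(train = sort(train),
         test = sort(setdiff(seq_along(labels), train)))
  })
  structure(list(images = images, labels = labels, class_names = classes,
                 split = split,
                 canvas_size = if (length(images)) nrow(images[[1]]) else NA_integer_,
                 seed = as.integer(seed), n_skipped = skipped),
            class = "labeled_dataset")
}

#' Read a single raster image (PNG or TIFF)
#'
#' @param path image path; format chosen by extension.
#' @return an image raster in [0, 1] (alpha channels are dropped).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               tif = ,
               tiff = tiff::readTIFF(path),
               stop("unsupported image format: .", ext, " (PNG/TIFF supported)"))
  if (length(dim(px)) == 3 && dim(px)[3] %in% c(2L, 4L)) {
    px <- px[, , seq_len(dim(px)[3] - 1L), drop = FALSE]  # drop alpha
  }
  if (length(dim(px)) == 3 && dim(px)[3] == 2L) px <- px[, , 1]
  as_raster(clamp01(px))
}

#' Write a single raster image (PNG or TIFF)
#'
#' @param img image raster.
#' @param path destination; format chosen by extension.
#' @export
write_image <- function(img, path) {
  img <- as_raster(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Write a labeled dataset as a class-per-subdirectory PNG tree
#'
#' Layout consumed by [load_dataset()]: one subdirectory per class, files
#' named train_0001.png / test_0001.png according to the split.
#'
#' @param dataset a `labeled_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  for (ci in seq_along(dataset$class_names)) {
    cdir <- file.path(dir, sprintf("%02d_%s", ci - 1,
                                   gsub("[^a-z0-9-]", "_",
                                        dataset$class_names[ci])))
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    for (role in c("train", "test")) {
      idx <- intersect(dataset$split[[role]], which(dataset$labels == ci - 1L))
      for (j in seq_along(idx)) {
        write_image(dataset$images[[idx[j]]],
                    file.path(cdir, sprintf("%s_%04d.png", role, j)))
      }
    }
  }
  invisible(dir)
}

#' Default run configuration
#'
#' A fully serializable description of one comparison run: either a dataset
#' directory or a synthetic-data request, the polar-transform parameters,
#' the backbone and SVM settings, the methods and seeds to run.
#'
#' @param data path to a class-per-subdirectory tree, or NULL to synthesize.
#' @param synth list(n_train, n_test, canvas, pose, seed) for the generator.
#' @param transform,backbone,svm parameter lists overriding the defaults of
#'   [transform_spec()], [backbone_config()] and [svm_config()].
#' @param methods methods to run.
#' @param seeds run seeds.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(data = NULL,
                       synth = list(n_train = 16L, n_test = 8L, canvas = 32L,
                                    pose = "random-rotation", seed = 1L),
                       transform = list(), backbone = list(), svm = list(),
                       methods = c("I", "II", "III", "IIII"),
                       seeds = 1L, out_dir = "polarfuse_run") {
  structure(list(data = data, synth = synth, transform = transform,
                 backbone = backbone, svm = svm, methods = methods,
                 seeds = as.integer(seeds), out_dir = out_dir),
            class = "run_config")
}

build_from_config <- function(cfg) {
  to_cfg <- function(f, over) do.call(f, over)
  list(transform = to_cfg(transform_spec, cfg$transform),
       backbone = to_cfg(backbone_config, cfg$backbone),
       svm = to_cfg(svm_config, cfg$svm))
}

#' Run the full pipeline from a configuration
#'
#' Synthesize or load the dataset, train the per-view extractors, splice
#' features, fit the SVMs, evaluate the requested methods over the
#' requested seeds, and write to `out_dir`: `reports.csv` (per-method,
#' per-class precision/recall and accuracy; deterministic given the
#' config), `summary.csv` (mean/sd accuracy and ranking), `timing.csv`
#' (informational, hardware-dependent) and `config.yaml` (verbatim copy of
#' the run configuration for provenance).
#'
#' @param cfg a [run_config()] or the path of a YAML file holding one.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- do.call(run_config, yaml::read_yaml(cfg))
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dataset <- stage("data", {
    if (!is.null(cfg$data)) {
      load_dataset(cfg$data, seed = cfg$synth$seed %||% 1L)
    } else {
      generate_dataset(n_train_per_class = cfg$synth$n_train,
                       n_test_per_class = cfg$synth$n_test,
                       canvas_size = cfg$synth$canvas,
                       pose_policy = cfg$synth$pose,
                       seed = cfg$synth$seed)
    }
  })
  parts <- stage("config", build_from_config(cfg))
  res <- stage("evaluate", compare_all(dataset, cfg$methods, parts$backbone,
                                       parts$svm, parts$transform, cfg$seeds))
  stage("report", {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(reports_to_frame(res$reports),
                     file.path(cfg$out_dir, "reports.csv"), row.names = FALSE)
    utils::write.csv(res$summary, file.path(cfg$out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(reports_to_frame(res$reports, include_timing = TRUE),
                     file.path(cfg$out_dir, "timing.csv"), row.names = FALSE)
    yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir, "config.yaml"))
  })
  invisible(cfg$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
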