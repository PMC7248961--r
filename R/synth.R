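#' Synthetic plankton-like silhouette images
#'
#' Seven shape families emulate the single-organism ROI crops an in situ
#' plankton imager produces: an elongated curved filament (arrow-worm-like),
#' a lobed blob (copepod-like), a finned ellipse (fish-larva-like), a radial
#' bell with trailing tentacles (jellyfish-like), a segmented rod
#' (krill-like), a logarithmic spiral (pteropod-like), and unstructured
#' speckle noise (the negative class). Objects are rendered as bright
#' silhouettes on a dim noisy background with a low-frequency gradient
#' (turbid-water vignetting) and always fit inside the inscribed circle of
#' the canvas so rotation never clips them.
#'
#' @name synthetic-data
NULL

# run code under a temporary RNG state seeded with `seed`
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

#' Shape family specifications
#'
#' @param families character vector of family names; the default seven
#'   cover the six organism-like classes plus the speckle negative class.
#' @return list of `shape_class_spec` objects (family, size range as a
#'   fraction of the inscribed radius, shape parameter ranges, foreground
#'   intensity range).
#' @export
default_shape_specs <- function(families = c("elongated-curve", "lobed-blob",
                                             "finned-ellipse", "radial-bell",
                                             "segmented-rod", "spiral",
                                             "speckle-noise")) {
  known <- c("elongated-curve", "lobed-blob", "finned-ellipse", "radial-bell",
             "segmented-rod", "spiral", "speckle-noise")
  bad <- setdiff(families, known)
  if (length(bad)) stop("unknown shape family: ", paste(bad, collapse = ", "))
  lapply(families, function(f) {
    structure(list(family = f,
                   size = c(0.55, 0.65),      # max extent / inscribed radius
                   shape_jitter = 0.2,        # relative param jitter
                   intensity = c(0.65, 0.95)),
              class = "shape_class_spec")
  })
}

# distance from each canvas point to a polyline, vectorized over points
dist_to_curve <- function(px, py, cx, cy) {
  d2 <- matrix(Inf, length(px), 1)
  for (i in seq_along(cx)) {
    d2 <- pmin(d2, (px - cx[i])^2 + (py - cy[i])^2)
  }
  sqrt(d2)
}

soft_in <- function(signed, edge = 0.04) {
  # signed < 0 inside; smooth 1 -> 0 over `edge`
  pmin(pmax(-signed / edge + 0.5, 0), 1)
}

# Render one canonical (unrotated, centered) silhouette on a size x size
# canvas; coordinates are normalized so the inscribed circle has radius 1.
# Consumes RNG for per-sample shape variation. Returns intensities in [0,1].
render_family <- function(family, size, spec) {
  g <- coord_grid(size, size)
  half <- (size - 1) / 2
  x <- (as.vector(g$x) - half) / (size / 2)
  y <- (as.vector(g$y) - half) / (size / 2)
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  ext <- stats::runif(1, spec$size[1], spec$size[2])   # max extent
  jit <- function(v) v * (1 + stats::runif(1, -spec$shape_jitter,
                                           spec$shape_jitter))
  mask <- switch(
    family,
    "elongated-curve" = {
      amp <- jit(0.25); thick <- jit(0.07)
      t <- seq(-1, 1, length.out = 80)
      cx <- t * ext
      cy <- amp * sin(pi * t) * ext
      soft_in(dist_to_curve(x, y, cx, cy) - thick)
    },
    "lobed-blob" = {
      k <- sample(2:3, 1); amp <- jit(0.3); r0 <- ext / (1 + amp) * 0.9
      rad <- r0 * (1 + amp * cos(k * th))
      soft_in(r - rad)
    },
    "finned-ellipse" = {
      a <- ext * 0.85; b <- jit(0.22) * ext
      body <- soft_in(sqrt((x / a)^2 + (y / b)^2) - 1, edge = 0.1)
      # triangular tail fin at the -x end
      fin <- soft_in(pmax(-(x + ext) , abs(y) - 0.5 * (x + ext),
                          x + ext * 0.55), edge = 0.05)
      pmax(body, fin)
    },
    "radial-bell" = {
      rb <- ext * 0.75; scal <- jit(0.08)
      bell <- soft_in(pmax(r - rb * (1 + scal * cos(6 * th)), y), edge = 0.06)
      nt <- sample(3:5, 1)
      tx <- seq(-0.6, 0.6, length.out = nt) * rb
      tent <- rep(0, length(x))
      for (j in seq_len(nt)) {
        t <- seq(0, 1, length.out = 30)
        cx <- tx[j] + 0.1 * ext * sin(3 * t + j)
        cy <- t * ext * 0.85
        tent <- pmax(tent, soft_in(dist_to_curve(x, y, cx, cy) - 0.035))
      }
      pmax(bell, tent)
    },
    "segmented-rod" = {
      len <- ext; wid <- jit(0.12); freq <- sample(4:6, 1)
      bend <- jit(0.1)
      yy <- y - bend * (x / len)^2
      inside <- soft_in(pmax(abs(x) - len, abs(yy) - wid), edge = 0.05)
      bands <- 0.75 + 0.25 * cos(freq * pi * x / len)
      inside * bands
    },
    "spiral" = {
      turns <- jit(2.2); b <- 0.22
      t <- seq(0, turns * 2 * pi, length.out = 120)
      rr <- 0.08 * exp(b * t)
      rr <- rr / max(rr) * ext
      cx <- rr * cos(t); cy <- rr * sin(t)
      soft_in(dist_to_curve(x, y, cx, cy) - jit(0.06))
    },
    "speckle-noise" = {
      n <- sample(6:12, 1)
      m <- rep(0, length(x))
      for (j in seq_len(n)) {
        ang <- stats::runif(1, 0, 2 * pi); rad <- stats::runif(1, 0, ext)
        cx <- rad * cos(ang); cy <- rad * sin(ang)
        rr <- stats::runif(1, 0.03, 0.1)
        m <- pmax(m, soft_in(sqrt((x - cx)^2 + (y - cy)^2) - rr))
      }
      m
    },
    stop("unknown shape family: ", family)
  )
  lvl <- stats::runif(1, spec$intensity[1], spec$intensity[2])
  out <- mask * lvl
  dim(out) <- c(size, size)
  out
}

# translate by (dx, dy) pixels using the shared sampler
translate_raster <- function(img, dx, dy, interpolation = "bilinear",
                             fill = 0) {
  d <- raster_dim(img)
  g <- coord_grid(d$h, d$w)
  out <- sample_raster(img, as.vector(g$x) - dx, as.vector(g$y) - dy,
                       c(d$h, d$w), interpolation, fill)
  clamp01(out)
}

# noisy turbid-water background; consumes RNG
render_background <- function(size, noise_sd = 0.05, gradient_amp = 0.12) {
  g <- coord_grid(size, size)
  ang <- stats::runif(1, 0, 2 * pi)
  lvl <- stats::runif(1, 0.05, 0.15)
  grad <- gradient_amp *
    (0.5 + 0.5 * sin(2 * pi * (cos(ang) * g$x + sin(ang) * g$y) / (2 * size)))
  noise <- matrix(stats::rnorm(size * size, 0, noise_sd), size, size)
  clamp01(lvl + grad + noise)
}

#' Render one posed synthetic object
#'
#' Draws a canonical silhouette for `family`, applies the pose (scale, then
#' rotation through the package's shared rotation operator, then
#' translation) and composites it over a noisy background. RNG state drives
#' the per-sample shape variation, so wrap calls in a seeded context for
#' reproducibility.
#'
#' @param family one of the seven family names of [default_shape_specs()].
#' @param canvas_size square canvas side in pixels (>= 16).
#' @param rotation_deg pose rotation in degrees.
#' @param translate (dx, dy) pixel offsets.
#' @param scale_factor isotropic pose scale.
#' @param spec a `shape_class_spec`; default from [default_shape_specs()].
#' @param background include the noisy background (TRUE) or render the bare
#'   silhouette (FALSE).
#' @return a canvas_size x canvas_size grayscale raster.
#' @export
render_shape <- function(family, canvas_size = 32L, rotation_deg = 0,
                         translate = c(0, 0), scale_factor = 1,
                         spec = NULL, background = TRUE) {
  if (canvas_size < 16) stop("canvas_size must be >= 16")
  if (is.null(spec)) spec <- default_shape_specs(family)[[1]]
  img <- render_family(family, as.integer(canvas_size), spec)
  if (scale_factor != 1) img <- scale_raster(img, scale_factor)
  if (rotation_deg != 0) img <- rotate_raster(img, rotation_deg)
  if (any(translate != 0)) img <- translate_raster(img, translate[1],
                                                   translate[2])
  if (background) {
    bg <- render_background(as.integer(canvas_size))
    img <- pmax(img, bg)
  }
  clamp01(img)
}

#' Generate a labeled synthetic dataset
#'
#' Deterministic given `seed`. Pose policies: "fixed" renders every object
#' in its canonical orientation; "random-rotation" draws the angle uniformly
#' on [0, 360); "random-rotation+jitter" additionally draws a translation
#' bounded by 10% of the canvas per axis and a scale in [0.8, 1.2].
#'
#' @param spec list of shape class specs (default: the seven families).
#' @param n_train_per_class,n_test_per_class samples per class (>= 1; >= 0
#'   for test).
#' @param canvas_size square canvas side (>= 16).
#' @param pose_policy "fixed", "random-rotation" or
#'   "random-rotation+jitter".
#' @param seed integer seed.
#' @return a `labeled_dataset`: list(images, labels (0-based integers),
#'   class_names, split = list(train, test), canvas_size, seed). Train and
#'   test index sets are disjoint, cover all samples, and are balanced per
#'   class.
#' @export
generate_dataset <- function(spec = default_shape_specs(),
                             n_train_per_class = 64L,
                             n_test_per_class = 16L,
                             canvas_size = 32L,
                             pose_policy = c("random-rotation", "fixed",
                                             "random-rotation+jitter"),
                             seed = 1L) {
  pose_policy <- match.arg(pose_policy)
  stopifnot(n_train_per_class >= 1, n_test_per_class >= 0, canvas_size >= 16)
  n_cls <- length(spec)
  per_cls <- n_train_per_class + n_test_per_class
  images <- vector("list", n_cls * per_cls)
  labels <- integer(n_cls * per_cls)
  with_seed(seed, {
    i <- 0L
    for (ci in seq_len(n_cls)) {
      s <- spec[[ci]]
      for (k in seq_len(per_cls)) {
        ang <- 0; tr <- c(0, 0); sc <- 1
        if (pose_policy != "fixed") ang <- stats::runif(1, 0, 360)
        if (pose_policy == "random-rotation+jitter") {
          tr <- stats::runif(2, -0.1, 0.1) * canvas_size
          sc <- stats::runif(1, 0.8, 1.2)
        }
        i <- i + 1L
        images[[i]] <- render_shape(s$family, canvas_size, ang, tr, sc,
                                    spec = s)
        labels[i] <- ci - 1L
      }
    }
  })
  idx <- matrix(seq_len(n_cls * per_cls), nrow = per_cls)  # column per class
  train <- as.integer(idx[seq_len(n_train_per_class), , drop = FALSE])
  test <- if (n_test_per_class > 0) {
    as.integer(idx[n_train_per_class + seq_len(n_test_per_class), ,
                   drop = FALSE])
  } else integer(0)
  structure(list(images = images, labels = labels,
                 class_names = vapply(spec, function(s) s$family, character(1)),
                 split = list(train = sort(train), test = sort(test)),
                 canvas_size = as.integer(canvas_size), seed = as.integer(seed)),
            class = "labeled_dataset")
}

#' Subset a labeled dataset to its train or test split
#'
#' @param dataset a `labeled_dataset`.
#' @param which "train" or "test".
#' @return a `labeled_dataset` whose train split holds all retained samples.
#' @export
dataset_split <- function(dataset, which = c("train", "test")) {
  which <- match.arg(which)
  keep <- dataset$split[[which]]
  structure(list(images = dataset$images[keep],
                 labels = dataset$labels[keep],
                 class_names = dataset$class_names,
                 split = list(train = seq_along(keep), test = integer(0)),
                 canvas_size = dataset$canvas_size, seed = dataset$seed),
            class = "labeled_dataset")
}

#' Rotation + flip augmentation
#'
#' Each source image yields exactly 14 images: the 12 rotations at 30-degree
#' steps (0, 30, ..., 330; the 0-degree member is the unmodified source)
#' plus the up-down and left-right flips of the source. Rotations use the
#' same rotation operator as the equivariance machinery ([rotate_raster()],
#' bilinear, background fill 0). Labels are inherited and ordering is
#' deterministic: for source i the outputs occupy positions
#' (i-1)*14 + 1 .. i*14.
#'
#' @param dataset a `labeled_dataset`.
#' @return a `labeled_dataset` 14 times the size.
#' @export
augment <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- length(dataset$images)
  images <- vector("list", 14L * n)
  labels <- integer(14L * n)
  for (i in seq_len(n)) {
    img <- dataset$images[[i]]
    base <- (i - 1L) * 14L
    images[[base + 1L]] <- img
    for (j in 1:11) {
      images[[base + 1L + j]] <- rotate_raster(img, 30 * j)
    }
    images[[base + 13L]] <- flip_raster(img, "ud")
    images[[base + 14L]] <- flip_raster(img, "lr")
    labels[base + 1:14] <- dataset$labels[i]
  }
  expand <- function(idx) as.integer(outer(1:14, (idx - 1L) * 14L, "+"))
  structure(list(images = images, labels = labels,
                 class_names = dataset$class_names,
                 split = list(train = sort(expand(dataset$split$train)),
                              test = sort(expand(dataset$split$test))),
                 canvas_size = dataset$canvas_size, seed = dataset$seed),
            class = "labeled_dataset")
}
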