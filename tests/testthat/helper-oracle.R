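# Independent per-pixel brute-force polar resampler. Evaluates the inverse
# mapping rho*(cos theta, sin theta) + center scalar-by-scalar with its own
# interpolation code; shares nothing with the package's vectorized path.

oracle_sample_px <- function(img, x, y, interpolation, fill) {
  h <- nrow(img); w <- ncol(img)
  if (interpolation == "nearest") {
    xi <- floor(x + 0.5); yi <- floor(y + 0.5)
    if (xi < 0 || xi > w - 1 || yi < 0 || yi > h - 1) return(fill)
    return(img[yi + 1, xi + 1])
  }
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  at <- function(xx, yy) {
    if (xx < 0 || xx > w - 1 || yy < 0 || yy > h - 1) fill
    else img[yy + 1, xx + 1]
  }
  (at(x0, y0) * (1 - fx) + at(x0 + 1, y0) * fx) * (1 - fy) +
    (at(x0, y0 + 1) * (1 - fx) + at(x0 + 1, y0 + 1) * fx) * fy
}

oracle_polar <- function(img, grid, interpolation = "bilinear") {
  radii <- if (is.null(grid$log_base)) {
    seq(0, grid$r_max, length.out = grid$n_rho)
  } else {
    exp(seq(log(grid$r_min), log(grid$r_max), length.out = grid$n_rho))
  }
  out <- matrix(0, grid$n_rho, grid$n_theta)
  for (i in seq_len(grid$n_rho)) {
    for (k in seq_len(grid$n_theta)) {
      th <- (k - 1) * 2 * pi / grid$n_theta
      x <- grid$center[1] + radii[i] * cos(th)
      y <- grid$center[2] + radii[i] * sin(th)
      out[i, k] <- oracle_sample_px(img, x, y, interpolation, grid$fill_value)
    }
  }
  out
}

# ---- small image builders ----------------------------------------------------

# centered disk of radius r on an n x n canvas
disk_image <- function(n, r, center = c((n - 1) / 2, (n - 1) / 2)) {
  m <- matrix(0, n, n)
  for (yy in 1:n) for (xx in 1:n) {
    if (sqrt((xx - 1 - center[1])^2 + (yy - 1 - center[2])^2) <= r) {
      m[yy, xx] <- 1
    }
  }
  m
}

# smooth (rotationally band-limited) test image: a few broad Gaussian blobs
smooth_blob_image <- function(n, seed = 42) {
  set.seed(seed)
  g <- expand.grid(y = 0:(n - 1), x = 0:(n - 1))
  m <- numeric(n * n)
  for (j in 1:4) {
    cx <- runif(1, n * 0.25, n * 0.75); cy <- runif(1, n * 0.25, n * 0.75)
    s <- runif(1, n / 8, n / 5)
    m <- m + runif(1, 0.3, 1) * exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * s^2))
  }
  m <- m / max(m)
  matrix(m, n, n)
}

# quick labeled dataset wrapper around a list of images
toy_dataset <- function(images, labels, class_names = NULL) {
  if (is.null(class_names)) {
    class_names <- paste0("c", sort(unique(labels)))
  }
  structure(list(images = images, labels = as.integer(labels),
                 class_names = class_names,
                 split = list(train = seq_along(images), test = integer(0)),
                 canvas_size = nrow(images[[1]]), seed = 1L),
            class = "labeled_dataset")
}

# bright-left / bright-right linearly separable toy images
separable_images <- function(n_per_class = 20, size = 32, seed = 1) {
  set.seed(seed)
  mk <- function(side) {
    m <- matrix(0.1, size, size)
    if (side == 0) m[, 1:(size / 2)] <- 0.9 else m[, (size / 2 + 1):size] <- 0.9
    polarfuse::as_raster(pmin(m + matrix(runif(size * size, 0, 0.05),
                                         size, size), 1))
  }
  toy_dataset(c(lapply(seq_len(n_per_class), function(i) mk(0)),
                lapply(seq_len(n_per_class), function(i) mk(1))),
              rep(0:1, each = n_per_class))
}
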