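#' Polar sampling grids
#'
#' A polar grid specifies how an (rho, theta) raster samples the Cartesian
#' plane: the center (xc, yc) in zero-based pixel coordinates, the radial
#' extent, the number of radial and angular bins, and optionally a log base.
#'
#' Angular bin k covers theta_k = k * 2*pi / n_theta, k = 0..n_theta-1,
#' measured from the +x axis toward +y (downward), so the theta axis is
#' periodic and rotation by phi degrees corresponds to a rightward circular
#' column shift of round(phi / 360 * n_theta) columns.
#'
#' Radial bin i samples rho_i = i * r_max / (n_rho - 1) in linear mode, or
#' rho_i log-spaced between r_min and r_max when `log_base` is set (the log
#' of zero radius is undefined, hence the positive inner radius). In log
#' mode an isotropic scaling by s becomes a vertical shift of
#' log(s) / log(log_base) / delta bins, delta being the per-bin log-radius
#' step (see [predicted_radial_shift()]).
#'
#' @param center numeric (xc, yc), zero-based pixel coordinates.
#' @param r_max outer sampling radius in pixels (> 0).
#' @param n_rho number of radial bins (>= 2).
#' @param n_theta number of angular bins (>= 4).
#' @param log_base NULL for linear radii, or a real > 1 (commonly 10 or
#'   exp(1)) for logarithmically spaced radii.
#' @param r_min inner radius for log mode (> 0); default r_max / n_rho.
#' @param fill_value intensity in [0, 1] used for samples falling outside
#'   the source image (default 0, matching dark-field imagery).
#' @return an object of class `polar_grid`.
#' @export
polar_grid <- function(center, r_max, n_rho = 64L, n_theta = 64L,
                       log_base = NULL, r_min = NULL, fill_value = 0) {
  stopifnot(length(center) == 2, all(is.finite(center)))
  if (!is.finite(r_max) || r_max <= 0) stop("r_max must be a positive real")
  n_rho <- as.integer(n_rho); n_theta <- as.integer(n_theta)
  if (n_rho < 2) stop("n_rho must be >= 2")
  if (n_theta < 4) stop("n_theta must be >= 4")
  if (!is.null(log_base)) {
    if (!is.finite(log_base) || log_base <= 1) {
      stop("log_base must be > 1 (or NULL for linear radii)")
    }
  }
  if (is.null(r_min)) r_min <- r_max / n_rho
  if (!is.null(log_base) && (r_min <= 0 || r_min >= r_max)) {
    stop("r_min must satisfy 0 < r_min < r_max in log mode")
  }
  if (fill_value < 0 || fill_value > 1) stop("fill_value must be in [0, 1]")
  structure(list(center = as.numeric(center), r_max = r_max,
                 n_rho = n_rho, n_theta = n_theta,
                 log_base = log_base, r_min = r_min,
                 fill_value = fill_value),
            class = "polar_grid")
}

#' Default polar grid for an image
#'
#' Centers the grid at the geometric image center (or the foreground
#' intensity centroid) with the inscribed-circle radius min(W, H) / 2 by
#' default, which guarantees no out-of-source sampling; the circumscribed
#' policy reaches the corners and relies on `fill_value`.
#'
#' @param img image raster.
#' @param n_rho,n_theta,log_base,r_min,fill_value see [polar_grid()].
#' @param r_max_policy "inscribed" (default) or "circumscribed".
#' @param center_mode "geometric" (default) or "centroid" (foreground
#'   intensity centroid; object-centered ROI crops make the two nearly
#'   coincide).
#' @return a `polar_grid`.
#' @export
polar_grid_for <- function(img, n_rho = 64L, n_theta = 64L, log_base = NULL,
                           r_min = NULL, fill_value = 0,
                           r_max_policy = c("inscribed", "circumscribed"),
                           center_mode = c("geometric", "centroid")) {
  img <- as_raster(img)
  r_max_policy <- match.arg(r_max_policy)
  center_mode <- match.arg(center_mode)
  d <- raster_dim(img)
  center <- if (center_mode == "geometric") {
    raster_center(img)
  } else {
    g <- to_gray(img)
    tot <- sum(g)
    if (tot <= 0) raster_center(img) else {
      gd <- coord_grid(d$h, d$w)
      c(sum(gd$x * g) / tot, sum(gd$y * g) / tot)
    }
  }
  r_max <- if (r_max_policy == "inscribed") {
    # largest radius fully covered by pixel centers about this center
    min(center[1], center[2], d$w - 1 - center[1], d$h - 1 - center[2])
  } else {
    corners_x <- c(0, d$w - 1); corners_y <- c(0, d$h - 1)
    sqrt(max(outer((corners_x - center[1])^2, (corners_y - center[2])^2, "+")))
  }
  polar_grid(center, r_max, n_rho, n_theta, log_base, r_min, fill_value)
}

# Radii sampled by each radial bin (length n_rho).
grid_radii <- function(grid) {
  if (is.null(grid$log_base)) {
    seq(0, grid$r_max, length.out = grid$n_rho)
  } else {
    exp(seq(log(grid$r_min), log(grid$r_max), length.out = grid$n_rho))
  }
}

# Angles sampled by each angular bin (length n_theta).
grid_angles <- function(grid) {
  (0:(grid$n_theta - 1)) * 2 * pi / grid$n_theta
}

# Per-bin step of log_base-logarithm of radius (log mode only).
grid_log_step <- function(grid) {
  stopifnot(!is.null(grid$log_base))
  (log(grid$r_max) - log(grid$r_min)) / (grid$n_rho - 1) / log(grid$log_base)
}

#' Map a Cartesian point to polar coordinates
#'
#' rho is the Euclidean distance from the grid center (its log_base
#' logarithm in log mode); theta lies in [0, 2*pi), measured from the +x
#' axis with the quadrant-aware inverse tangent under the downward-y image
#' convention. At the exact center theta is undefined and returned as 0 by
#' convention; in log mode the center is a degenerate point and is
#' rejected rather than mapped to -Inf.
#'
#' @param p numeric (x, y), zero-based pixel coordinates.
#' @param grid a [polar_grid()].
#' @return named numeric vector c(rho =, theta =).
#' @export
point_to_polar <- function(p, grid) {
  stopifnot(inherits(grid, "polar_grid"), length(p) == 2, all(is.finite(p)))
  dx <- p[1] - grid$center[1]
  dy <- p[2] - grid$center[2]
  r <- sqrt(dx^2 + dy^2)
  if (r == 0) {
    if (!is.null(grid$log_base)) {
      stop("degenerate point: the grid center has no log-polar radius")
    }
    return(c(rho = 0, theta = 0))
  }
  theta <- atan2(dy, dx) %% (2 * pi)
  rho <- if (is.null(grid$log_base)) r else log(r) / log(grid$log_base)
  c(rho = rho, theta = theta)
}

# Shared core: sample img at the Cartesian positions of each (rho, theta)
# bin. Vectorized over the whole n_rho x n_theta grid.
polar_resample <- function(img, grid, interpolation) {
  img <- as_raster(img)
  d <- raster_dim(img)
  ctr <- grid$center
  if (ctr[1] < 0 || ctr[1] > d$w - 1 || ctr[2] < 0 || ctr[2] > d$h - 1) {
    stop("grid center must lie inside the image bounds")
  }
  radii <- grid_radii(grid)
  ang <- grid_angles(grid)
  sx <- ctr[1] + outer(radii, cos(ang))   # n_rho x n_theta
  sy <- ctr[2] + outer(radii, sin(ang))
  out <- sample_raster(img, as.vector(sx), as.vector(sy),
                       c(grid$n_rho, grid$n_theta),
                       interpolation, grid$fill_value)
  clamp01(out)
}

#' Resample an image into polar coordinates
#'
#' Output pixel (i, k) holds the source intensity at the Cartesian position
#' of radius rho_i and angle theta_k about the grid center; rotation of the
#' source about that center becomes a circular shift along the column
#' (theta) axis. Positions outside the source take `grid$fill_value`.
#'
#' @param img image raster.
#' @param grid a linear-radius [polar_grid()] (log_base NULL).
#' @param interpolation "bilinear" (default) or "nearest".
#' @return an n_rho x n_theta raster (rows = radius, columns = angle).
#' @export
to_polar <- function(img, grid, interpolation = c("bilinear", "nearest")) {
  stopifnot(inherits(grid, "polar_grid"))
  interpolation <- match.arg(interpolation)
  polar_resample(img, grid, interpolation)
}

#' Resample an image into log-polar coordinates
#'
#' As [to_polar()] but with radii logarithmically spaced between
#' `grid$r_min` and `grid$r_max`, so isotropic scaling about the center
#' becomes a vertical (radial-axis) shift.
#'
#' @inheritParams to_polar
#' @param grid a [polar_grid()] with `log_base` set.
#' @return an n_rho x n_theta raster.
#' @export
to_log_polar <- function(img, grid, interpolation = c("bilinear", "nearest")) {
  stopifnot(inherits(grid, "polar_grid"))
  if (is.null(grid$log_base)) {
    stop("to_log_polar requires a grid with log_base set")
  }
  interpolation <- match.arg(interpolation)
  polar_resample(img, grid, interpolation)
}

#' Predicted circular column shift for a rotation
#'
#' A rotation of phi degrees about the grid center translates the polar
#' image horizontally by phi / 360 of the angular axis; this returns that
#' shift rounded to whole columns, round(phi / 360 * n_theta).
#'
#' @param rotation_deg rotation angle in degrees (any sign).
#' @param grid a [polar_grid()].
#' @return integer column shift (positive = rightward).
#' @export
predicted_shift <- function(rotation_deg, grid) {
  stopifnot(inherits(grid, "polar_grid"))
  as.integer(round(rotation_deg / 360 * grid$n_theta))
}

#' Predicted radial-bin shift for an isotropic scaling (log mode)
#'
#' Scaling the source by s moves a feature at radius r to r * s, i.e. by
#' log(s) in log-radius, which is log(s) / log(log_base) divided by the
#' per-bin log step in rows (positive = downward, toward larger radii).
#'
#' @param scale_factor isotropic scale factor (> 0).
#' @param grid a [polar_grid()] with `log_base` set.
#' @return integer row shift.
#' @export
predicted_radial_shift <- function(scale_factor, grid) {
  stopifnot(inherits(grid, "polar_grid"), scale_factor > 0)
  as.integer(round(log(scale_factor) / log(grid$log_base) / grid_log_step(grid)))
}

#' Approximate inverse of the polar transform
#'
#' Reconstructs a Cartesian raster from a polar (or log-polar) raster by
#' bilinear lookup in (rho, theta) space, periodic along theta. Pixels
#' outside the disk of radius r_max (or inside r_min in log mode) take
#' `grid$fill_value`. Enables round-trip testing; the composition
#' from_polar(to_polar(img)) approximates img on the covered annulus.
#'
#' @param polar_img n_rho x n_theta raster as produced by [to_polar()].
#' @param grid the [polar_grid()] that produced it.
#' @param out_shape integer (H, W) of the reconstruction.
#' @return an H x W raster.
#' @export
from_polar <- function(polar_img, grid, out_shape) {
  stopifnot(inherits(grid, "polar_grid"), length(out_shape) == 2)
  d <- raster_dim(polar_img)
  if (d$h != grid$n_rho || d$w != grid$n_theta) {
    stop("polar image shape does not match grid (n_rho x n_theta)")
  }
  h <- as.integer(out_shape[1]); w <- as.integer(out_shape[2])
  g <- coord_grid(h, w)
  dx <- as.vector(g$x) - grid$center[1]
  dy <- as.vector(g$y) - grid$center[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) %% (2 * pi)
  # fractional polar-grid coordinates (zero-based): row from radius,
  # column from angle
  row <- if (is.null(grid$log_base)) {
    r / grid$r_max * (grid$n_rho - 1)
  } else {
    lr <- ifelse(r < grid$r_min, 0,
                 (log(pmax(r, grid$r_min)) - log(grid$r_min)) /
                   (log(grid$r_max) - log(grid$r_min)) * (grid$n_rho - 1))
    lr
  }
  col <- theta / (2 * pi) * grid$n_theta
  outside <- r > grid$r_max
  # periodic theta: append the first column so col in [n_theta-1, n_theta]
  # interpolates between the last and first columns
  pad <- function(m) cbind(m, m[, 1])
  sample_one <- function(m) {
    v <- sample_channel(pad(m), col, pmin(pmax(row, 0), grid$n_rho - 1),
                        "bilinear", grid$fill_value, edge = "clamp")
    v[outside] <- grid$fill_value
    v
  }
  if (d$c == 1) {
    out <- sample_one(polar_img)
    dim(out) <- c(h, w)
  } else {
    out <- array(0, c(h, w, d$c))
    for (ch in seq_len(d$c)) {
      v <- sample_one(polar_img[, , ch])
      out[, , ch] <- v
    }
  }
  clamp01(out)
}
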