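#' Image rasters and the shared resampling core
#'
#' An image raster is a numeric matrix (grayscale, H x W) or a 3-d array
#' (H x W x 3 for RGB) with intensities in [0, 1]. Pixel (0, 0) is the
#' upper-left corner: x indexes columns rightward, y indexes rows downward,
#' both zero-based. Every geometric operation in the package (polar
#' resampling, rotation, flips, scaling, resizing) goes through the single
#' sampler implemented here, so interpolation behaviour is identical
#' repo-wide.
#'
#' @param pixels numeric matrix or H x W x C array, C in {1, 3}.
#' @return the validated raster (a matrix for C = 1).
#' @export
as_raster <- function(pixels) {
  if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 1) {
    pixels <- pixels[, , 1, drop = TRUE]
  }
  if (!(is.matrix(pixels) ||
        (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3))) {
    stop("raster must be an H x W matrix or an H x W x 3 array")
  }
  d <- dim(pixels)
  if (d[1] < 2 || d[2] < 2) stop("raster must be at least 2 x 2")
  if (!is.numeric(pixels) || any(!is.finite(pixels))) {
    stop("raster intensities must be finite numbers")
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("raster intensities must lie in [0, 1]")
  }
  pixels
}

raster_dim <- function(img) {
  d <- dim(img)
  list(h = d[1], w = d[2], c = if (length(d) == 3) d[3] else 1L)
}

#' Geometric center of a raster in pixel coordinates
#'
#' Returns ((W-1)/2, (H-1)/2), the default rotation / polar center.
#' @param img image raster.
#' @return numeric length-2 vector (xc, yc).
#' @export
raster_center <- function(img) {
  d <- raster_dim(img)
  c((d$w - 1) / 2, (d$h - 1) / 2)
}

# Sample one channel (a matrix) at fractional zero-based coordinates.
# edge = "fill": positions outside the source take `fill`;
# edge = "clamp": coordinates are clamped to the border (used by resize so
# constants stay constant).
sample_channel <- function(m, x, y, interpolation, fill, edge = "fill") {
  h <- nrow(m); w <- ncol(m)
  if (edge == "clamp") {
    x <- pmin(pmax(x, 0), w - 1)
    y <- pmin(pmax(y, 0), h - 1)
  }
  if (interpolation == "nearest") {
    xi <- floor(x + 0.5); yi <- floor(y + 0.5)
    inside <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    out <- rep(fill, length(x))
    idx <- yi[inside] + 1 + xi[inside] * h
    out[inside] <- m[idx]
    out
  } else if (interpolation == "bilinear") {
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    # gather the four neighbours, substituting `fill` outside the source
    pick <- function(xi, yi) {
      ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
      v <- rep(fill, length(xi))
      v[ok] <- m[yi[ok] + 1 + xi[ok] * h]
      v
    }
    v00 <- pick(x0, y0); v10 <- pick(x0 + 1, y0)
    v01 <- pick(x0, y0 + 1); v11 <- pick(x0 + 1, y0 + 1)
    (v00 * (1 - fx) + v10 * fx) * (1 - fy) + (v01 * (1 - fx) + v11 * fx) * fy
  } else {
    stop("unknown interpolation: ", interpolation)
  }
}

# Sample a raster (any channel count) at vectors of zero-based coordinates;
# returns a matrix/array shaped like out_dim = c(h, w).
sample_raster <- function(img, x, y, out_dim, interpolation = "bilinear",
                          fill = 0, edge = "fill") {
  d <- raster_dim(img)
  if (d$c == 1) {
    out <- sample_channel(img, x, y, interpolation, fill, edge)
    dim(out) <- out_dim
    out
  } else {
    out <- array(0, c(out_dim, d$c))
    for (ch in seq_len(d$c)) {
      v <- sample_channel(img[, , ch], x, y, interpolation, fill, edge)
      out[, , ch] <- v
    }
    out
  }
}

# Target-pixel coordinate grid for an out_h x out_w output, zero-based.
coord_grid <- function(out_h, out_w) {
  list(x = matrix(rep(0:(out_w - 1), each = out_h), out_h, out_w),
       y = matrix(rep(0:(out_h - 1), times = out_w), out_h, out_w))
}

#' Rotate a raster about a center
#'
#' Angles are measured from the +x axis toward +y; with the image
#' convention of y pointing downward this is visually clockwise. A point at
#' polar angle theta in the source appears at theta + degrees in the
#' output, so rotation corresponds to a rightward circular column shift of
#' the polar image (see [predicted_shift()]).
#'
#' @param img image raster.
#' @param degrees rotation angle in degrees.
#' @param center (xc, yc), default geometric center.
#' @param interpolation "bilinear" (default) or "nearest".
#' @param fill intensity for pixels mapped from outside the source.
#' @return rotated raster, same dimensions.
#' @export
rotate_raster <- function(img, degrees, center = raster_center(img),
                          interpolation = "bilinear", fill = 0) {
  img <- as_raster(img)
  d <- raster_dim(img)
  g <- coord_grid(d$h, d$w)
  a <- degrees * pi / 180
  dx <- g$x - center[1]; dy <- g$y - center[2]
  # inverse map: rotate target offsets by -a
  sx <- center[1] + cos(a) * dx + sin(a) * dy
  sy <- center[2] - sin(a) * dx + cos(a) * dy
  out <- sample_raster(img, as.vector(sx), as.vector(sy), c(d$h, d$w),
                       interpolation, fill)
  clamp01(out)
}

#' Scale a raster about a center
#'
#' @inheritParams rotate_raster
#' @param factor isotropic scale factor (> 0); factor > 1 magnifies.
#' @return scaled raster, same dimensions.
#' @export
scale_raster <- function(img, factor, center = raster_center(img),
                         interpolation = "bilinear", fill = 0) {
  img <- as_raster(img)
  stopifnot(is.finite(factor), factor > 0)
  d <- raster_dim(img)
  g <- coord_grid(d$h, d$w)
  sx <- center[1] + (g$x - center[1]) / factor
  sy <- center[2] + (g$y - center[2]) / factor
  out <- sample_raster(img, as.vector(sx), as.vector(sy), c(d$h, d$w),
                       interpolation, fill)
  clamp01(out)
}

#' Flip a raster
#'
#' @param img image raster.
#' @param axis "ud" (up-down, reverses rows) or "lr" (left-right).
#' @return flipped raster.
#' @export
flip_raster <- function(img, axis = c("ud", "lr")) {
  img <- as_raster(img)
  axis <- match.arg(axis)
  d <- raster_dim(img)
  ri <- if (axis == "ud") d$h:1 else seq_len(d$h)
  ci <- if (axis == "lr") d$w:1 else seq_len(d$w)
  if (d$c == 1) img[ri, ci, drop = FALSE] else img[ri, ci, , drop = FALSE]
}

#' Resize a raster
#'
#' Bilinear resampling with pixel-center alignment and clamp-to-edge
#' boundaries (so constant images stay constant). Used for the input-size
#' standardization applied before feature extraction.
#'
#' @param img image raster.
#' @param out_h,out_w output dimensions (>= 2).
#' @return resized raster.
#' @export
resize_raster <- function(img, out_h, out_w) {
  img <- as_raster(img)
  d <- raster_dim(img)
  if (out_h == d$h && out_w == d$w) return(img)
  stopifnot(out_h >= 2, out_w >= 2)
  g <- coord_grid(out_h, out_w)
  sx <- (g$x + 0.5) * d$w / out_w - 0.5
  sy <- (g$y + 0.5) * d$h / out_h - 0.5
  out <- sample_raster(img, as.vector(sx), as.vector(sy), c(out_h, out_w),
                       "bilinear", 0, edge = "clamp")
  clamp01(out)
}

#' Convert an RGB raster to grayscale
#'
#' Rec. 601 luma weights.
#' @param img image raster.
#' @return grayscale matrix.
#' @export
to_gray <- function(img) {
  d <- raster_dim(img)
  if (d$c == 1) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Circularly shift the columns of a matrix
#'
#' Column k of the output is column (k - shift) mod n of the input, i.e.
#' positive shifts move content rightward. The column axis is treated as
#' periodic, matching the angular axis of a polar image.
#'
#' @param m matrix.
#' @param shift integer shift (any sign; reduced mod ncol).
#' @return shifted matrix.
#' @export
circshift_cols <- function(m, shift) {
  n <- ncol(m)
  s <- ((shift %% n) + n) %% n
  if (s == 0) return(m)
  m[, c((n - s + 1):n, 1:(n - s)), drop = FALSE]
}

# Row analogue (used for radial shifts in scale-equivariance checks);
# non-periodic: vacated rows take `fill`.
shift_rows <- function(m, shift, fill = 0) {
  n <- nrow(m)
  out <- matrix(fill, n, ncol(m))
  if (shift >= 0) {
    if (shift < n) out[(shift + 1):n, ] <- m[1:(n - shift), ]
  } else {
    s <- -shift
    if (s < n) out[1:(n - s), ] <- m[(s + 1):n, ]
  }
  out
}
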