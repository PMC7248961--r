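# grid with integer center and integer sampling radii: nearest-neighbour
# resampling then hits exact pixel positions for quarter-turn rotations
exact_grid <- function(n = 65, n_theta = 64) {
  polar_grid(c((n - 1) / 2, (n - 1) / 2), r_max = (n - 1) / 2 - 2,
             n_rho = (n - 1) / 2 - 1, n_theta = n_theta)
}

test_that("point_to_polar matches the quadrant-aware inverse tangent", {
  grid <- polar_grid(c(10, 10), r_max = 8, n_rho = 8, n_theta = 16)
  expect_equal(point_to_polar(c(10, 10), grid), c(rho = 0, theta = 0))
  expect_equal(point_to_polar(c(15, 10), grid), c(rho = 5, theta = 0))
  # downward-y convention: +y offset sits at theta = pi/2
  expect_equal(point_to_polar(c(10, 13), grid), c(rho = 3, theta = pi / 2))
  # brute-force check over a lattice of offsets
  for (dx in -3:3) for (dy in -3:3) {
    if (dx == 0 && dy == 0) next
    got <- point_to_polar(c(10 + dx, 10 + dy), grid)
    expect_equal(unname(got["rho"]), sqrt(dx^2 + dy^2))
    expect_equal(unname(got["theta"]), atan2(dy, dx) %% (2 * pi))
  }
  # log mode: radius becomes a logarithm; the exact center is degenerate
  lgrid <- polar_grid(c(10, 10), 8, 8, 16, log_base = 10)
  expect_equal(unname(point_to_polar(c(10, 13), lgrid)["rho"]), log10(3))
  expect_error(point_to_polar(c(10, 10), lgrid), "degenerate")
})

test_that("grid validation enforces the documented preconditions", {
  expect_error(polar_grid(c(0, 0), -1), "r_max")
  expect_error(polar_grid(c(0, 0), 8, n_rho = 1), "n_rho")
  expect_error(polar_grid(c(0, 0), 8, n_theta = 3), "n_theta")
  expect_error(polar_grid(c(0, 0), 8, log_base = 1), "log_base")
  expect_error(polar_grid(c(0, 0), 8, log_base = 0.5), "log_base")
  expect_error(polar_grid(c(0, 0), 8, fill_value = 2), "fill_value")
  expect_error(to_log_polar(matrix(0.5, 8, 8),
                            polar_grid(c(3.5, 3.5), 4)), "log_base")
  expect_error(to_polar(matrix(0.5, 8, 8), polar_grid(c(40, 3), 4)),
               "center")
})

test_that("resampling a constant image is constant, for any mode", {
  const <- matrix(0.42, 32, 32)
  grid <- polar_grid_for(const, n_rho = 24, n_theta = 32)
  lgrid <- polar_grid_for(const, n_rho = 24, n_theta = 32, log_base = exp(1))
  for (interp in c("nearest", "bilinear")) {
    expect_equal(to_polar(const, grid, interp),
                 matrix(0.42, 24, 32))
    expect_equal(to_log_polar(const, lgrid, interp),
                 matrix(0.42, 24, 32))
  }
})

test_that("a centered disk maps to saturated top rows for every angle", {
  img <- disk_image(64, 20)
  grid <- polar_grid_for(img, n_rho = 32, n_theta = 48)
  P <- to_polar(img, grid, "nearest")
  radii <- seq(0, grid$r_max, length.out = grid$n_rho)
  expect_true(all(P[radii <= 19, ] == 1))
  expect_true(all(P[radii >= 21, ] == 0))
  # log-polar: transition row where the log-spaced radius crosses r
  lgrid <- polar_grid_for(img, n_rho = 32, n_theta = 48, log_base = exp(1))
  L <- to_log_polar(img, lgrid, "nearest")
  lr <- exp(seq(log(lgrid$r_min), log(lgrid$r_max), length.out = 32))
  expect_true(all(L[lr <= 19, ] == 1))
  expect_true(all(L[lr >= 21, ] == 0))
})

test_that("vectorized resampler agrees with the brute-force oracle", {
  set.seed(11)
  img <- as_raster(matrix(runif(64 * 64), 64, 64))
  for (log_base in list(NULL, exp(1), 10)) {
    grid <- polar_grid_for(img, n_rho = 40, n_theta = 36,
                           log_base = log_base, fill_value = 0.25,
                           r_max_policy = "circumscribed")
    expect_identical(polarfuse:::polar_resample(img, grid, "nearest"),
                     oracle_polar(img, grid, "nearest"))
    expect_lt(max(abs(polarfuse:::polar_resample(img, grid, "bilinear") -
                        oracle_polar(img, grid, "bilinear"))), 1e-6)
  }
})

test_that("rotation becomes an exact column shift for quarter turns (nearest)", {
  set.seed(12)
  img <- as_raster(matrix(runif(65 * 65), 65, 65))
  grid <- exact_grid(65, 64)
  P <- to_polar(img, grid, "nearest")
  for (ang in c(90, 180, 270)) {
    rot <- rotate_raster(img, ang, interpolation = "nearest")
    expect_identical(to_polar(rot, grid, "nearest"),
                     circshift_cols(P, predicted_shift(ang, grid)))
  }
})

test_that("rotation equivariance holds within tolerance for bilinear", {
  img <- smooth_blob_image(64)
  grid <- polar_grid_for(img, n_rho = 48, n_theta = 72)
  P <- to_polar(img, grid)
  for (ang in c(30, 45, 135)) {
    rot <- rotate_raster(img, ang)
    Prot <- to_polar(rot, grid)
    shift <- predicted_shift(ang, grid)
    expect_lt(mean(abs(Prot - circshift_cols(P, shift))), 0.02)
  }
})

test_that("scaling becomes a radial shift in log-polar coordinates", {
  img <- smooth_blob_image(64, seed = 5)
  lgrid <- polar_grid_for(img, n_rho = 48, n_theta = 64, log_base = exp(1))
  L <- to_log_polar(img, lgrid)
  for (s in c(1.25, 0.8)) {
    Ls <- to_log_polar(scale_raster(img, s), lgrid)
    sh <- predicted_radial_shift(s, lgrid)
    rows <- if (sh >= 0) (sh + 1):48 else 1:(48 + sh)
    expect_lt(mean(abs(Ls[rows, ] - shift_rows(L, sh)[rows, ])), 0.02)
  }
})

test_that("predicted shifts follow the stated proportions", {
  g64 <- polar_grid(c(0, 0), 8, 8, 64)
  expect_identical(predicted_shift(0, g64), 0L)
  expect_identical(predicted_shift(90, polar_grid(c(0, 0), 8, 8, 360)), 90L)
  expect_identical(predicted_shift(30, polar_grid(c(0, 0), 8, 8, 256)), 21L)
  expect_identical(predicted_shift(-90, g64), -16L)
  # shifting by the full angular period is the identity
  m <- matrix(runif(8 * 64), 8, 64)
  expect_identical(circshift_cols(m, 64), m)
})

test_that("from_polar approximately inverts to_polar", {
  # smooth radial gradient: exactly representable along rho
  g <- polarfuse:::coord_grid(64, 64)
  r <- sqrt((g$x - 31.5)^2 + (g$y - 31.5)^2)
  img <- as_raster(pmin(r / 45, 1))
  grid <- polar_grid_for(img, n_rho = 64, n_theta = 128)
  rec <- from_polar(to_polar(img, grid), grid, c(64, 64))
  inside <- r <= grid$r_max - 1
  expect_lt(mean(abs(rec[inside] - img[inside])), 0.01)
  # constant round trip is constant on the covered disk
  const <- matrix(0.6, 64, 64)
  recc <- from_polar(to_polar(const, grid), grid, c(64, 64))
  expect_equal(recc[r <= grid$r_max - 1], rep(0.6, sum(inside)))
  # energy of a single off-center bright pixel returns near its origin
  px <- matrix(0, 64, 64); px[40, 44] <- 1
  fine <- polar_grid_for(px, n_rho = 96, n_theta = 256)
  rec2 <- from_polar(to_polar(px, fine), fine, c(64, 64))
  hot <- which(rec2 == max(rec2), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(hot - c(40, 44))), 1)
  # shape mismatch is rejected
  expect_error(from_polar(matrix(0, 5, 5), grid, c(64, 64)), "shape")
})
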