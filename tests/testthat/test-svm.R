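tag <- function(m, view) { attr(m, "view") <- view; m }

test_that("splicing concatenates Cartesian then polar blocks", {
  vc <- tag(matrix(1:12, 3, 4), "cartesian")
  vp <- tag(matrix(13:21, 3, 3), "polar")
  v <- splice(vc, vp)
  expect_identical(dim(v), c(3L, 7L))
  expect_identical(v[, 1:4], unclass(vc)[, 1:4])
  expect_identical(v[, 5:7], unclass(vp)[, 1:3])
  expect_identical(attr(v, "view"), "fused")
  # view tags enforce the block order
  expect_error(splice(vp, vc), "cartesian")
  expect_error(splice(vc, vc), "polar")
  expect_error(splice(tag(matrix(0, 2, 4), "cartesian"), vp), "row counts")
  # zero blocks splice to a zero vector of combined length
  z <- splice(tag(matrix(0, 1, 64), "cartesian"), tag(matrix(0, 1, 64), "polar"))
  expect_identical(as.numeric(z), rep(0, 128))
})

test_that("the one-vs-rest SVM separates Gaussian clouds and fails on XOR", {
  set.seed(8)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 4), 50, 2))
  y <- rep(0:1, each = 50)
  clf <- fit_svm(x, y, svm_config(kernel = "linear", cost = 10))
  expect_equal(mean(predict_svm(clf, x) == y), 1)
  # XOR: not linearly separable, easily solved by the RBF kernel
  set.seed(9)
  xx <- matrix(runif(400, -1, 1), 200, 2)
  yy <- as.integer(xx[, 1] * xx[, 2] > 0)
  lin <- fit_svm(xx, yy, svm_config(kernel = "linear"))
  rbf <- fit_svm(xx, yy, svm_config(kernel = "rbf", cost = 10))
  expect_lte(mean(predict_svm(lin, xx) == yy), 0.75)
  expect_gte(mean(predict_svm(rbf, xx) == yy), 0.95)
})

test_that("one machine per class; degenerate inputs rejected", {
  set.seed(10)
  x <- matrix(rnorm(7 * 10 * 4), 70, 4) + rep(seq(0, 18, by = 3), each = 10)
  y <- rep(0:6, each = 10)
  clf <- fit_svm(x, y, svm_config())
  expect_length(clf$machines, 7)
  expect_identical(clf$classes, 0:6)
  pred <- predict_svm(clf, x)
  expect_true(all(pred %in% 0:6))
  expect_error(fit_svm(x[1:10, ], y[1:10], svm_config()), "2 classes")
  xb <- x; xb[1, 1] <- NaN
  expect_error(fit_svm(xb, y, svm_config()), "finite")
  expect_error(predict_svm(clf, x[, 1:3]), "length mismatch")
})

test_that("training order does not affect the fitted classifier", {
  set.seed(11)
  x <- matrix(rnorm(240), 80, 3) + rep(c(0, 2, 5, 8), each = 20)
  y <- rep(0:3, each = 20)
  ho <- matrix(rnorm(60), 20, 3) + 3
  p1 <- predict_svm(fit_svm(x, y, svm_config()), ho)
  perm <- sample(80)
  p2 <- predict_svm(fit_svm(x[perm, ], y[perm], svm_config()), ho)
  expect_identical(p1, p2)
})

test_that("standardization is fitted on training data only", {
  set.seed(12)
  x <- matrix(rnorm(200, 5, 3), 100, 2) + rep(c(0, 6), each = 50)
  y <- rep(0:1, each = 50)
  clf <- fit_svm(x, y, svm_config())
  expect_equal(clf$center, colMeans(x), tolerance = 1e-12)
  expect_equal(clf$scale, apply(x, 2, sd), tolerance = 1e-12)
  # refitting on the same data reproduces the stored training predictions
  expect_identical(predict_svm(clf, x),
                   predict_svm(fit_svm(x, y, svm_config()), x))
})

test_that("decision ties break toward the lowest class index", {
  # mirror-symmetric 1-d problem: the midpoint is equidistant from both
  # one-vs-rest hyperplanes, so its two decision values coincide
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  clf <- fit_svm(x, y, svm_config(scaling = "none", cost = 1))
  dv <- polarfuse:::decision_matrix(clf$machines, matrix(0, 1, 1))
  expect_equal(dv[1, 1], -dv[1, 2], tolerance = 1e-8)
  expect_identical(predict_svm(clf, matrix(0, 1, 1)), 0L)
})

test_that("cost tuning picks a grid value by cross-validation", {
  set.seed(13)
  x <- matrix(rnorm(300), 150, 2) + rep(c(0, 2.5, 5), each = 50)
  y <- rep(0:2, each = 50)
  cfg <- svm_config(tune = TRUE, cost_grid = c(0.01, 1), folds = 3, seed = 4)
  clf <- fit_svm(x, y, cfg)
  expect_true(clf$cost %in% cfg$cost_grid)
  # tuned refit is deterministic
  clf2 <- fit_svm(x, y, cfg)
  expect_identical(clf$cost, clf2$cost)
  expect_identical(predict_svm(clf, x), predict_svm(clf2, x))
})
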