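test_that("training is deterministic and solves a separable toy task", {
  ds <- separable_images(20)
  cfg <- backbone_config(n_classes = 2, epochs = 5, seed = 7)
  e1 <- train_extractor(ds, cfg, "cartesian")
  e2 <- train_extractor(ds, cfg, "cartesian")
  expect_identical(e1$params, e2$params)
  expect_identical(e1$loss, e2$loss)
  # bright-left vs bright-right is separable: perfect training accuracy
  expect_equal(mean(predict(e1, ds$images) == ds$labels), 1)
  # loss decreases over training
  expect_lt(tail(e1$loss, 1), e1$loss[1])
})

test_that("cartesian and polar extractors share the architecture", {
  ds <- separable_images(6, size = 32)
  cfg <- backbone_config(n_classes = 2, epochs = 1, seed = 3)
  ec <- train_extractor(ds, cfg, "cartesian")
  ep <- train_extractor(ds, cfg, "polar")
  expect_identical(n_parameters(ec), n_parameters(ep))
  expect_identical(lapply(ec$params$conv, function(p) dim(p$W)),
                   lapply(ep$params$conv, function(p) dim(p$W)))
  # same structure, different weights after training on different views
  expect_false(identical(ec$params, ep$params))
})

test_that("feature extraction is pure and respects the configured width", {
  ds <- separable_images(8)
  cfg <- backbone_config(n_classes = 2, fc = c(48L), epochs = 2, seed = 1)
  ext <- train_extractor(ds, cfg, "cartesian")
  f <- extract_features(ext, ds$images[1:5])
  expect_identical(dim(f), c(5L, 48L))
  expect_identical(attr(f, "view"), "cartesian")
  expect_true(all(is.finite(f)))
  # identical inputs give identical vectors
  f2 <- extract_features(ext, ds$images[c(1, 1)])
  expect_identical(f2[1, ], f2[2, ])
  expect_identical(extract_features(ext, ds$images[1:5]), f)
})

test_that("prediction contracts hold", {
  ds <- separable_images(10)
  cfg <- backbone_config(n_classes = 2, epochs = 5, seed = 2)
  ext <- train_extractor(ds, cfg, "cartesian")
  pred <- predict(ext, ds$images)
  expect_true(all(pred %in% 0:1))
  # constant-input batch gets one label
  const <- lapply(1:4, function(i) matrix(0.5, 32, 32))
  expect_length(unique(predict(ext, const)), 1)
  # untrained extractor is rejected
  broken <- ext; broken$trained <- FALSE
  expect_error(extract_features(broken, ds$images[1]), "not trained")
  expect_error(predict(broken, ds$images[1]), "not trained")
  # label range checked at training time
  bad <- ds; bad$labels[1] <- 5L
  expect_error(train_extractor(bad, cfg, "cartesian"), "n_classes")
  empty <- ds; empty$images <- list(); empty$labels <- integer(0)
  expect_error(train_extractor(empty, cfg, "cartesian"), "empty")
})

test_that("polar features move less than cartesian features under rotation", {
  # the operational core of the method: a 30-degree rotation perturbs the
  # polar-view representation less than the cartesian-view one, on average
  ds <- generate_dataset(n_train_per_class = 12, n_test_per_class = 16,
                         canvas_size = 32, pose_policy = "random-rotation",
                         seed = 21)
  train <- dataset_split(ds, "train")
  test <- dataset_split(ds, "test")
  cfg <- backbone_config(n_classes = 7, epochs = 6, seed = 5)
  ec <- train_extractor(train, cfg, "cartesian")
  ep <- train_extractor(train, cfg, "polar")
  imgs <- test$images                       # 112 pairs
  rots <- lapply(imgs, rotate_raster, degrees = 30)
  dist_ratio <- function(ext) {
    a <- extract_features(ext, imgs)
    b <- extract_features(ext, rots)
    num <- sqrt(rowSums((a - b)^2))
    den <- pmax(sqrt(rowSums(a^2)), 1e-8)
    num / den
  }
  expect_gt(length(imgs), 100)
  expect_lt(mean(dist_ratio(ep)), mean(dist_ratio(ec)))
})
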