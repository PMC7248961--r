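test_that("confusion matrix and metrics match a hand-computed fixture", {
  # 3 classes, 9 samples, worked out by hand:
  # true:      0 0 0 1 1 1 2 2 2
  # predicted: 0 1 0 1 1 0 2 2 1
  truth <- c(0, 0, 0, 1, 1, 1, 2, 2, 2)
  pred <- c(0, 1, 0, 1, 1, 0, 2, 2, 1)
  m <- confusion_and_metrics(truth, pred, 3)
  expect_identical(unname(m$confusion),
                   matrix(c(2L, 1L, 0L,
                            1L, 2L, 1L,
                            0L, 0L, 2L), 3, 3, byrow = FALSE))
  # columns: predicted. precision = TP / column sum; recall = TP / row sum
  expect_equal(m$precision, c(2 / 3, 2 / 4, 2 / 2))
  expect_equal(m$recall, c(2 / 3, 2 / 3, 2 / 3))
  expect_equal(m$accuracy, 6 / 9)
  expect_equal(m$macro_recall, 2 / 3)
  expect_equal(m$macro_precision, mean(c(2 / 3, 1 / 2, 1)))
  expect_equal(sum(m$confusion), length(truth))
  expect_equal(sum(diag(m$confusion)) / sum(m$confusion), m$accuracy)
})

test_that("metric edge cases follow the documented conventions", {
  # perfect prediction
  p <- confusion_and_metrics(0:4, 0:4, 5)
  expect_equal(p$accuracy, 1)
  expect_equal(p$macro_recall, 1)
  expect_true(all(p$precision == 1))
  # everything predicted as class 0 on balanced 2-class data
  q <- confusion_and_metrics(rep(0:1, each = 10), rep(0, 20), 2)
  expect_equal(q$recall, c(1, 0))
  expect_equal(q$accuracy, 0.5)
  expect_equal(q$precision[2], 0)     # 0/0 precision defined as 0
  # invalid labels rejected
  expect_error(confusion_and_metrics(c(0, 5), c(0, 1), 3), "n_classes")
  expect_error(confusion_and_metrics(c(0, 1), c(0, -1), 3), "n_classes")
  expect_error(confusion_and_metrics(0:2, 0:1, 3), "equal length")
})

test_that("a uniform-random predictor scores near chance on 7 classes", {
  set.seed(14)
  n <- 7 * 200
  truth <- rep(0:6, each = 200)
  pred <- sample(0:6, n, replace = TRUE)
  m <- confusion_and_metrics(truth, pred, 7)
  # binomial 99.9% bounds around 1/7
  bound <- 3.29 * sqrt((1 / 7) * (6 / 7) / n)
  expect_lt(abs(m$accuracy - 1 / 7), bound)
})

test_that("evaluate_method honours the method contracts", {
  ds <- generate_dataset(n_train_per_class = 8, n_test_per_class = 4,
                         canvas_size = 32, seed = 6)
  train <- dataset_split(ds, "train")
  test <- dataset_split(ds, "test")
  cfg <- backbone_config(n_classes = 7, epochs = 2, seed = 1)
  expect_error(evaluate_method("V", train, test, cfg), "unknown method")
  r1 <- evaluate_method("I", train, test, cfg, seed = 1)
  expect_s3_class(r1, "method_report")
  expect_length(r1$precision, 7)
  expect_true(all(r1$precision >= 0 & r1$precision <= 1))
  expect_equal(sum(r1$confusion), length(test$labels))
  expect_equal(sum(diag(r1$confusion)) / sum(r1$confusion), r1$accuracy)
  # method II trains on exactly 14x the training images
  expect_length(augment(train)$images, 14 * length(train$images))
  # reports are deterministic given the seed
  r2 <- evaluate_method("I", train, test, cfg, seed = 1)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("compare_all emits one report per method and seed, reproducibly", {
  ds <- generate_dataset(n_train_per_class = 6, n_test_per_class = 3,
                         canvas_size = 32, seed = 7)
  cfg <- backbone_config(n_classes = 7, epochs = 2, seed = 1)
  res <- compare_all(ds, methods = c("I", "III"), config = cfg, seeds = 1:2)
  expect_length(res$reports, 4)
  expect_identical(sort(unique(vapply(res$reports, `[[`, "", "method"))),
                   c("I", "III"))
  expect_identical(nrow(res$summary), 2L)
  expect_true(all(diff(res$summary$mean_accuracy) <= 0))  # ranked by accuracy
  res2 <- compare_all(ds, methods = c("I", "III"), config = cfg, seeds = 1:2)
  expect_identical(res$summary, res2$summary)
})
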