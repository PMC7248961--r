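#' Confusion matrix and per-class precision/recall
#'
#' Rows of the confusion matrix are the true class, columns the predicted
#' class. precision_c = TP_c / (TP_c + FP_c) with the 0/0 case defined as 0
#' (a class never predicted has precision 0); recall_c = TP_c / (TP_c +
#' FN_c). Macro averages are unweighted means over classes; on balanced
#' test sets macro recall equals overall accuracy.
#'
#' @param truth,predicted equal-length integer vectors of 0-based labels.
#' @param n_classes number of classes; labels outside [0, n_classes) are
#'   rejected.
#' @return list(confusion, precision, recall, accuracy, macro_precision,
#'   macro_recall, n).
#' @export
confusion_and_metrics <- function(truth, predicted, n_classes) {
  if (length(truth) != length(predicted)) {
    stop("label sequences must have equal length")
  }
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (any(truth < 0 | truth >= n_classes) ||
      any(predicted < 0 | predicted >= n_classes)) {
    stop("labels must lie in [0, n_classes)")
  }
  lv <- 0:(n_classes - 1)
  cm <- table(factor(truth, levels = lv), factor(predicted, levels = lv))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(true = lv, predicted = lv))
  tp <- diag(cm)
  colsum <- colSums(cm); rowsum_ <- rowSums(cm)
  precision <- ifelse(colsum == 0, 0, tp / colsum)
  recall <- ifelse(rowsum_ == 0, 0, tp / rowsum_)
  list(confusion = cm,
       precision = as.numeric(precision),
       recall = as.numeric(recall),
       accuracy = sum(tp) / length(truth),
       macro_precision = mean(precision),
       macro_recall = mean(recall),
       n = length(truth))
}

method_ids <- c("I", "II", "III", "IIII")

#' Run one comparison arm and report its metrics
#'
#' The four arms of the comparison:
#' \describe{
#'   \item{I}{plain CNN on Cartesian images (softmax predictions).}
#'   \item{II}{the same CNN trained on the 14x rotation/flip-augmented
#'     training set.}
#'   \item{III}{one-vs-rest SVM on the Cartesian CNN's first-fc-layer
#'     features.}
#'   \item{IIII}{one-vs-rest SVM on the spliced Cartesian + polar features
#'     from two view-specific CNNs (the proposed method).}
#' }
#' The test set is never augmented; method IIII runs every test image
#' through both views. Deterministic given `seed` (which offsets the
#' backbone and SVM seeds).
#'
#' @param method one of "I", "II", "III", "IIII".
#' @param train,test `labeled_dataset`s with disjoint samples; all images
#'   of each are used.
#' @param config a [backbone_config()].
#' @param svm an [svm_config()] (methods III/IIII).
#' @param transform a [transform_spec()] for the polar view.
#' @param seed integer run seed.
#' @param extractors optional pre-trained list(cartesian =, polar =,
#'   augmented =) to reuse across methods (as [compare_all()] does).
#' @return a `method_report`: list(method, accuracy, macro_precision,
#'   macro_recall, precision, recall, confusion, time_per_sample_ms, seed).
#' @export
evaluate_method <- function(method, train, test, config = backbone_config(),
                            svm = svm_config(), transform = transform_spec(),
                            seed = 1L, extractors = list()) {
  if (!method %in% method_ids) {
    stop("unknown method id: ", method, " (expected I, II, III or IIII)")
  }
  cfg <- config
  cfg$seed <- as.integer(config$seed + seed)
  svm_cfg <- svm
  svm_cfg$seed <- as.integer(svm$seed + seed)
  need <- function(name, builder) {
    if (is.null(extractors[[name]])) builder() else extractors[[name]]
  }
  t0 <- proc.time()[["elapsed"]]
  if (method == "I") {
    ext <- need("cartesian",
                function() train_extractor(train, cfg, "cartesian", transform))
    tp0 <- proc.time()[["elapsed"]]
    pred <- predict(ext, test$images)
    tms <- (proc.time()[["elapsed"]] - tp0) / length(test$images) * 1000
  } else if (method == "II") {
    ext <- need("augmented",
                function() train_extractor(augment(train), cfg, "cartesian",
                                           transform))
    tp0 <- proc.time()[["elapsed"]]
    pred <- predict(ext, test$images)
    tms <- (proc.time()[["elapsed"]] - tp0) / length(test$images) * 1000
  } else if (method == "III") {
    ext <- need("cartesian",
                function() train_extractor(train, cfg, "cartesian", transform))
    ftr <- extract_features(ext, train$images)
    clf <- fit_svm(ftr, train$labels, svm_cfg)
    tp0 <- proc.time()[["elapsed"]]
    pred <- predict_svm(clf, extract_features(ext, test$images))
    tms <- (proc.time()[["elapsed"]] - tp0) / length(test$images) * 1000
  } else {
    extc <- need("cartesian",
                 function() train_extractor(train, cfg, "cartesian", transform))
    extp <- need("polar",
                 function() train_extractor(train, cfg, "polar", transform))
    ftr <- splice(extract_features(extc, train$images),
                  extract_features(extp, train$images))
    clf <- fit_svm(ftr, train$labels, svm_cfg)
    tp0 <- proc.time()[["elapsed"]]
    fte <- splice(extract_features(extc, test$images),
                  extract_features(extp, test$images))
    pred <- predict_svm(clf, fte)
    tms <- (proc.time()[["elapsed"]] - tp0) / length(test$images) * 1000
  }
  m <- confusion_and_metrics(test$labels, pred, config$n_classes)
  structure(list(method = method,
                 accuracy = m$accuracy,
                 macro_precision = m$macro_precision,
                 macro_recall = m$macro_recall,
                 precision = m$precision,
                 recall = m$recall,
                 confusion = m$confusion,
                 class_names = train$class_names,
                 time_per_sample_ms = tms,
                 total_time_s = proc.time()[["elapsed"]] - t0,
                 seed = seed),
            class = "method_report")
}

#' Run the full method comparison over several seeds
#'
#' Trains the per-view extractors once per seed and evaluates every
#' requested method on the same untouched test split, then summarizes mean
#' and sd accuracy per method and ranks methods by mean accuracy.
#'
#' @param dataset a `labeled_dataset` with train/test split metadata (e.g.
#'   from [generate_dataset()] or [load_dataset()]).
#' @param methods subset of c("I", "II", "III", "IIII").
#' @param config,svm,transform see [evaluate_method()].
#' @param seeds integer vector of run seeds (>= 1 seed).
#' @return list(reports = list of `method_report`, summary = data.frame
#'   (method, mean_accuracy, sd_accuracy, mean_macro_recall, rank)).
#' @export
compare_all <- function(dataset, methods = method_ids,
                        config = backbone_config(), svm = svm_config(),
                        transform = transform_spec(), seeds = 1:5) {
  stopifnot(length(seeds) >= 1, all(methods %in% method_ids))
  train <- dataset_split(dataset, "train")
  test <- dataset_split(dataset, "test")
  reports <- list()
  for (sd_ in seeds) {
    cfg <- config
    cfg$seed <- as.integer(config$seed + sd_)
    extractors <- list()
    if (any(c("I", "III", "IIII") %in% methods)) {
      extractors$cartesian <- train_extractor(train, cfg, "cartesian",
                                              transform)
    }
    if ("IIII" %in% methods) {
      extractors$polar <- train_extractor(train, cfg, "polar", transform)
    }
    if ("II" %in% methods) {
      extractors$augmented <- train_extractor(augment(train), cfg,
                                              "cartesian", transform)
    }
    for (m in methods) {
      reports[[length(reports) + 1]] <-
        evaluate_method(m, train, test, config, svm, transform,
                        seed = sd_, extractors = extractors)
    }
  }
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  rec <- vapply(reports, function(r) r$macro_recall, numeric(1))
  mth <- vapply(reports, function(r) r$method, character(1))
  summary <- data.frame(
    method = methods,
    mean_accuracy = vapply(methods, function(m) mean(acc[mth == m]),
                           numeric(1)),
    sd_accuracy = vapply(methods, function(m) {
      if (sum(mth == m) > 1) stats::sd(acc[mth == m]) else 0
    }, numeric(1)),
    mean_macro_recall = vapply(methods, function(m) mean(rec[mth == m]),
                               numeric(1)),
    row.names = NULL)
  summary$rank <- rank(-summary$mean_accuracy, ties.method = "min")
  list(reports = reports, summary = summary[order(summary$rank), ])
}

#' @export
print.method_report <- function(x, ...) {
  cat(sprintf("Method %-4s accuracy %.4f  macro recall %.4f  (%.2f ms/sample, seed %d)\n",
              x$method, x$accuracy, x$macro_recall, x$time_per_sample_ms,
              x$seed))
  invisible(x)
}

# flatten reports into the tabular layout written by run_pipeline; timing is
# hardware-dependent and kept out of the deterministic report by default
reports_to_frame <- function(reports, include_timing = FALSE) {
  do.call(rbind, lapply(reports, function(r) {
    out <- data.frame(method = r$method, seed = r$seed,
                      class = c("overall", r$class_names),
                      precision = round(c(r$macro_precision, r$precision), 6),
                      recall = round(c(r$macro_recall, r$recall), 6),
                      accuracy = round(rep(r$accuracy,
                                           1 + length(r$precision)), 6),
                      row.names = NULL)
    if (include_timing) {
      out$time_ms_per_sample <- round(rep(r$time_per_sample_ms, nrow(out)), 4)
    }
    out
  }))
}
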