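#' Splice Cartesian and polar feature vectors
#'
#' Concatenates the Cartesian feature block first and the polar block
#' second, V = [Vc Vp], per batch of images. View tags (the `view`
#' attribute set by [extract_features()]) are checked so the block order is
#' enforced.
#'
#' @param vc n x dc feature matrix with view attribute "cartesian".
#' @param vp n x dp feature matrix with view attribute "polar".
#' @return n x (dc + dp) matrix with view attribute "fused".
#' @export
splice <- function(vc, vp) {
  if (!identical(attr(vc, "view"), "cartesian")) {
    stop("first block must carry view = 'cartesian'")
  }
  if (!identical(attr(vp, "view"), "polar")) {
    stop("second block must carry view = 'polar'")
  }
  if (nrow(vc) != nrow(vp)) stop("feature blocks must have equal row counts")
  out <- cbind(vc, vp)
  attr(out, "view") <- "fused"
  out
}

#' Configuration of the multiclass soft-margin SVM
#'
#' One-vs-rest scheme: one binary soft-margin SVM per class; prediction is
#' the argmax of the decision values, ties broken toward the lowest class
#' index. Feature standardization statistics are fitted on training data
#' only. When `tune` is TRUE the cost (and the RBF width) are chosen by a
#' small grid search with stratified cross-validation on the training split.
#'
#' @param kernel "linear" (default) or "rbf".
#' @param cost soft-margin cost C > 0.
#' @param gamma RBF width, or "auto" (1 / n_features on standardized data).
#' @param scaling "standardize" (default) or "none".
#' @param tune logical; grid-search C (and gamma) by cross-validation.
#' @param cost_grid,gamma_grid candidate values used when `tune` is TRUE.
#' @param folds number of stratified CV folds for tuning.
#' @param seed integer seed (fixes fold assignment).
#' @return an `svm_config`.
#' @export
svm_config <- function(kernel = c("linear", "rbf"), cost = 1, gamma = "auto",
                       scaling = c("standardize", "none"), tune = FALSE,
                       cost_grid = c(0.1, 1, 10),
                       gamma_grid = NULL, folds = 3L, seed = 1L) {
  kernel <- match.arg(kernel)
  scaling <- match.arg(scaling)
  if (!is.numeric(cost) || cost <= 0) stop("cost must be > 0")
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 scaling = scaling, tune = tune, cost_grid = cost_grid,
                 gamma_grid = gamma_grid, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "svm_config")
}

# canonical training order: by label, then lexicographically by features,
# so permuting the caller's sample order cannot change the fitted model
canonical_order <- function(x, labels) {
  do.call(order, c(list(labels), lapply(seq_len(ncol(x)), function(j) x[, j])))
}

fit_ovr <- function(x, labels, classes, kernel, cost, gamma) {
  kern <- if (kernel == "rbf") "radial" else kernel
  lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(x, y, type = "C-classification", kernel = kern,
               cost = cost, gamma = gamma, scale = FALSE)
  })
}

decision_matrix <- function(machines, x) {
  dv <- vapply(machines, function(m) {
    dv <- attr(stats::predict(m, x, decision.values = TRUE),
               "decision.values")
    # libsvm orients the value toward the first label seen in training;
    # the column name "a/b" means positive favours "a"
    s <- if (startsWith(colnames(dv)[1], "pos/")) 1 else -1
    s * as.numeric(dv)
  }, numeric(nrow(x)))
  if (!is.matrix(dv)) dv <- matrix(dv, nrow(x), length(machines))
  dv
}

#' Fit the one-vs-rest soft-margin SVM on feature vectors
#'
#' @param x n x d feature matrix (any view).
#' @param labels integer 0-based class labels, >= 2 distinct classes.
#' @param config an [svm_config()].
#' @return a `fusion_svm` (per-class machines, scaler, config).
#' @export
fit_svm <- function(x, labels, config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("features contain non-finite values")
  if (nrow(x) != length(labels)) stop("feature/label length mismatch")
  classes <- sort(unique(as.integer(labels)))
  if (length(classes) < 2) stop("need at least 2 classes")
  ord <- canonical_order(x, labels)
  x <- x[ord, , drop = FALSE]
  labels <- as.integer(labels)[ord]
  if (config$scaling == "standardize") {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    ctr <- numeric(ncol(x)); scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  gamma_of <- function(g) if (identical(g, "auto")) 1 / ncol(xs) else g
  cost <- config$cost
  gamma <- gamma_of(config$gamma)
  if (isTRUE(config$tune)) {
    gg <- if (config$kernel == "rbf") {
      if (is.null(config$gamma_grid)) gamma * c(0.25, 1, 4) else config$gamma_grid
    } else gamma
    grid <- expand.grid(cost = config$cost_grid, gamma = gg)
    folds <- with_seed(config$seed, stratified_folds(labels, config$folds))
    cv_acc <- vapply(seq_len(nrow(grid)), function(gi) {
      acc <- 0
      for (f in seq_len(config$folds)) {
        tr <- folds != f; te <- !tr
        if (length(unique(labels[tr])) < 2) return(0)
        m <- fit_ovr(xs[tr, , drop = FALSE], labels[tr], classes,
                     config$kernel, grid$cost[gi], grid$gamma[gi])
        dv <- decision_matrix(m, xs[te, , drop = FALSE])
        pred <- classes[max.col(dv, ties.method = "first")]
        acc <- acc + mean(pred == labels[te])
      }
      acc / config$folds
    }, numeric(1))
    best <- which.max(cv_acc)   # ties -> smallest cost first (grid order)
    cost <- grid$cost[best]; gamma <- grid$gamma[best]
  }
  machines <- fit_ovr(xs, labels, classes, config$kernel, cost, gamma)
  structure(list(machines = machines, classes = classes,
                 center = ctr, scale = scl, config = config,
                 cost = cost, gamma = gamma, n_features = ncol(x)),
            class = "fusion_svm")
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Predict class labels with a fitted one-vs-rest SVM
#'
#' Label = argmax over the per-class decision values; exact ties go to the
#' lowest class index.
#'
#' @param classifier a `fusion_svm` from [fit_svm()].
#' @param x n x d feature matrix; d must match the training features.
#' @return integer vector of 0-based class labels.
#' @export
predict_svm <- function(classifier, x) {
  stopifnot(inherits(classifier, "fusion_svm"))
  x <- as.matrix(x)
  if (ncol(x) != classifier$n_features) {
    stop("feature length mismatch: expected ", classifier$n_features,
         " got ", ncol(x))
  }
  xs <- sweep(sweep(x, 2, classifier$center), 2, classifier$scale, "/")
  dv <- decision_matrix(classifier$machines, xs)
  classifier$classes[max.col(dv, ties.method = "first")]
}
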