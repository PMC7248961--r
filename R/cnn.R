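#' Backbone configuration for the convolutional feature extractor
#'
#' Defines a small convolutional classifier: a stack of valid 3x3 (or k x k)
#' convolution + ReLU + max-pool blocks followed by fully connected layers
#' and a softmax head. The activations of the first fully connected layer
#' (after its ReLU) are the feature vector ("eigenvector") the fusion
#' classifier consumes, so the first entry of `fc` fixes the feature length.
#' Two extractors built from one config share the architecture exactly and
#' therefore have equal parameter counts, whatever view they are trained on.
#'
#' @param input_size (H, W, C) of the network input; images are resized to
#'   this before entering the network.
#' @param conv_blocks list of integer triples (out_channels, kernel, pool).
#' @param fc widths of the fully connected layers before the softmax head;
#'   the first width is the feature dimension.
#' @param n_classes number of output classes (>= 2).
#' @param epochs,batch_size,lr Adam training schedule.
#' @param seed integer seed fixing initialization and batch order.
#' @return a `backbone_config`.
#' @export
backbone_config <- function(input_size = c(32L, 32L, 1L),
                            conv_blocks = list(c(8L, 3L, 2L),
                                               c(16L, 3L, 2L),
                                               c(32L, 3L, 2L)),
                            fc = c(64L),
                            n_classes = 7L,
                            epochs = 12L, batch_size = 32L, lr = 2e-3,
                            seed = 1L) {
  stopifnot(length(input_size) == 3, input_size[3] %in% c(1L, 3L),
            length(fc) >= 1, n_classes >= 2, epochs >= 1, batch_size >= 1,
            lr > 0)
  structure(list(input_size = as.integer(input_size),
                 conv_blocks = lapply(conv_blocks, as.integer),
                 fc = as.integer(fc), n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, seed = as.integer(seed)),
            class = "backbone_config")
}

# ---- layer plumbing ---------------------------------------------------------

# spatial dimensions after each block
plan_shapes <- function(config) {
  h <- config$input_size[1]; w <- config$input_size[2]
  ch <- config$input_size[3]
  shapes <- list()
  for (b in seq_along(config$conv_blocks)) {
    blk <- config$conv_blocks[[b]]
    k <- blk[2]; p <- blk[3]
    oh <- h - k + 1; ow <- w - k + 1
    if (oh < 1 || ow < 1) stop("input too small for conv stack")
    ph <- if (p > 1) oh %/% p else oh
    pw <- if (p > 1) ow %/% p else ow
    shapes[[b]] <- list(in_h = h, in_w = w, in_c = ch, k = k, pool = p,
                        oh = oh, ow = ow, ph = ph, pw = pw, oc = blk[1])
    h <- ph; w <- pw; ch <- blk[1]
  }
  list(blocks = shapes, flat = h * w * ch)
}

# im2col gather indices for one image of layout [h, w, c] (column-major):
# K = k*k*c rows (ky fastest, then kx, then channel), oh*ow columns
# (oy fastest). Values are 1-based linear indices into the image vector.
im2col_index <- function(h, w, ch, k) {
  oh <- h - k + 1; ow <- w - k + 1
  ky <- rep(0:(k - 1), times = k * ch)
  kx <- rep(rep(0:(k - 1), each = k), times = ch)
  kc <- rep(0:(ch - 1), each = k * k)
  oy <- rep(0:(oh - 1), times = ow)
  ox <- rep(rep(0:(ow - 1), each = oh))
  # index(y, x, c) = y + x*h + c*h*w + 1
  outer(ky + kx * h + kc * h * w, oy + ox * h, "+") + 1L
}

# extend single-image indices to a batch of B images stored contiguously
batch_index <- function(idx, img_len, B) {
  full <- outer(as.vector(idx), (0:(B - 1)) * img_len, "+")
  dim(full) <- c(nrow(idx), ncol(idx) * B)
  full
}

# linear indices of the four candidates of each 2x2 pooling window within
# an (oh, ow, C, B) array, each shaped (ph, pw, C, B)
pool_indices <- function(oh, ow, ch, B, p) {
  ph <- oh %/% p; pw <- ow %/% p
  py <- rep(seq(0, by = p, length.out = ph), times = pw * ch * B)
  px <- rep(rep(seq(0, by = p, length.out = pw), each = ph), times = ch * B)
  pc <- rep(rep(0:(ch - 1), each = ph * pw), times = B)
  pb <- rep(0:(B - 1), each = ph * pw * ch)
  base <- py + px * oh + pc * oh * ow + pb * oh * ow * ch + 1L
  offs <- as.vector(outer(0:(p - 1), (0:(p - 1)) * oh, "+"))
  lapply(offs, function(o) base + o)
}

init_params <- function(config) {
  plan <- plan_shapes(config)
  params <- list(conv = list(), fc = list())
  for (b in seq_along(plan$blocks)) {
    s <- plan$blocks[[b]]
    fan_in <- s$k * s$k * s$in_c
    params$conv[[b]] <- list(
      W = matrix(stats::rnorm(s$oc * fan_in, 0, sqrt(2 / fan_in)),
                 s$oc, fan_in),
      b = numeric(s$oc))
  }
  widths <- c(plan$flat, config$fc, config$n_classes)
  for (l in seq_len(length(widths) - 1)) {
    params$fc[[l]] <- list(
      W = matrix(stats::rnorm(widths[l + 1] * widths[l], 0,
                              sqrt(2 / widths[l])),
                 widths[l + 1], widths[l]),
      b = numeric(widths[l + 1]))
  }
  params
}

# forward pass over a batch; X is an (H, W, C, B) array.
# Returns logits plus (optionally) every intermediate needed for backprop.
forward_cnn <- function(params, config, plan, X, keep = FALSE) {
  B <- dim(X)[4]
  a <- X
  cache <- list(conv = vector("list", length(plan$blocks)))
  for (bi in seq_along(plan$blocks)) {
    s <- plan$blocks[[bi]]
    idx <- batch_index(im2col_index(s$in_h, s$in_w, s$in_c, s$k),
                       s$in_h * s$in_w * s$in_c, B)
    cols <- a[idx]
    dim(cols) <- dim(idx)
    z <- params$conv[[bi]]$W %*% cols + params$conv[[bi]]$b
    relu_mask <- z > 0
    z <- z * relu_mask                       # oc x (oh*ow*B)
    zz <- z
    dim(zz) <- c(s$oc, s$oh, s$ow, B)
    A <- aperm(zz, c(2, 3, 1, 4))            # (oh, ow, oc, B)
    if (s$pool > 1) {
      li <- pool_indices(s$oh, s$ow, s$oc, B, s$pool)
      cand <- lapply(li, function(ix) A[ix])
      M <- do.call(pmax, cand)
      # first-wins argmax for deterministic gradient routing
      chosen <- li[[1]]
      decided <- cand[[1]] >= M
      for (j in 2:length(li)) {
        take <- !decided & cand[[j]] >= M
        chosen[take] <- li[[j]][take]
        decided <- decided | take
      }
      out <- array(M, c(s$ph, s$pw, s$oc, B))
    } else {
      chosen <- NULL
      out <- A
    }
    if (keep) {
      cache$conv[[bi]] <- list(idx = idx, cols = cols, relu = relu_mask,
                               chosen = chosen, pre_dim = c(s$oh, s$ow, s$oc, B))
    }
    a <- out
  }
  f <- a
  dim(f) <- c(plan$flat, B)
  acts <- list()
  nf <- length(params$fc)
  for (l in seq_len(nf)) {
    f_in <- f
    f <- params$fc[[l]]$W %*% f + params$fc[[l]]$b
    if (l < nf) {
      f <- f * (f > 0)
      if (l == 1) feats <- f                 # first fc layer, post-ReLU
    }
    if (keep) acts[[l]] <- f_in
  }
  if (nf == 1) feats <- f                    # degenerate single-fc case
  list(logits = f, features = feats,
       cache = if (keep) c(cache, list(acts = acts, fc_out = NULL)) else NULL)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

backward_cnn <- function(params, config, plan, fwd, y_onehot) {
  B <- ncol(y_onehot)
  grads <- list(conv = vector("list", length(plan$blocks)),
                fc = vector("list", length(params$fc)))
  p <- softmax_cols(fwd$logits)
  delta <- (p - y_onehot) / B                # n_classes x B
  nf <- length(params$fc)
  for (l in nf:1) {
    a_in <- fwd$cache$acts[[l]]
    grads$fc[[l]] <- list(W = delta %*% t(a_in), b = rowSums(delta))
    if (l > 1) {
      delta <- t(params$fc[[l]]$W) %*% delta
      delta <- delta * (a_in > 0)            # a_in is post-ReLU of layer l-1
    } else {
      delta <- t(params$fc[[l]]$W) %*% delta # gradient w.r.t. flat features
    }
  }
  nb <- length(plan$blocks)
  for (bi in nb:1) {
    s <- plan$blocks[[bi]]
    cc <- fwd$cache$conv[[bi]]
    if (s$pool > 1) {
      dpre <- numeric(prod(cc$pre_dim))
      dpre[cc$chosen] <- as.vector(delta)
      dim(dpre) <- cc$pre_dim                # (oh, ow, oc, B)
    } else {
      dpre <- array(as.vector(delta), cc$pre_dim)
    }
    dz <- aperm(dpre, c(3, 1, 2, 4))         # (oc, oh, ow, B)
    dim(dz) <- c(s$oc, s$oh * s$ow * B)
    dz <- dz * cc$relu
    grads$conv[[bi]] <- list(W = dz %*% t(cc$cols), b = rowSums(dz))
    if (bi > 1) {
      dcols <- t(params$conv[[bi]]$W) %*% dz # K x (oh*ow*B)
      dx <- numeric(s$in_h * s$in_w * s$in_c * B)
      for (r in seq_len(nrow(cc$idx))) {
        ii <- cc$idx[r, ]
        dx[ii] <- dx[ii] + dcols[r, ]
      }
      sp <- plan$blocks[[bi - 1]]
      delta <- array(dx, c(sp$ph, sp$pw, sp$oc, B))
    }
  }
  grads
}

adam_init <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk(params, grads, state$m, state$v)
}

# ---- view preparation -------------------------------------------------------

#' Polar transform parameters used by the polar view loader
#'
#' The polar resampling is applied at (n_rho x n_theta) resolution first and
#' the result is then resized to the backbone input size.
#'
#' @param n_rho,n_theta polar raster size (defaults 64 x 64).
#' @param log_base NULL for the linear-radius polar transform (default) or a
#'   base > 1 for log-polar.
#' @param interpolation "bilinear" or "nearest".
#' @param r_max_policy,center_mode see [polar_grid_for()].
#' @return a `transform_spec`.
#' @export
transform_spec <- function(n_rho = 64L, n_theta = 64L, log_base = NULL,
                           interpolation = "bilinear",
                           r_max_policy = "inscribed",
                           center_mode = "geometric") {
  structure(list(n_rho = as.integer(n_rho), n_theta = as.integer(n_theta),
                 log_base = log_base, interpolation = interpolation,
                 r_max_policy = r_max_policy, center_mode = center_mode),
            class = "transform_spec")
}

# apply the view (identity or polar transform), channel conversion and the
# input-size standardization; returns an (H, W, C, N) array
prepare_view <- function(images, view, config, transform = transform_spec()) {
  h <- config$input_size[1]; w <- config$input_size[2]
  ch <- config$input_size[3]
  n <- length(images)
  X <- array(0, c(h, w, ch, n))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (view == "polar") {
      grid <- polar_grid_for(img, n_rho = transform$n_rho,
                             n_theta = transform$n_theta,
                             log_base = transform$log_base,
                             r_max_policy = transform$r_max_policy,
                             center_mode = transform$center_mode)
      img <- polar_resample(img, grid, transform$interpolation)
    }
    d <- raster_dim(img)
    if (ch == 1 && d$c == 3) img <- to_gray(img)
    img <- resize_raster(img, h, w)
    if (ch == 3 && raster_dim(img)$c == 1) {
      img <- array(rep(img, 3), c(h, w, 3))
    }
    if (ch == 1) X[, , 1, i] <- img else X[, , , i] <- img
  }
  X
}

# ---- training / inference ---------------------------------------------------

#' Train a convolutional feature extractor on one view
#'
#' Trains the configured backbone with softmax cross-entropy and Adam on the
#' dataset's training images, seen either directly ("cartesian") or through
#' the polar transform ("polar"). The two views use the same architecture;
#' they are trained separately and do not share weights. Training is
#' deterministic given `config$seed` (fixed initialization and batch order).
#'
#' @param train a `labeled_dataset` (its `images`/`labels` are used as the
#'   training set).
#' @param config a [backbone_config()].
#' @param view "cartesian" or "polar".
#' @param transform a [transform_spec()] for the polar view.
#' @return a trained `cnn_extractor` (weights, config, view, loss history).
#' @export
train_extractor <- function(train, config, view = c("cartesian", "polar"),
                            transform = transform_spec()) {
  view <- match.arg(view)
  stopifnot(inherits(config, "backbone_config"))
  if (length(train$images) == 0) stop("empty training dataset")
  labs <- train$labels
  if (max(labs) >= config$n_classes || min(labs) < 0) {
    stop("labels exceed configured n_classes")
  }
  X <- prepare_view(train$images, view, config, transform)
  n <- dim(X)[4]
  plan <- plan_shapes(config)
  losses <- numeric(config$epochs)
  params <- NULL
  with_seed(config$seed, {
    params <- init_params(config)
    state <- list(m = adam_init(params), v = adam_init(params))
    t <- 0
    onehot <- diag(config$n_classes)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        take <- ord[start:min(start + config$batch_size - 1, n)]
        Xb <- X[, , , take, drop = FALSE]
        yb <- onehot[, labs[take] + 1, drop = FALSE]
        fwd <- forward_cnn(params, config, plan, Xb, keep = TRUE)
        p <- softmax_cols(fwd$logits)
        ep_loss <- ep_loss - sum(log(pmax(colSums(p * yb), 1e-12)))
        grads <- backward_cnn(params, config, plan, fwd, yb)
        t <- t + 1
        upd <- adam_step(params, grads, state, config$lr, t)
        params <- upd$p
        state <- list(m = upd$m, v = upd$v)
      }
      losses[ep] <- ep_loss / n
    }
  })
  structure(list(params = params, config = config, plan = plan, view = view,
                 transform = transform, loss = losses, trained = TRUE),
            class = "cnn_extractor")
}

batched_forward <- function(extractor, images, batch = 64L) {
  X <- prepare_view(images, extractor$view, extractor$config,
                    extractor$transform)
  n <- dim(X)[4]
  feats <- NULL; logits <- NULL
  for (start in seq(1, n, by = batch)) {
    take <- start:min(start + batch - 1, n)
    fwd <- forward_cnn(extractor$params, extractor$config, extractor$plan,
                       X[, , , take, drop = FALSE])
    feats <- cbind(feats, fwd$features)
    logits <- cbind(logits, fwd$logits)
  }
  list(features = feats, logits = logits)
}

#' Extract feature vectors from a trained extractor
#'
#' Taps the activations of the first fully connected layer (after its ReLU),
#' one fixed-length vector per image; a pure function of the trained weights
#' and the inputs.
#'
#' @param extractor a trained `cnn_extractor`.
#' @param images list of image rasters.
#' @return an n x d numeric matrix with attribute `view` set to the
#'   extractor's view ("cartesian" or "polar").
#' @export
extract_features <- function(extractor, images) {
  stopifnot(inherits(extractor, "cnn_extractor"))
  if (!isTRUE(extractor$trained)) stop("extractor is not trained")
  out <- t(batched_forward(extractor, images)$features)
  attr(out, "view") <- extractor$view
  out
}

#' Predict class labels with a trained extractor
#'
#' @param object a trained `cnn_extractor`.
#' @param images list of image rasters.
#' @param ... unused.
#' @return integer vector of 0-based class labels (argmax of the softmax).
#' @export
predict.cnn_extractor <- function(object, images, ...) {
  if (!isTRUE(object$trained)) stop("extractor is not trained")
  logits <- batched_forward(object, images)$logits
  max.col(t(logits), ties.method = "first") - 1L
}

#' Total number of trainable parameters of an extractor
#' @param extractor a `cnn_extractor`.
#' @return integer parameter count.
#' @export
n_parameters <- function(extractor) {
  sum(rapply(extractor$params, length, how = "unlist"))
}
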