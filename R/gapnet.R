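# A small convolutional classifier with a global-average-pooling head.
#
# The network exists to expose, exactly and inspectably, every quantity the
# CAM and FGSM machinery consumes: the last-conv feature stack g_k(x,y), the
# pooled features G^k, the linear head weights omega_k^i (bias fixed at 0),
# the class scores S_i and probabilities P_i, and the input gradient
# grad_x L(x, y, phi) via full backpropagation. Convolutions are im2col +
# BLAS matrix products; everything is plain R, deterministic under a seed.
#
# Pooling convention: G^k is the spatial SUM of g_k over the last-conv grid
# (not the mean), so that S_i = sum_{x,y} M_i(x,y) holds with no scale
# factor. A mean-pooling backend would have to rescale omega by the grid
# size to preserve that identity.

#' Classifier architecture specification
#'
#' @param input_size Square input side in pixels.
#' @param channels Integer vector of output channels per conv block; the last
#'   entry is K, the number of feature maps entering global average pooling.
#' @param kernel_sizes Kernel side per block.
#' @param strides Stride per block.
#' @param classes Number of classes (2: benign = class 1, malignant = class 2).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(input_size = 128L,
                       channels = c(8L, 16L, 32L),
                       kernel_sizes = c(5L, 3L, 3L),
                       strides = c(2L, 2L, 2L),
                       classes = 2L) {
  stopifnot(length(channels) == length(kernel_sizes),
            length(channels) == length(strides),
            classes >= 2)
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 kernel_sizes = as.integer(kernel_sizes),
                 strides = as.integer(strides),
                 classes = as.integer(classes)),
            class = "model_spec")
}

#' Training configuration
#'
#' @param epochs Maximum number of epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param val_fraction Fraction of the dataset held out for validation,
#'   in (0, 1).
#' @param seed Seed controlling initialization, the split and shuffling.
#' @param early_stop_auc If non-`NULL`, stop once validation AUC reaches this
#'   value.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 15L, batch_size = 32L,
                         learning_rate = 1e-3, val_fraction = 0.2,
                         seed = 1L, early_stop_auc = NULL) {
  stopifnot(epochs >= 1, val_fraction > 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction,
                 seed = as.integer(seed),
                 early_stop_auc = early_stop_auc),
            class = "train_config")
}

# im2col geometry for one conv layer: a (n_positions x kh*kw*C) matrix of
# 1-based linear indices into the zero-padded input array (Hp, Wp, C).
conv_geom <- function(H, W, C, k, stride, pad) {
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oy <- rep(seq_len(Ho), times = Wo)
  ox <- rep(seq_len(Wo), each = Ho)
  corner <- (ox - 1L) * stride * Hp + (oy - 1L) * stride
  patch <- as.vector(outer(seq_len(k) - 1L, (seq_len(k) - 1L) * Hp, "+"))
  off <- as.vector(outer(patch, (seq_len(C) - 1L) * (Hp * Wp), "+"))
  idx <- outer(corner, off, "+") + 1L
  # col2im scatter plan: segmented sums over the gathered-index multiset,
  # so backprop needs no hashing (cumsum over a precomputed sort order)
  iv <- as.vector(idx)
  ord <- order(iv)
  runs <- rle(iv[ord])
  list(H = H, W = W, C = C, k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, npos = Ho * Wo, idx = idx,
       scatter_ord = ord, scatter_targets = runs$values,
       scatter_ends = cumsum(runs$lengths))
}

#' Initialize a classifier
#'
#' He-scaled random conv weights; the head starts near zero. The head has no
#' bias term by construction.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @return An object of class `gapnet`.
#' @export
gapnet_init <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, {
    n_blocks <- length(spec$channels)
    geom <- vector("list", n_blocks)
    layers <- vector("list", n_blocks)
    H <- spec$input_size
    C <- 1L
    for (l in seq_len(n_blocks)) {
      k <- spec$kernel_sizes[l]
      g <- conv_geom(H, H, C, k, spec$strides[l], pad = k %/% 2L)
      fan_in <- k * k * C
      Cout <- spec$channels[l]
      layers[[l]] <- list(
        W = matrix(stats::rnorm(fan_in * Cout, 0, sqrt(2 / fan_in)),
                   fan_in, Cout),
        b = numeric(Cout)
      )
      geom[[l]] <- g
      H <- g$Ho
      C <- Cout
    }
    K <- spec$channels[n_blocks]
    head <- matrix(stats::rnorm(K * spec$classes, 0, 1e-3), K, spec$classes)
    structure(list(spec = spec, layers = layers, head = head, geom = geom,
                   grid = c(H, H), K = K),
              class = "gapnet")
  })
}

#' @export
print.gapnet <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b),
                      numeric(1))) + length(x$head)
  cat(sprintf(
    "<gapnet> input %dx%d, %d conv blocks, K=%d feature maps on a %dx%d grid, %d parameters\n",
    x$spec$input_size, x$spec$input_size, length(x$layers), x$K,
    x$grid[1], x$grid[2], n_par))
  invisible(x)
}

# Stack a list of images / a single matrix into an (H, W, B) array.
as_image_batch <- function(images, input_size) {
  if (is.matrix(images)) images <- list(images)
  if (inherits(images, "nodule_dataset") ||
      (is.list(images) && length(images) && inherits(images[[1]], "synthetic_nodule"))) {
    images <- lapply(images, function(s) s$image)
  }
  B <- length(images)
  x <- array(0, c(input_size, input_size, B))
  for (b in seq_len(B)) {
    img <- images[[b]]
    if (!is.matrix(img) || nrow(img) != input_size || ncol(img) != input_size) {
      stop(sprintf("image %d does not match the model input size %dx%d",
                   b, input_size, input_size), call. = FALSE)
    }
    x[, , b] <- img
  }
  x
}

# Forward pass over a batch; optionally keeps per-layer caches for backprop.
gapnet_forward_batch <- function(model, x, keep_cache = FALSE) {
  B <- dim(x)[3]
  n_blocks <- length(model$layers)
  caches <- if (keep_cache) vector("list", n_blocks) else NULL
  # canonical preprocessing: center intensities (gradient wrt x unaffected)
  # activations live as (B*npos x C) matrices between layers; the padded
  # array view is materialized per image only for the im2col gather
  a <- matrix(x - 0.5, ncol = 1L)
  for (l in seq_len(n_blocks)) {
    g <- model$geom[[l]]
    W <- model$layers[[l]]$W
    bces <- model$layers[[l]]$b
    cols <- matrix(0, B * g$npos, g$k * g$k * g$C)
    xpad <- array(0, c(g$Hp, g$Wp, g$C))
    rows <- seq_len(g$npos)
    nin <- g$H * g$W
    iy <- g$pad + seq_len(g$H)
    ix <- g$pad + seq_len(g$W)
    for (b in seq_len(B)) {
      xpad[iy, ix, ] <- a[(b - 1L) * nin + seq_len(nin), ]
      cols[(b - 1L) * g$npos + rows, ] <- xpad[g$idx]
    }
    z <- cols %*% W
    for (cc in seq_along(bces)) z[, cc] <- z[, cc] + bces[cc]
    act <- z > 0
    a <- z * act
    if (keep_cache) caches[[l]] <- list(cols = cols, act = act)
  }
  K <- model$K
  npos_last <- prod(model$grid)
  feat <- array(0, c(model$grid[1], model$grid[2], K, B))  # (Hg, Wg, K, B)
  for (b in seq_len(B)) {
    feat[, , , b] <- a[(b - 1L) * npos_last + seq_len(npos_last), ]
  }
  # G^k: spatial SUM over the last-conv grid
  Gmat <- t(matrix(colSums(matrix(feat, npos_last, K * B)), K, B))  # B x K
  S <- Gmat %*% model$head                                          # B x classes
  Smax <- apply(S, 1, max)
  expS <- exp(S - Smax)
  P <- expS / rowSums(expS)
  list(feat = feat, G = Gmat, S = S, P = P, caches = caches, B = B)
}

# Backward pass from dS (B x classes). Returns parameter gradients and,
# optionally, gradients with respect to the input images.
gapnet_backward_batch <- function(model, fwd, dS, need_input_grad = FALSE) {
  B <- fwd$B
  n_blocks <- length(model$layers)
  dHead <- t(fwd$G) %*% dS
  dG <- dS %*% t(model$head)                  # B x K
  npos_last <- prod(model$grid)
  dA <- dG[rep(seq_len(B), each = npos_last), , drop = FALSE]
  grads <- vector("list", n_blocks)
  for (l in rev(seq_len(n_blocks))) {
    g <- model$geom[[l]]
    cache <- fwd$caches[[l]]
    dZ <- dA * cache$act
    grads[[l]] <- list(W = crossprod(cache$cols, dZ), b = colSums(dZ))
    if (l > 1L || need_input_grad) {
      dcols <- dZ %*% t(model$layers[[l]]$W)     # (B*npos) x (k*k*C)
      npad <- g$Hp * g$Wp * g$C
      rows <- seq_len(g$npos)
      ends <- g$scatter_ends
      dA_prev <- matrix(0, B * g$H * g$W, g$C)   # layer input as (npos_prev) x C
      for (b in seq_len(B)) {
        v <- as.vector(dcols[(b - 1L) * g$npos + rows, , drop = FALSE])
        cs <- cumsum(v[g$scatter_ord])
        dxpad <- numeric(npad)
        dxpad[g$scatter_targets] <- diff(c(0, cs[ends]))
        dxpad <- array(dxpad, c(g$Hp, g$Wp, g$C))
        dx <- dxpad[g$pad + seq_len(g$H), g$pad + seq_len(g$W), , drop = FALSE]
        dA_prev[(b - 1L) * (g$H * g$W) + seq_len(g$H * g$W), ] <-
          matrix(dx, g$H * g$W, g$C)
      }
      dA <- dA_prev
    }
  }
  out <- list(layers = grads, head = dHead)
  if (need_input_grad) {
    H <- model$spec$input_size
    dx_imgs <- array(0, c(H, H, B))
    for (b in seq_len(B)) {
      dx_imgs[, , b] <- matrix(dA[(b - 1L) * H * H + seq_len(H * H), 1], H, H)
    }
    out$input_grad <- dx_imgs
  }
  out
}

#' Forward pass on one image
#'
#' @param model A trained or initialized [gapnet_init()] model.
#' @param image Numeric matrix matching the model's input size.
#' @return An object of class `classifier_output` with `feature_stack`
#'   (the last-conv maps g_k), `pooled` (G^k, the spatial sums),
#'   `class_scores` (S_i), `probabilities` (P_i), `predicted_class`
#'   (1 = benign, 2 = malignant) and `head_weights` (omega, K x classes).
#' @export
gapnet_forward <- function(model, image) {
  stopifnot(inherits(model, "gapnet"))
  x <- as_image_batch(image, model$spec$input_size)
  fwd <- gapnet_forward_batch(model, x)
  structure(list(
    feature_stack = fwd$feat[, , , 1],
    pooled = fwd$G[1, ],
    class_scores = fwd$S[1, ],
    probabilities = fwd$P[1, ],
    predicted_class = which.max(fwd$P[1, ]),
    head_weights = model$head
  ), class = "classifier_output")
}

#' Batch class probabilities
#'
#' @param model A `gapnet` model.
#' @param images List of image matrices (or a `nodule_dataset`).
#' @param chunk Internal batch size.
#' @return Matrix of class probabilities, one row per image.
#' @export
gapnet_predict <- function(model, images, chunk = 32L) {
  if (is.matrix(images)) images <- list(images)
  if (inherits(images, "nodule_dataset") ||
      (is.list(images) && length(images) && inherits(images[[1]], "synthetic_nodule"))) {
    images <- lapply(images, function(s) s$image)
  }
  n <- length(images)
  P <- matrix(NA_real_, n, model$spec$classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    x <- as_image_batch(images[i:j], model$spec$input_size)
    P[i:j, ] <- gapnet_forward_batch(model, x)$P
    i <- j + 1L
  }
  colnames(P) <- c("benign", "malignant")[seq_len(min(2L, ncol(P)))]
  P
}

label_to_index <- function(label) {
  if (is.character(label)) {
    match(match.arg(label, c("benign", "malignant")), c("benign", "malignant"))
  } else if (all(label %in% c(0, 1))) {
    as.integer(label) + 1L
  } else {
    as.integer(label)
  }
}

#' Input gradient of the training loss
#'
#' Computes `grad_x L(x, y, phi)` by full backpropagation, where `L` is the
#' cross-entropy on the supplied label — the quantity whose sign field drives
#' the FGSM perturbation.
#'
#' @param model A `gapnet` model.
#' @param image Image matrix.
#' @param label `"benign"`/`"malignant"`, or 0/1.
#' @return Gradient matrix of the same shape as `image`.
#' @export
input_gradient <- function(model, image, label) {
  input_gradients(model, list(image), label)[[1]]
}

#' Input gradients for a batch of images
#'
#' @param model A `gapnet` model.
#' @param images List of image matrices (or a `nodule_dataset`).
#' @param labels Vector of labels, recycled if length 1.
#' @param chunk Internal batch size.
#' @return List of gradient matrices.
#' @export
input_gradients <- function(model, images, labels, chunk = 32L) {
  if (is.matrix(images)) images <- list(images)
  if (inherits(images, "nodule_dataset") ||
      (is.list(images) && length(images) && inherits(images[[1]], "synthetic_nodule"))) {
    if (missing(labels)) labels <- vapply(images, function(s) s$label, character(1))
    images <- lapply(images, function(s) s$image)
  }
  n <- length(images)
  if (length(labels) == 1L) labels <- rep(labels, n)
  yidx <- vapply(labels, label_to_index, integer(1))
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    x <- as_image_batch(images[i:j], model$spec$input_size)
    fwd <- gapnet_forward_batch(model, x, keep_cache = TRUE)
    dS <- fwd$P
    for (b in seq_len(j - i + 1L)) {
      dS[b, yidx[i + b - 1L]] <- dS[b, yidx[i + b - 1L]] - 1
    }
    bwd <- gapnet_backward_batch(model, fwd, dS, need_input_grad = TRUE)
    for (b in seq_len(j - i + 1L)) out[[i + b - 1L]] <- bwd$input_grad[, , b]
    i <- j + 1L
  }
  out
}

adam_new <- function(param) {
  lapply(param, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mh <- st$m / (1 - beta1^t)
  vh <- st$v / (1 - beta2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), st = st)
}

#' Train the classifier
#'
#' Adam on the softmax cross-entropy, with a seeded train/validation split.
#' Reproducible: the same spec, data and seed give bit-identical parameters.
#'
#' @param spec A [model_spec()] (or an already initialized `gapnet` to
#'   continue training).
#' @param dataset A `nodule_dataset` containing both classes.
#' @param cfg A [train_config()].
#' @return List with `model`, `metrics` (per-epoch data frame: epoch, train
#'   loss, validation AUC) and `val_idx` (indices of the held-out nodules).
#' @export
gapnet_train <- function(spec, dataset, cfg = train_config()) {
  labels <- dataset_label_int(dataset)
  if (length(unique(labels)) < 2L) {
    stop("training requires both classes in the dataset", call. = FALSE)
  }
  model <- if (inherits(spec, "gapnet")) spec else gapnet_init(spec, seed = cfg$seed)
  images <- lapply(dataset, function(s) s$image)
  n <- length(images)
  with_seed(cfg$seed + 7L, {
    # stratified split: both classes stay represented in the training fold
    val_idx <- sort(unlist(lapply(c(0L, 1L), function(cl) {
      cl_idx <- which(labels == cl)
      n_val <- floor(cfg$val_fraction * length(cl_idx))
      if (n_val > 0) sample(cl_idx, n_val) else integer(0)
    })))
    tr_idx <- setdiff(seq_len(n), val_idx)
    st <- list(layers = lapply(model$layers, function(l) adam_new(l)),
               head = adam_new(list(W = model$head))$W)
    metrics <- data.frame(epoch = integer(), loss = numeric(),
                          val_auc = numeric())
    t_step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0
      n_seen <- 0L
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + cfg$batch_size - 1L, length(ord))
        sel <- ord[i:j]
        B <- length(sel)
        x <- as_image_batch(images[sel], model$spec$input_size)
        fwd <- gapnet_forward_batch(model, x, keep_cache = TRUE)
        yi <- labels[sel] + 1L
        pick <- cbind(seq_len(B), yi)
        ep_loss <- ep_loss - sum(log(pmax(fwd$P[pick], 1e-12)))
        n_seen <- n_seen + B
        dS <- fwd$P
        dS[pick] <- dS[pick] - 1
        dS <- dS / B
        bwd <- gapnet_backward_batch(model, fwd, dS)
        t_step <- t_step + 1L
        for (l in seq_along(model$layers)) {
          up <- adam_step(model$layers[[l]]$W, bwd$layers[[l]]$W,
                          st$layers[[l]]$W, cfg$learning_rate, t_step)
          model$layers[[l]]$W <- up$p; st$layers[[l]]$W <- up$st
          up <- adam_step(model$layers[[l]]$b, bwd$layers[[l]]$b,
                          st$layers[[l]]$b, cfg$learning_rate, t_step)
          model$layers[[l]]$b <- up$p; st$layers[[l]]$b <- up$st
        }
        up <- adam_step(model$head, bwd$head, st$head, cfg$learning_rate, t_step)
        model$head <- up$p; st$head <- up$st
        i <- j + 1L
      }
      val_p <- gapnet_predict(model, images[val_idx])[, 2]
      val_auc <- if (length(unique(labels[val_idx])) == 2L) {
        roc_auc(labels[val_idx], val_p)$auc
      } else NA_real_
      metrics <- rbind(metrics, data.frame(
        epoch = ep, loss = ep_loss / n_seen, val_auc = val_auc))
      if (!is.null(cfg$early_stop_auc) && !is.na(val_auc) &&
          val_auc >= cfg$early_stop_auc) break
    }
    list(model = model, metrics = metrics, val_idx = val_idx)
  })
}

#' Save / load a model checkpoint
#'
#' @param model A `gapnet` model.
#' @param path Checkpoint file path.
#' @return `save_gapnet` invisibly returns `path`; `load_gapnet` returns the
#'   model.
#' @export
save_gapnet <- function(model, path) {
  stopifnot(inherits(model, "gapnet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_gapnet
#' @export
load_gapnet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "gapnet"))
  model
}
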