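# Three-direction classifier: a small convolutional network mapping
# flow-color images to insertion / withdrawal / stop.
#
# The network is an input stage (color image resized to 170x150), a feature
# extraction stage of three convolution blocks (3x3 convolution -> ReLU ->
# 2x2 max pooling), and a classification stage (fully connected hidden layer
# with dropout 0.5, then a softmax over the three classes). Because the
# classes differ mainly in the hue distribution of the flow coloring, the
# network does not need to be deep. Layers are implemented directly on BLAS
# matrix products via im2col patch extraction; training is mini-batch SGD
# with momentum and L2 weight decay, with hyperparameters drawn by
# randomized search (log-uniform for learning rate and L2, uniform for
# momentum) and selected on a validation split.

DIRECTION_LEVELS <- c("insertion", "withdrawal", "stop")
DIRECTION_VALUES <- c(insertion = 1, withdrawal = -1, stop = 0)

#' Configuration for the three-direction CNN
#'
#' Defaults follow the reference architecture: 170x150 color input, three
#' 3x3 convolution blocks (16/32/64 filters, each followed by ReLU and 2x2
#' max pooling), a 128-unit fully connected layer with dropout 0.5, softmax
#' over 3 classes, batch size 128, and randomized hyperparameter search over
#' learning rate in `[1e-7, 1e-2]` (log-uniform), SGD momentum in
#' `[0.8, 0.99]` (uniform) and L2 regularization in `[1e-10, 1e-2]`
#' (log-uniform).
#'
#' @param input_width,input_height Input image size in pixels.
#' @param conv_filters Integer vector, one filter count per convolution block.
#' @param kernel_size Convolution kernel side (square, stride 1, no padding).
#' @param fc_units Width of the fully connected hidden layer.
#' @param dropout_rate Dropout probability on the hidden layer, in `[0, 1)`.
#' @param n_classes Number of output classes.
#' @param batch_size Mini-batch size for SGD.
#' @param learning_rate_range,momentum_range,l2_range Randomized-search
#'   ranges, each `c(low, high)` with `low < high`.
#' @param n_search_draws Number of random hyperparameter draws; each draw is
#'   trained for `search_epochs` epochs and ranked by validation accuracy.
#'   With 0 draws the fixed `learning_rate`/`momentum`/`l2` are used.
#' @param search_epochs Epochs per search draw.
#' @param n_epochs Training epochs for the selected draw (early stopping on
#'   validation loss with the given `patience`).
#' @param patience Early-stopping patience in epochs.
#' @param validation_fraction Fraction of the training set held out for
#'   validation during search and early stopping.
#' @param learning_rate,momentum,l2 Fixed hyperparameters used when
#'   `n_search_draws = 0`.
#' @param seed Integer seed governing initialization, shuffling, search draws
#'   and dropout.
#' @return A `cnn_config` object.
#' @export
cnn_config <- function(input_width = 170L, input_height = 150L,
                       conv_filters = c(16L, 32L, 64L), kernel_size = 3L,
                       fc_units = 128L, dropout_rate = 0.5, n_classes = 3L,
                       batch_size = 128L,
                       learning_rate_range = c(1e-7, 1e-2),
                       momentum_range = c(0.8, 0.99),
                       l2_range = c(1e-10, 1e-2),
                       n_search_draws = 4L, search_epochs = 2L,
                       n_epochs = 30L, patience = 5L,
                       validation_fraction = 0.2,
                       learning_rate = 1e-2, momentum = 0.9, l2 = 1e-5,
                       seed = 1L) {
  chk_range <- function(r, nm) {
    if (length(r) != 2 || any(r <= 0) || r[1] >= r[2])
      stop(nm, " must be positive and ordered low < high")
  }
  chk_range(learning_rate_range, "learning_rate_range")
  chk_range(momentum_range, "momentum_range")
  chk_range(l2_range, "l2_range")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (input_width < 8 || input_height < 8) stop("input size too small")
  if (length(conv_filters) < 1) stop("need at least one convolution block")
  structure(list(
    input_width = as.integer(input_width), input_height = as.integer(input_height),
    conv_filters = as.integer(conv_filters), kernel_size = as.integer(kernel_size),
    n_conv_blocks = length(conv_filters),
    fc_units = as.integer(fc_units), dropout_rate = dropout_rate,
    n_classes = as.integer(n_classes), batch_size = as.integer(batch_size),
    learning_rate_range = learning_rate_range, momentum_range = momentum_range,
    l2_range = l2_range, n_search_draws = as.integer(n_search_draws),
    search_epochs = as.integer(search_epochs), n_epochs = as.integer(n_epochs),
    patience = as.integer(patience), validation_fraction = validation_fraction,
    learning_rate = learning_rate, momentum = momentum, l2 = l2,
    seed = as.integer(seed)), class = "cnn_config")
}

# -- index templates ---------------------------------------------------------
# Activations for one image are stored as a single vector in channel-major,
# column-major layout: element (row i, col j, channel c) of an H x W x C map
# sits at (c-1)*H*W + (j-1)*H + i. im2col templates are integer matrices
# (one row per output position, one column per patch entry, entry order:
# row offset fastest, then column offset, then channel) indexing into that
# vector; patch extraction is then a single vectorized gather.

make_im2col_idx <- function(H, W, C, k) {
  ph <- H - k + 1L; pw <- W - k + 1L
  base <- as.vector(outer(seq_len(ph), (seq_len(pw) - 1L) * H, `+`))
  offs <- as.vector(outer(
    as.vector(outer(0:(k - 1L), (0:(k - 1L)) * H, `+`)),
    (seq_len(C) - 1L) * H * W, `+`))
  outer(base, offs, `+`)
}

make_pool_idx <- function(H, W, C) {
  ph <- H %/% 2L; pw <- W %/% 2L
  base <- as.vector(outer(2L * seq_len(ph) - 1L, (2L * seq_len(pw) - 2L) * H, `+`))
  one <- cbind(base, base + 1L, base + H, base + H + 1L)
  if (C == 1L) return(one)
  do.call(rbind, lapply(seq_len(C), function(c) one + (c - 1L) * H * W))
}

he_init <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)

#' Build an untrained three-direction CNN
#'
#' Allocates the layer geometry and seeded He-normal initial weights for the
#' architecture described in [cnn_config()].
#'
#' @param config A [cnn_config].
#' @return A `direction_model` (untrained).
#' @export
build_model <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  k <- config$kernel_size
  H <- config$input_height; W <- config$input_width; C <- 3L
  conv <- list()
  withr::with_seed(config$seed, {
    for (b in seq_len(config$n_conv_blocks)) {
      f <- config$conv_filters[b]
      ph <- H - k + 1L; pw <- W - k + 1L
      if (ph < 2 || pw < 2) stop("input too small for the configured conv blocks")
      lay <- list(
        H = H, W = W, C = C, F = f, ph = ph, pw = pw,
        idx = make_im2col_idx(H, W, C, k),
        W_ = he_init(k * k * C, f), b_ = numeric(f),
        pool_idx = make_pool_idx(ph, pw, f),
        oh = ph %/% 2L, ow = pw %/% 2L)
      # backward template: full correlation of the (k-1)-padded output grad
      # with the flipped kernel recovers the input gradient
      lay$bk_padh <- ph + 2L * (k - 1L)
      lay$bk_padw <- pw + 2L * (k - 1L)
      if (b > 1L) {
        lay$bk_idx <- make_im2col_idx(lay$bk_padh, lay$bk_padw, f, k)
        # linear indices of the unpadded ph x pw x F block inside the padded
        # volume, so backward can scatter without building arrays
        ii <- rep(k:(k + ph - 1L), times = pw)
        jj <- rep(k:(k + pw - 1L), each = ph)
        one <- (jj - 1L) * lay$bk_padh + ii
        lay$bk_interior <- as.vector(outer(one, (seq_len(f) - 1L) *
                                             lay$bk_padh * lay$bk_padw, `+`))
      }
      conv[[b]] <- lay
      H <- lay$oh; W <- lay$ow; C <- f
    }
    n_flat <- H * W * C
    fc1 <- list(W_ = he_init(n_flat, config$fc_units), b_ = numeric(config$fc_units))
    fc2 <- list(W_ = he_init(config$fc_units, config$n_classes),
                b_ = numeric(config$n_classes))
  })
  structure(list(conv = conv, fc1 = fc1, fc2 = fc2, n_flat = H * W * C,
                 config = config, trained = FALSE, log = NULL, meta = list()),
            class = "direction_model")
}

#' @export
print.direction_model <- function(x, ...) {
  np <- sum(vapply(x$conv, function(l) length(l$W_) + length(l$b_), 0)) +
    length(x$fc1$W_) + length(x$fc1$b_) + length(x$fc2$W_) + length(x$fc2$b_)
  cat(sprintf("<direction_model %dx%d input, %s conv filters, %d params, %s>\n",
              x$config$input_width, x$config$input_height,
              paste(x$config$conv_filters, collapse = "/"), np,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# flip kernel spatially and swap in/out channels: (k*k*C x F) -> (k*k*F x C)
flip_kernel <- function(W_, k, C, F_) {
  A <- array(W_, c(k, k, C, F_))
  A <- A[k:1, k:1, , , drop = FALSE]
  matrix(aperm(A, c(1, 2, 4, 3)), k * k * F_, C)
}

# forward pass for one image vector; returns caches when train = TRUE
cnn_forward <- function(model, xvec, train = FALSE, drop_rate = 0) {
  caches <- if (train) vector("list", length(model$conv))
  a <- xvec
  for (b in seq_along(model$conv)) {
    l <- model$conv[[b]]
    cols <- a[l$idx]; dim(cols) <- dim(l$idx)
    z <- cols %*% l$W_
    z <- sweep(z, 2, l$b_, `+`)
    r <- z > 0
    z[!r] <- 0
    zv <- as.vector(z)
    pv <- zv[l$pool_idx]; dim(pv) <- dim(l$pool_idx)
    mx <- max.col(pv, ties.method = "first")
    sel <- cbind(seq_len(nrow(pv)), mx)
    pooled <- pv[sel]
    if (train) caches[[b]] <- list(cols = cols, relu = r,
                                   win = l$pool_idx[sel])
    a <- pooled                      # vector, channel-major layout preserved
  }
  h <- drop(crossprod(model$fc1$W_, a)) + model$fc1$b_
  hr <- h > 0
  h[!hr] <- 0
  mask <- NULL
  if (train && drop_rate > 0) {
    mask <- (stats::runif(length(h)) >= drop_rate) / (1 - drop_rate)
    h <- h * mask
  }
  s <- drop(crossprod(model$fc2$W_, h)) + model$fc2$b_
  s <- s - max(s)
  p <- exp(s); p <- p / sum(p)
  list(probs = p, flat = a, hidden = h, hidden_relu = hr, mask = mask,
       caches = caches)
}

# backward pass for one image. Returns the fully-connected deltas (the
# weight gradients for those layers are formed batch-wise from one matrix
# product) plus per-image convolution gradients. `flips` caches the flipped
# kernels, which are constant within a batch.
cnn_backward <- function(model, fw, y_onehot, flips) {
  ds <- fw$probs - y_onehot
  dh <- drop(model$fc2$W_ %*% ds)
  if (!is.null(fw$mask)) dh <- dh * fw$mask
  dh[!fw$hidden_relu] <- 0
  da <- drop(model$fc1$W_ %*% dh)
  conv <- vector("list", length(model$conv))
  for (b in rev(seq_along(model$conv))) {
    l <- model$conv[[b]]
    cache <- fw$caches[[b]]
    # un-pool: gradients flow to the argmax positions (2x2 stride-2 windows
    # do not overlap, so plain assignment suffices)
    dz <- numeric(l$ph * l$pw * l$F)
    dz[cache$win] <- da
    dim(dz) <- c(l$ph * l$pw, l$F)
    dz[!cache$relu] <- 0
    conv[[b]] <- list(W_ = crossprod(cache$cols, dz), b_ = colSums(dz))
    if (b > 1L) {
      pv <- numeric(l$bk_padh * l$bk_padw * l$F)
      pv[l$bk_interior] <- dz
      colsb <- pv[l$bk_idx]; dim(colsb) <- dim(l$bk_idx)
      da <- as.vector(colsb %*% flips[[b]])
    }
  }
  list(ds = ds, dh = dh, conv = conv)
}

# bilinear resize of an H x W x 3 array (or matrix) to out_h x out_w
resize_bilinear <- function(px, out_h, out_w) {
  was_mat <- is.matrix(px)
  if (was_mat) px <- array(px, c(dim(px), 1))
  H <- dim(px)[1]; W <- dim(px)[2]; C <- dim(px)[3]
  sy <- pmin(pmax((seq_len(out_h) - 0.5) * H / out_h - 0.5, 0), H - 1)
  sx <- pmin(pmax((seq_len(out_w) - 0.5) * W / out_w - 0.5, 0), W - 1)
  y0 <- pmin(floor(sy), H - 1) ; y1 <- pmin(y0 + 1, H - 1); wy <- sy - y0
  x0 <- pmin(floor(sx), W - 1) ; x1 <- pmin(x0 + 1, W - 1); wx <- sx - x0
  out <- array(0, c(out_h, out_w, C))
  for (c in seq_len(C)) {
    m <- px[, , c]
    top <- m[y0 + 1, x0 + 1, drop = FALSE] * (1 - wx)[col(matrix(0, out_h, out_w))] +
           m[y0 + 1, x1 + 1, drop = FALSE] * wx[col(matrix(0, out_h, out_w))]
    bot <- m[y1 + 1, x0 + 1, drop = FALSE] * (1 - wx)[col(matrix(0, out_h, out_w))] +
           m[y1 + 1, x1 + 1, drop = FALSE] * wx[col(matrix(0, out_h, out_w))]
    out[, , c] <- top * (1 - wy) + bot * wy
  }
  if (was_mat && C == 1) out[, , 1] else out
}

# normalize assorted image inputs to the model's input vector: resize to the
# configured size and center intensities at mid-gray (flow colorings are
# mostly bright, and centering keeps SGD well-conditioned)
image_to_input <- function(img, config) {
  px <- if (inherits(img, "flow_color_image")) img$pixels
        else if (inherits(img, "frame_image")) img$pixels else img
  if (is.matrix(px)) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[1] != config$input_height || dim(px)[2] != config$input_width)
    px <- resize_bilinear(px, config$input_height, config$input_width)
  as.vector(px) - 0.5   # channel-major, column-major within channel
}

canon_labels <- function(labels) {
  if (is.numeric(labels)) {
    lv <- c(`1` = "insertion", `-1` = "withdrawal", `0` = "stop")
    labels <- lv[as.character(labels)]
  }
  f <- factor(as.character(labels), levels = DIRECTION_LEVELS)
  if (anyNA(f)) stop("labels must be insertion / withdrawal / stop (or +1/-1/0)")
  f
}

zero_grads_like <- function(model) {
  list(fc1_W = model$fc1$W_ * 0, fc1_b = model$fc1$b_ * 0,
       fc2_W = model$fc2$W_ * 0, fc2_b = model$fc2$b_ * 0,
       conv = lapply(model$conv, function(l) list(W_ = l$W_ * 0, b_ = l$b_ * 0)))
}

kernel_flips <- function(model) {
  k <- model$config$kernel_size
  lapply(seq_along(model$conv), function(b) {
    l <- model$conv[[b]]
    if (b > 1L) flip_kernel(l$W_, k, l$C, l$F) else NULL
  })
}

sgd_update <- function(model, vel, grads, n, lr, mom, l2) {
  upd <- function(w, v, g) {
    v <- mom * v - lr * (g / n + l2 * w)
    list(w = w + v, v = v)
  }
  for (b in seq_along(model$conv)) {
    r <- upd(model$conv[[b]]$W_, vel$conv[[b]]$W_, grads$conv[[b]]$W_)
    model$conv[[b]]$W_ <- r$w; vel$conv[[b]]$W_ <- r$v
    r <- upd(model$conv[[b]]$b_, vel$conv[[b]]$b_, grads$conv[[b]]$b_)
    model$conv[[b]]$b_ <- r$w; vel$conv[[b]]$b_ <- r$v
  }
  r <- upd(model$fc1$W_, vel$fc1_W, grads$fc1_W); model$fc1$W_ <- r$w; vel$fc1_W <- r$v
  r <- upd(model$fc1$b_, vel$fc1_b, grads$fc1_b); model$fc1$b_ <- r$w; vel$fc1_b <- r$v
  r <- upd(model$fc2$W_, vel$fc2_W, grads$fc2_W); model$fc2$W_ <- r$w; vel$fc2_W <- r$v
  r <- upd(model$fc2$b_, vel$fc2_b, grads$fc2_b); model$fc2$b_ <- r$w; vel$fc2_b <- r$v
  list(model = model, vel = vel)
}

# one SGD epoch over X (columns = images); returns model, velocity, mean loss
run_epoch <- function(model, vel, X, y_int, lr, mom, l2, batch_size, drop_rate) {
  n <- ncol(X)
  ord <- sample.int(n)
  loss <- 0
  eye <- diag(model$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    ids <- ord[start:min(start + batch_size - 1, n)]
    nb <- length(ids)
    flips <- kernel_flips(model)
    FLAT <- matrix(0, model$n_flat, nb)
    DH <- matrix(0, model$config$fc_units, nb)
    HID <- matrix(0, model$config$fc_units, nb)
    DS <- matrix(0, model$config$n_classes, nb)
    conv_g <- lapply(model$conv, function(l) list(W_ = l$W_ * 0, b_ = l$b_ * 0))
    for (j in seq_len(nb)) {
      i <- ids[j]
      fw <- cnn_forward(model, X[, i], train = TRUE, drop_rate = drop_rate)
      loss <- loss - log(max(fw$probs[y_int[i]], 1e-12))
      g <- cnn_backward(model, fw, eye[y_int[i], ], flips)
      FLAT[, j] <- fw$flat; HID[, j] <- fw$hidden
      DH[, j] <- g$dh; DS[, j] <- g$ds
      for (b in seq_along(conv_g)) {
        conv_g[[b]]$W_ <- conv_g[[b]]$W_ + g$conv[[b]]$W_
        conv_g[[b]]$b_ <- conv_g[[b]]$b_ + g$conv[[b]]$b_
      }
    }
    grads <- list(fc1_W = tcrossprod(FLAT, DH), fc1_b = rowSums(DH),
                  fc2_W = tcrossprod(HID, DS), fc2_b = rowSums(DS),
                  conv = conv_g)
    r <- sgd_update(model, vel, grads, nb, lr, mom, l2)
    model <- r$model; vel <- r$vel
  }
  list(model = model, vel = vel, loss = loss / n)
}

eval_model <- function(model, X, y_int) {
  n <- ncol(X)
  loss <- 0; correct <- 0
  for (i in seq_len(n)) {
    fw <- cnn_forward(model, X[, i], train = FALSE)
    loss <- loss - log(max(fw$probs[y_int[i]], 1e-12))
    correct <- correct + (which.max(fw$probs) == y_int[i])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train the three-direction CNN
#'
#' Resizes all images to the configured input size, splits off a stratified
#' validation set, draws `n_search_draws` random hyperparameter settings
#' (each trained briefly and ranked by validation accuracy), then trains the
#' best setting with SGD + momentum for up to `n_epochs` epochs with early
#' stopping on validation loss. Fully deterministic for a fixed config seed.
#'
#' @param model An untrained (or trained) `direction_model` from
#'   [build_model()].
#' @param images List of `flow_color_image` objects or `H x W x 3` arrays.
#' @param labels Direction labels (`insertion`/`withdrawal`/`stop`, a factor,
#'   or the numeric `+1/-1/0` encoding).
#' @param config Optional [cnn_config] overriding the model's.
#' @return The trained `direction_model`; `$log` holds the per-epoch training
#'   log and `$meta` the selected hyperparameters and validation accuracy.
#' @export
train_model <- function(model, images, labels, config = NULL) {
  stopifnot(inherits(model, "direction_model"))
  cfg <- if (is.null(config)) model$config else config
  y <- canon_labels(labels)
  if (length(images) != length(y)) stop("images and labels differ in length")
  if (any(table(y) == 0)) stop("every class needs at least one sample")
  y_int <- as.integer(y)
  X <- vapply(images, image_to_input, numeric(3 * cfg$input_height * cfg$input_width),
              config = cfg)
  withr::with_seed(cfg$seed, {
    val_idx <- which(make_folds(y_int, max(2L, round(1 / cfg$validation_fraction))) == 1L)
    tr_idx <- setdiff(seq_along(y_int), val_idx)
    Xtr <- X[, tr_idx, drop = FALSE]; ytr <- y_int[tr_idx]
    Xva <- X[, val_idx, drop = FALSE]; yva <- y_int[val_idx]

    draws <- if (cfg$n_search_draws > 0) {
      data.frame(
        lr = exp(stats::runif(cfg$n_search_draws, log(cfg$learning_rate_range[1]),
                              log(cfg$learning_rate_range[2]))),
        momentum = stats::runif(cfg$n_search_draws, cfg$momentum_range[1],
                                cfg$momentum_range[2]),
        l2 = exp(stats::runif(cfg$n_search_draws, log(cfg$l2_range[1]),
                              log(cfg$l2_range[2]))))
    } else {
      data.frame(lr = cfg$learning_rate, momentum = cfg$momentum, l2 = cfg$l2)
    }
    draws$val_acc <- NA_real_
    for (d in seq_len(nrow(draws))) {
      m <- model; vel <- zero_grads_like(model)
      ne <- if (cfg$n_search_draws > 0) cfg$search_epochs else 0L
      for (ep in seq_len(ne)) {
        r <- run_epoch(m, vel, Xtr, ytr, draws$lr[d], draws$momentum[d],
                       draws$l2[d], cfg$batch_size, cfg$dropout_rate)
        m <- r$model; vel <- r$vel
      }
      draws$val_acc[d] <- if (ne > 0) eval_model(m, Xva, yva)$acc else NA_real_
    }
    best <- if (cfg$n_search_draws > 0) which.max(draws$val_acc) else 1L

    m <- model; vel <- zero_grads_like(model)
    log_df <- data.frame()
    best_loss <- Inf; best_state <- NULL; stall <- 0L
    for (ep in seq_len(cfg$n_epochs)) {
      r <- run_epoch(m, vel, Xtr, ytr, draws$lr[best], draws$momentum[best],
                     draws$l2[best], cfg$batch_size, cfg$dropout_rate)
      m <- r$model; vel <- r$vel
      va <- eval_model(m, Xva, yva)
      log_df <- rbind(log_df, data.frame(epoch = ep, train_loss = r$loss,
                                         val_loss = va$loss, val_acc = va$acc))
      if (va$loss < best_loss - 1e-6) {
        best_loss <- va$loss; best_state <- m; stall <- 0L
      } else stall <- stall + 1L
      if (va$acc >= 1 - 1e-12 || stall >= cfg$patience) break
    }
    if (!is.null(best_state) && utils::tail(log_df$val_loss, 1) > best_loss)
      m <- best_state
    va <- eval_model(m, Xva, yva)
  })
  m$trained <- TRUE
  m$log <- log_df
  m$meta <- list(learning_rate = draws$lr[best], momentum = draws$momentum[best],
                 l2 = draws$l2[best], epochs = nrow(log_df),
                 val_accuracy = va$acc, search = draws, seed = cfg$seed)
  m
}

#' Predict the movement direction for one flow-color image
#'
#' Deterministic inference (dropout disabled).
#'
#' @param model A trained `direction_model`.
#' @param image A `flow_color_image` or `H x W x 3` array.
#' @return List with `label` (factor level), `value` (+1/-1/0) and `probs`
#'   (named probability triple summing to 1).
#' @export
predict_direction <- function(model, image) {
  stopifnot(inherits(model, "direction_model"))
  if (!model$trained) stop("model is untrained; call train_model() first")
  p <- cnn_forward(model, image_to_input(image, model$config), train = FALSE)$probs
  names(p) <- DIRECTION_LEVELS[seq_along(p)]
  lab <- DIRECTION_LEVELS[which.max(p)]
  list(label = lab, value = unname(DIRECTION_VALUES[lab]), probs = p)
}

#' Predict directions for a list of images
#'
#' @param model A trained `direction_model`.
#' @param images List of images accepted by [predict_direction()].
#' @return Character vector of predicted labels.
#' @export
predict_directions <- function(model, images) {
  vapply(images, function(im) predict_direction(model, im)$label, "")
}

#' Stratified k-fold cross-validation of the CNN
#'
#' Splits the data into `k` stratified folds; each fold serves once as the
#' validation set while a fresh model is trained on the rest. Validation
#' predictions from all folds are accumulated into one 3x3 confusion matrix
#' (rows = predicted class, columns = true class), so every sample is
#' validated exactly once.
#'
#' @param images,labels As in [train_model()].
#' @param config A [cnn_config].
#' @param k Number of folds.
#' @return A [confusion_matrix3]; attribute `fold_accuracy` holds per-fold
#'   validation accuracies.
#' @export
cross_validate <- function(images, labels, config = cnn_config(), k = 5L) {
  y <- canon_labels(labels)
  if (length(images) < k) stop("k exceeds the number of samples")
  folds <- withr::with_seed(config$seed, make_folds(as.integer(y), k))
  cm <- matrix(0L, 3, 3)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(folds != f); va <- which(folds == f)
    cfg <- config; cfg$seed <- config$seed + f
    m <- build_model(cfg)
    m <- train_model(m, images[tr], y[tr], cfg)
    pred <- predict_directions(m, images[va])
    pi_ <- match(pred, DIRECTION_LEVELS)
    ti <- as.integer(y[va])
    for (i in seq_along(va)) cm[pi_[i], ti[i]] <- cm[pi_[i], ti[i]] + 1L
    fold_acc[f] <- mean(pi_ == ti)
  }
  out <- confusion_matrix3(cm)
  attr(out, "fold_accuracy") <- fold_acc
  out
}
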