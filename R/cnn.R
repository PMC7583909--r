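#' Twin-tower CNN configuration
#'
#' Architecture and optimization settings for the pair classifier. Defaults:
#' per tower conv(32, 3x3) -> BN -> dropout(0.25) -> conv(64, 3x3) -> BN ->
#' dropout(0.25), flatten, concatenate towers, dense(128, ReLU) ->
#' dropout(0.5) -> dense(1, sigmoid); Adam with learning rate 1e-3, batch 64,
#' up to 50 epochs with early stopping (patience 10) on validation loss. The
#' kernel is fixed at 3x3 with stride 1 and there is no pooling; both towers
#' share the architecture but not the weights.
#'
#' @param conv_filters Integer vector of filters per conv block.
#' @param dense_units Integer vector of hidden dense layer sizes.
#' @param dropout_conv,dropout_dense Dropout rates after conv blocks and
#'   hidden dense layers.
#' @param learning_rate,batch_size,epochs Adam step size, minibatch size and
#'   epoch cap.
#' @param patience Early-stopping patience in epochs on validation loss
#'   (`Inf` disables early stopping).
#' @param val_frac Fraction of the training set held out for validation when
#'   no explicit validation set is given (0 disables).
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(conv_filters = c(32L, 64L), dense_units = 128L,
                       dropout_conv = 0.25, dropout_dense = 0.5,
                       learning_rate = 1e-3, batch_size = 64L, epochs = 50L,
                       patience = 10L, val_frac = 0.1, seed = 1L) {
  stopifnot(length(conv_filters) >= 1L, all(conv_filters >= 1L),
            dropout_conv >= 0, dropout_conv < 1,
            dropout_dense >= 0, dropout_dense < 1,
            batch_size >= 1L, epochs >= 1L)
  structure(list(conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 dropout_conv = dropout_conv, dropout_dense = dropout_dense,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = patience,
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "cnn_config")
}

# im2col geometry for one valid 3x3 stride-1 convolution over H x W x C:
# K maps patch rows to flat input indices; S is the transposed scatter used
# by the backward pass (col2im).
conv_geometry <- function(H, W, C) {
  Ho <- H - 2L; Wo <- W - 2L
  if (Ho < 1L || Wo < 1L) stop_input("input %dx%d too small for a 3x3 kernel", H, W)
  P <- Ho * Wo
  K <- matrix(0L, 9L * C, P)
  p <- 0L
  for (j in seq_len(Wo)) for (i in seq_len(Ho)) {
    p <- p + 1L
    r <- 0L
    for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
      r <- r + 1L
      K[r, p] <- (i + di) + (j + dj - 1L) * H + (c - 1L) * H * W
    }
  }
  S <- Matrix::sparseMatrix(i = as.vector(K), j = seq_len(length(K)), x = 1,
                            dims = c(H * W * C, length(K)))
  list(H = H, W = W, C = C, Ho = Ho, Wo = Wo, P = P, K = K,
       Kvec = as.vector(K), S = S)
}

#' Build an untrained twin-tower CNN
#'
#' Constructs the parameter set and layer geometry for the classifier: two
#' convolutional towers with separate weights over the lncRNA and miRNA
#' tensors, flattened, concatenated and passed through dense layers to a
#' single sigmoid unit. Construction is deterministic for a fixed config.
#'
#' @param input_shape Integer vector `c(H, W, C)` of each input tensor
#'   (default `c(20, 20, 4)`).
#' @param config A [cnn_config()].
#' @return An object of class `lncmir_cnn` (untrained).
#' @export
build_cnn <- function(input_shape = c(20L, 20L, 4L), config = cnn_config()) {
  stopifnot(length(input_shape) == 3L)
  nf <- config$conv_filters
  geoms <- list()
  H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
  for (l in seq_along(nf)) {
    geoms[[l]] <- conv_geometry(H, W, C)
    H <- geoms[[l]]$Ho; W <- geoms[[l]]$Wo; C <- nf[l]
  }
  flat <- H * W * C
  par <- list()
  with_seed(derive_seed(config$seed, 101L), {
    for (tw in c("lnc", "mir")) {
      for (l in seq_along(nf)) {
        fan_in <- 9L * geoms[[l]]$C
        par[[paste0(tw, "_conv", l, "_W")]] <-
          matrix(stats::rnorm(nf[l] * fan_in, sd = sqrt(2 / fan_in)), nf[l], fan_in)
        par[[paste0(tw, "_conv", l, "_b")]] <- rep(0, nf[l])
        par[[paste0(tw, "_conv", l, "_gamma")]] <- rep(1, nf[l])
        par[[paste0(tw, "_conv", l, "_beta")]] <- rep(0, nf[l])
      }
    }
    d_in <- 2L * flat
    for (l in seq_along(config$dense_units)) {
      d_out <- config$dense_units[l]
      par[[paste0("dense", l, "_W")]] <-
        matrix(stats::rnorm(d_out * d_in, sd = sqrt(2 / d_in)), d_out, d_in)
      par[[paste0("dense", l, "_b")]] <- rep(0, d_out)
      d_in <- d_out
    }
    par$out_W <- matrix(stats::rnorm(d_in, sd = sqrt(1 / d_in)), 1L, d_in)
    par$out_b <- 0
  })
  bn <- list()
  for (tw in c("lnc", "mir"))
    for (l in seq_along(nf)) {
      bn[[paste0(tw, "_conv", l, "_mean")]] <- rep(0, nf[l])
      bn[[paste0(tw, "_conv", l, "_var")]] <- rep(1, nf[l])
    }
  structure(list(config = config, input_shape = as.integer(input_shape),
                 geoms = geoms, flat = flat, par = par, bn = bn,
                 trained = FALSE, history = NULL),
            class = "lncmir_cnn")
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# forward pass of one tower; X is (H*W*C) x B. Returns the flattened output
# and (in training mode) everything the backward pass needs.
tower_forward <- function(model, tw, X, training, bn_batch) {
  nf <- model$config$conv_filters
  caches <- vector("list", length(nf))
  for (l in seq_along(nf)) {
    g <- model$geoms[[l]]
    B <- ncol(X)
    cols <- X[g$Kvec, , drop = FALSE]
    dim(cols) <- c(9L * g$C, g$P * B)
    Wt <- model$par[[paste0(tw, "_conv", l, "_W")]]
    Z <- Wt %*% cols + model$par[[paste0(tw, "_conv", l, "_b")]]
    mask <- Z > 0
    A <- Z * mask
    gamma <- model$par[[paste0(tw, "_conv", l, "_gamma")]]
    beta <- model$par[[paste0(tw, "_conv", l, "_beta")]]
    if (training) {
      mu <- rowMeans(A)
      va <- rowMeans(A * A) - mu * mu
      bn_batch[[paste0(tw, "_conv", l, "_mean")]] <- mu
      bn_batch[[paste0(tw, "_conv", l, "_var")]] <- va
    } else {
      mu <- model$bn[[paste0(tw, "_conv", l, "_mean")]]
      va <- model$bn[[paste0(tw, "_conv", l, "_var")]]
    }
    invstd <- 1 / sqrt(va + BN_EPS)
    xhat <- (A - mu) * invstd
    Y <- xhat * gamma + beta
    drop_mask <- NULL
    rate <- model$config$dropout_conv
    if (training && rate > 0) {
      drop_mask <- (stats::runif(length(Y)) >= rate) / (1 - rate)
      dim(drop_mask) <- dim(Y)
      Y <- Y * drop_mask
    }
    if (training)
      caches[[l]] <- list(cols = cols, mask = mask, xhat = xhat,
                          invstd = invstd, gamma = gamma,
                          drop_mask = drop_mask, B = B)
    a <- array(Y, c(nf[l], g$P, B))
    X <- aperm(a, c(2L, 1L, 3L))
    dim(X) <- c(g$P * nf[l], B)
  }
  list(out = X, caches = caches, bn_batch = bn_batch)
}

# backward pass of one tower; dOut matches the flattened tower output.
tower_backward <- function(model, tw, dOut, caches, grads) {
  nf <- model$config$conv_filters
  for (l in rev(seq_along(nf))) {
    g <- model$geoms[[l]]
    cc <- caches[[l]]
    B <- cc$B
    a <- array(dOut, c(g$P, nf[l], B))
    dY <- aperm(a, c(2L, 1L, 3L))
    dim(dY) <- c(nf[l], g$P * B)
    if (!is.null(cc$drop_mask)) dY <- dY * cc$drop_mask
    grads[[paste0(tw, "_conv", l, "_gamma")]] <- rowSums(dY * cc$xhat)
    grads[[paste0(tw, "_conv", l, "_beta")]] <- rowSums(dY)
    dxhat <- dY * cc$gamma
    dA <- cc$invstd * (dxhat - rowMeans(dxhat) -
                         cc$xhat * rowMeans(dxhat * cc$xhat))
    dZ <- dA * cc$mask
    grads[[paste0(tw, "_conv", l, "_W")]] <- tcrossprod(dZ, cc$cols)
    grads[[paste0(tw, "_conv", l, "_b")]] <- rowSums(dZ)
    if (l > 1L) {  # the first layer's input gradient is never consumed
      dcols <- crossprod(model$par[[paste0(tw, "_conv", l, "_W")]], dZ)
      dim(dcols) <- c(9L * g$C * g$P, B)
      dOut <- as.matrix(g$S %*% dcols)
    }
  }
  list(dX = dOut, grads = grads)
}

cnn_forward <- function(model, xl, xm, training = FALSE) {
  B <- ncol(xl)
  bn_batch <- list()
  tl <- tower_forward(model, "lnc", xl, training, bn_batch)
  tm <- tower_forward(model, "mir", xm, training, tl$bn_batch)
  Xf <- rbind(tl$out, tm$out)
  dense_caches <- list()
  A <- Xf
  for (l in seq_along(model$config$dense_units)) {
    Z <- model$par[[paste0("dense", l, "_W")]] %*% A +
      model$par[[paste0("dense", l, "_b")]]
    mask <- Z > 0
    Y <- Z * mask
    drop_mask <- NULL
    rate <- model$config$dropout_dense
    if (training && rate > 0) {
      drop_mask <- matrix((stats::runif(length(Y)) >= rate) / (1 - rate),
                          nrow(Y), ncol(Y))
      Y <- Y * drop_mask
    }
    if (training) dense_caches[[l]] <- list(input = A, mask = mask,
                                            drop_mask = drop_mask)
    A <- Y
  }
  z <- as.numeric(model$par$out_W %*% A + model$par$out_b)
  p <- 1 / (1 + exp(-pmin(pmax(z, -30), 30)))
  list(prob = p, top = A, dense_caches = dense_caches,
       tower_l = tl, tower_m = tm, n_lnc_flat = nrow(tl$out))
}

cnn_backward <- function(model, fwd, y) {
  B <- length(y)
  grads <- list()
  dz <- matrix((fwd$prob - y) / B, 1L, B)
  grads$out_W <- dz %*% t(fwd$top)
  grads$out_b <- sum(dz)
  dA <- crossprod(model$par$out_W, dz)
  for (l in rev(seq_along(model$config$dense_units))) {
    cc <- fwd$dense_caches[[l]]
    if (!is.null(cc$drop_mask)) dA <- dA * cc$drop_mask
    dZ <- dA * cc$mask
    grads[[paste0("dense", l, "_W")]] <- tcrossprod(dZ, cc$input)
    grads[[paste0("dense", l, "_b")]] <- rowSums(dZ)
    dA <- crossprod(model$par[[paste0("dense", l, "_W")]], dZ)
  }
  nl <- fwd$n_lnc_flat
  bl <- tower_backward(model, "lnc", dA[seq_len(nl), , drop = FALSE],
                       fwd$tower_l$caches, grads)
  bm <- tower_backward(model, "mir", dA[-seq_len(nl), , drop = FALSE],
                       fwd$tower_m$caches, bl$grads)
  bm$grads
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

flatten_batch <- function(x, idx = NULL) {
  d <- dim(x)
  if (length(d) != 4L) stop_input("expected a H x W x C x N array")
  m <- x
  dim(m) <- c(d[1] * d[2] * d[3], d[4])
  if (!is.null(idx)) m <- m[, idx, drop = FALSE]
  m
}

#' Train the twin-tower CNN
#'
#' Minimizes binary cross-entropy with Adam on minibatches. A validation set
#' (explicit, or split off the training set when `config$val_frac > 0`) drives
#' early stopping; the best-validation-loss weights are restored. Training is
#' reproducible for a fixed config seed.
#'
#' @param model An `lncmir_cnn` from [build_cnn()].
#' @param x_lnc,x_mir Arrays `H x W x C x N` of paired fused tensors.
#' @param y Numeric/integer 0-1 labels of length N; both classes must be
#'   present.
#' @param x_lnc_val,x_mir_val,y_val Optional explicit validation set.
#' @param verbose Print per-epoch losses.
#' @return The trained model, with `$history` (per-epoch train/validation
#'   loss).
#' @export
train_cnn <- function(model, x_lnc, x_mir, y,
                      x_lnc_val = NULL, x_mir_val = NULL, y_val = NULL,
                      verbose = FALSE) {
  if (!inherits(model, "lncmir_cnn")) stop_input("not an lncmir_cnn model")
  cfg <- model$config
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop_input("training labels contain a single class; need both 0 and 1")
  Xl <- flatten_batch(x_lnc)
  Xm <- flatten_batch(x_mir)
  if (ncol(Xl) != length(y) || ncol(Xm) != length(y))
    stop_input("number of tensors (%d, %d) does not match labels (%d)",
               ncol(Xl), ncol(Xm), length(y))
  if (nrow(Xl) != prod(model$input_shape))
    stop_input("tensor shape does not match model input %s",
               paste(model$input_shape, collapse = "x"))

  have_val <- !is.null(y_val)
  if (have_val) {
    Xl_val <- flatten_batch(x_lnc_val); Xm_val <- flatten_batch(x_mir_val)
    yv <- as.numeric(y_val)
  }

  adam_m <- lapply(model$par, function(p) p * 0)
  adam_v <- lapply(model$par, function(p) p * 0)
  t_step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_loss <- Inf; best_par <- NULL; best_bn <- NULL; wait <- 0L

  model <- with_seed(derive_seed(cfg$seed, 202L), {
    if (!have_val && cfg$val_frac > 0 && length(y) >= 10L) {
      n_val <- max(1L, floor(cfg$val_frac * length(y)))
      vi <- sample.int(length(y), n_val)
      Xl_val <- Xl[, vi, drop = FALSE]; Xm_val <- Xm[, vi, drop = FALSE]
      yv <- y[vi]
      Xl <- Xl[, -vi, drop = FALSE]; Xm <- Xm[, -vi, drop = FALSE]
      y <- y[-vi]
      have_val <- TRUE
    }
    n <- length(y)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        if (length(idx) < 2L) next  # batch norm needs > 1 sample
        fwd <- cnn_forward(model, Xl[, idx, drop = FALSE],
                           Xm[, idx, drop = FALSE], training = TRUE)
        losses <- c(losses, bce_loss(fwd$prob, y[idx]))
        grads <- cnn_backward(model, fwd, y[idx])
        for (nm in names(fwd$tower_m$bn_batch)) {
          stat <- fwd$tower_m$bn_batch[[nm]]
          model$bn[[nm]] <- BN_MOMENTUM * model$bn[[nm]] +
            (1 - BN_MOMENTUM) * stat
        }
        t_step <- t_step + 1L
        lr_t <- cfg$learning_rate * sqrt(1 - beta2^t_step) / (1 - beta1^t_step)
        for (nm in names(grads)) {
          g <- grads[[nm]]
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g * g
          model$par[[nm]] <- model$par[[nm]] -
            lr_t * adam_m[[nm]] / (sqrt(adam_v[[nm]]) + eps)
        }
      }
      train_loss <- mean(losses)
      val_loss <- NA_real_
      if (have_val) {
        pv <- cnn_forward(model, Xl_val, Xm_val, training = FALSE)$prob
        val_loss <- bce_loss(pv, yv)
      }
      history <- rbind(history, data.frame(epoch = ep, train_loss = train_loss,
                                           val_loss = val_loss))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %s", ep, train_loss,
                        ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
      if (have_val && is.finite(cfg$patience)) {
        if (val_loss < best_loss - 1e-9) {
          best_loss <- val_loss; best_par <- model$par; best_bn <- model$bn
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      }
    }
    if (!is.null(best_par)) { model$par <- best_par; model$bn <- best_bn }
    model
  })
  model$history <- history
  model$trained <- TRUE
  model
}

#' Predict interaction probabilities for tensor pairs
#'
#' Runs the trained network in inference mode (batch-norm running statistics,
#' no dropout). The interaction call follows the strict 0.5 rule: a pair is
#' called interacting only when its probability exceeds 0.5.
#'
#' @param object A trained `lncmir_cnn`.
#' @param x_lnc,x_mir Arrays `H x W x C x N` of fused tensors.
#' @param ids Optional data frame with columns `lnc_id`, `mir_id`.
#' @param ... Unused.
#' @return Data frame with columns (`lnc_id`, `mir_id` if given),
#'   `probability` and logical `call` (`probability > 0.5`).
#' @export
predict.lncmir_cnn <- function(object, x_lnc, x_mir, ids = NULL, ...) {
  if (!isTRUE(object$trained)) stop_input("model has not been trained")
  Xl <- flatten_batch(x_lnc); Xm <- flatten_batch(x_mir)
  if (ncol(Xl) != ncol(Xm)) stop_input("tensor batch sizes differ")
  if (ncol(Xl) == 0L) {
    out <- data.frame(probability = numeric(), call = logical())
  } else {
    if (nrow(Xl) != prod(object$input_shape))
      stop_input("tensor shape does not match model input %s",
                 paste(object$input_shape, collapse = "x"))
    p <- cnn_forward(object, Xl, Xm, training = FALSE)$prob
    out <- data.frame(probability = p, call = p > 0.5)
  }
  if (!is.null(ids)) out <- cbind(ids[seq_len(nrow(out)), , drop = FALSE], out)
  rownames(out) <- NULL
  out
}

#' @export
print.lncmir_cnn <- function(x, ...) {
  cat(sprintf("twin-tower CNN (%s input, conv %s, dense %s): %s\n",
              paste(x$input_shape, collapse = "x"),
              paste(x$config$conv_filters, collapse = "-"),
              paste(x$config$dense_units, collapse = "-"),
              if (isTRUE(x$trained)) sprintf("trained, %d epochs", nrow(x$history))
              else "untrained"))
  invisible(x)
}

# number of trainable parameters (used in tests and print summaries)
n_parameters <- function(model) sum(vapply(model$par, length, integer(1)))

# stack a list of fused tensors into a H x W x C x N array
stack_tensors <- function(tensors) {
  if (length(tensors) == 0L) stop_input("no tensors to stack")
  d <- dim(tensors[[1]])
  arr <- array(0, c(d, length(tensors)))
  for (i in seq_along(tensors)) {
    if (!all(dim(tensors[[i]]) == d)) stop_input("tensor shape mismatch in stack")
    arr[, , , i] <- tensors[[i]]
  }
  arr
}
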