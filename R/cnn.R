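#' Configuration of the 1-D convolutional RMS regressor
#'
#' Architecture constants follow the reference design for regressing sEMG RMS
#' from a raw 2-s PPG window: convolution kernel size 3, ReLU activations,
#' max-pool size 2, a 128-unit hidden layer, dropout rate 0.5, batch size 64,
#' Adam optimization and an L1 (mean-absolute-error) loss. The number of
#' convolution blocks and their filter counts are design choices here: two
#' blocks of 16 and 32 filters, the smallest standard shape consistent with a
#' twice-pooled 200-sample input.
#'
#' @param input_len Window length in samples (200 = 2 s at 100 Hz).
#' @param conv_filters Integer vector, one entry per conv block.
#' @param kernel_size Convolution kernel width.
#' @param pool_size Max-pooling width.
#' @param hidden_units Units in the dense hidden layer.
#' @param dropout_rate Dropout probability on the hidden layer (training only).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param lr_decay Per-epoch multiplicative learning-rate decay (1 = constant
#'   rate). Annealing tightens final convergence, since L1 gradients keep a
#'   constant magnitude near the optimum.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); the best-validation weights are restored.
#' @param validation_frac Fraction of pairs held out for early stopping.
#' @param seed Integer seed for weight init, shuffling and dropout.
#' @return A `cnn_config` list.
#' @export
#' @examples
#' cnn_config(epochs = 10)
cnn_config <- function(input_len = 200, conv_filters = c(16, 32),
                       kernel_size = 3, pool_size = 2, hidden_units = 128,
                       dropout_rate = 0.5, batch_size = 64,
                       learning_rate = 1e-3, lr_decay = 1, epochs = 100,
                       patience = 10, validation_frac = 0.1, seed = 1L) {
  stopifnot(input_len >= 1, length(conv_filters) >= 1, all(conv_filters >= 1),
            kernel_size >= 1, pool_size >= 1, hidden_units >= 1,
            dropout_rate >= 0, dropout_rate < 1, batch_size >= 1,
            learning_rate > 0, lr_decay > 0, lr_decay <= 1, epochs >= 1,
            validation_frac >= 0, validation_frac < 1)
  len <- input_len
  for (b in seq_along(conv_filters)) {
    if (len %% pool_size != 0 || len / pool_size < 1) {
      stop("input_len ", input_len, " does not survive ", length(conv_filters),
           " pooling stages of size ", pool_size, call. = FALSE)
    }
    len <- len / pool_size
  }
  structure(
    list(input_len = as.integer(input_len),
         conv_filters = as.integer(conv_filters),
         kernel_size = as.integer(kernel_size),
         pool_size = as.integer(pool_size),
         hidden_units = as.integer(hidden_units),
         dropout_rate = dropout_rate,
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate,
         lr_decay = lr_decay,
         epochs = as.integer(epochs),
         patience = as.integer(patience),
         validation_frac = validation_frac,
         flat_len = as.integer(len * utils::tail(conv_filters, 1)),
         seed = as.integer(seed)),
    class = "cnn_config"
  )
}

#' Mean absolute error (L1 loss)
#'
#' The training criterion of the RMS regressor: the batch mean of
#' `|y_i - r_i|` between predicted and true EMG RMS values.
#'
#' @param predictions,targets Equal-length numeric vectors.
#' @return A single non-negative number.
#' @export
#' @examples
#' l1_loss(c(1, 3), c(2, 1))  # 1.5
l1_loss <- function(predictions, targets) {
  if (length(predictions) != length(targets)) {
    stop("predictions and targets must have equal length", call. = FALSE)
  }
  if (length(predictions) == 0) {
    stop("l1_loss needs at least one element", call. = FALSE)
  }
  mean(abs(predictions - targets))
}

# ---- network internals ------------------------------------------------------
# Tensors are (batch, length, channels) arrays. Convolutions use kernel 3
# with 'same' zero padding via im2col, so each block halves the length only
# through its max-pool.

cnn_init_weights <- function(config) {
  withr::with_seed(config$seed, {
    k <- config$kernel_size
    c_in <- 1L
    conv <- list()
    for (f in config$conv_filters) {
      fan_in <- k * c_in
      conv[[length(conv) + 1]] <- list(
        W = matrix(stats::rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f),
        b = rep(0, f)
      )
      c_in <- f
    }
    list(
      conv = conv,
      dense = list(
        W = matrix(stats::rnorm(config$flat_len * config$hidden_units,
                                sd = sqrt(2 / config$flat_len)),
                   config$flat_len, config$hidden_units),
        b = rep(0, config$hidden_units)
      ),
      out = list(
        W = matrix(stats::rnorm(config$hidden_units,
                                sd = sqrt(1 / config$hidden_units)),
                   config$hidden_units, 1),
        b = 0
      )
    )
  })
}

cnn_n_params <- function(weights) {
  sum(purrr::map_dbl(weights$conv, ~ length(.x$W) + length(.x$b))) +
    length(weights$dense$W) + length(weights$dense$b) +
    length(weights$out$W) + length(weights$out$b)
}

# im2col for kernel k with 'same' zero padding: (B, L, C) -> (B*L, k*C),
# column blocks ordered by kernel offset, channels within each offset.
im2col_same <- function(A, k) {
  d <- dim(A)
  B <- d[1]; L <- d[2]; C <- d[3]
  pad <- (k - 1) %/% 2
  Ap <- array(0, c(B, L + 2 * pad, C))
  Ap[, pad + seq_len(L), ] <- A
  do.call(cbind, lapply(seq_len(k) - 1, function(o) {
    matrix(Ap[, o + seq_len(L), , drop = FALSE], nrow = B * L)
  }))
}

col2im_same <- function(dXcol, k, B, L, C) {
  pad <- (k - 1) %/% 2
  dAp <- array(0, c(B, L + 2 * pad, C))
  for (o in seq_len(k) - 1) {
    block <- dXcol[, ((o * C) + 1):((o + 1) * C), drop = FALSE]
    dAp[, o + seq_len(L), ] <- dAp[, o + seq_len(L), , drop = FALSE] +
      array(block, c(B, L, C))
  }
  dAp[, pad + seq_len(L), , drop = FALSE]
}

cnn_forward <- function(weights, X, config, training = FALSE,
                        dropout_mask = NULL) {
  B <- dim(X)[1]
  cache <- list(conv = list())
  A <- X
  p <- config$pool_size
  for (l in seq_along(weights$conv)) {
    L <- dim(A)[2]; C <- dim(A)[3]
    Xcol <- im2col_same(A, config$kernel_size)
    Z <- sweep(Xcol %*% weights$conv[[l]]$W, 2, weights$conv[[l]]$b, "+")
    R <- pmax(Z, 0)
    C_out <- ncol(Z)
    Ar <- array(R, c(B, L, C_out))
    # max-pool over non-overlapping pairs along the length axis
    Lp <- L %/% p
    odd <- Ar[, p * (seq_len(Lp) - 1) + 1, , drop = FALSE]
    even <- Ar[, p * seq_len(Lp), , drop = FALSE]
    mask <- odd >= even
    P <- pmax(odd, even)
    cache$conv[[l]] <- list(Xcol = Xcol, Z = Z, mask = mask,
                            L = L, C_in = C, C_out = C_out, Lp = Lp)
    A <- P
  }
  Fl <- matrix(A, nrow = B)   # flatten (length, channel) column-major
  H_pre <- sweep(Fl %*% weights$dense$W, 2, weights$dense$b, "+")
  H <- pmax(H_pre, 0)
  if (training && config$dropout_rate > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(
        stats::runif(length(H)) >= config$dropout_rate, nrow(H), ncol(H))
    }
    H <- H * dropout_mask / (1 - config$dropout_rate)
  }
  y <- drop(H %*% weights$out$W) + weights$out$b
  cache$Fl <- Fl; cache$H_pre <- H_pre; cache$H <- H
  cache$dropout_mask <- dropout_mask
  list(y = y, cache = cache)
}

cnn_backward <- function(weights, X, y, targets, cache, config) {
  B <- dim(X)[1]
  p <- config$pool_size
  dy <- sign(y - targets) / B                     # d(L1)/dy
  grads <- list(conv = vector("list", length(weights$conv)))
  grads$out <- list(W = crossprod(cache$H, dy), b = sum(dy))
  dH <- matrix(dy, ncol = 1) %*% t(weights$out$W)  # B x hidden
  if (!is.null(cache$dropout_mask)) {
    dH <- dH * cache$dropout_mask / (1 - config$dropout_rate)
  }
  dH <- dH * (cache$H_pre > 0)
  grads$dense <- list(W = crossprod(cache$Fl, dH), b = colSums(dH))
  dFl <- dH %*% t(weights$dense$W)
  # unflatten to the last pooled tensor's shape
  last <- cache$conv[[length(cache$conv)]]
  dP <- array(dFl, c(B, last$Lp, last$C_out))
  for (l in rev(seq_along(weights$conv))) {
    cc <- cache$conv[[l]]
    # un-pool: route gradient to the argmax member of each pair
    dA_r <- array(0, c(B, cc$L, cc$C_out))
    dA_r[, p * (seq_len(cc$Lp) - 1) + 1, ] <- dP * cc$mask
    dA_r[, p * seq_len(cc$Lp), ] <- dP * !cc$mask
    dZ <- matrix(dA_r, nrow = B * cc$L) * (matrix(cc$Z > 0, nrow = B * cc$L))
    grads$conv[[l]] <- list(W = crossprod(cc$Xcol, dZ), b = colSums(dZ))
    if (l > 1) {
      dXcol <- dZ %*% t(weights$conv[[l]]$W)
      dP <- col2im_same(dXcol, config$kernel_size, B, cc$L, cc$C_in)
    }
  }
  grads
}

adam_state_init <- function(weights) {
  zero_like <- function(w) purrr::map(w, ~ .x * 0)
  list(
    m = list(conv = purrr::map(weights$conv, zero_like),
             dense = zero_like(weights$dense), out = zero_like(weights$out)),
    v = list(conv = purrr::map(weights$conv, zero_like),
             dense = zero_like(weights$dense), out = zero_like(weights$out)),
    t = 0
  )
}

adam_update <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1
  step <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^state$t)
    vhat <- v / (1 - beta2^state$t)
    list(w = w - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (l in seq_along(weights$conv)) {
    for (nm in c("W", "b")) {
      u <- step(weights$conv[[l]][[nm]], grads$conv[[l]][[nm]],
                state$m$conv[[l]][[nm]], state$v$conv[[l]][[nm]])
      weights$conv[[l]][[nm]] <- u$w
      state$m$conv[[l]][[nm]] <- u$m
      state$v$conv[[l]][[nm]] <- u$v
    }
  }
  for (layer in c("dense", "out")) {
    for (nm in c("W", "b")) {
      u <- step(weights[[layer]][[nm]], grads[[layer]][[nm]],
                state$m[[layer]][[nm]], state$v[[layer]][[nm]])
      weights[[layer]][[nm]] <- u$w
      state$m[[layer]][[nm]] <- u$m
      state$v[[layer]][[nm]] <- u$v
    }
  }
  list(weights = weights, state = state)
}

# ---- user-facing surface ----------------------------------------------------

#' Build an untrained RMS regressor
#'
#' Instantiates the network `[conv(k=3) -> ReLU -> maxpool(2)] x blocks ->
#' flatten -> dense(128) -> ReLU -> dropout(0.5) -> linear(1)` with
#' deterministic He-initialized weights.
#'
#' @param config A [cnn_config()].
#' @return An `rms_regressor` object (untrained).
#' @export
#' @examples
#' m <- build_rms_regressor(cnn_config())
#' m$n_params
build_rms_regressor <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  weights <- cnn_init_weights(config)
  structure(
    list(config = config, weights = weights, n_params = cnn_n_params(weights),
         target_scale = 1, trained = FALSE, loss_trace = NULL),
    class = "rms_regressor"
  )
}

pairs_to_tensor <- function(pairs, input_len) {
  lens <- lengths(pairs$samples)
  if (any(lens != input_len)) {
    stop("window length ", lens[which(lens != input_len)[1]],
         " does not match the configured input_len ", input_len, call. = FALSE)
  }
  # per-window zero-mean standardization removes the PPG DC offset
  X <- t(vapply(pairs$samples, function(x) x - mean(x), numeric(input_len)))
  array(X, c(nrow(pairs), input_len, 1))
}

#' Train the PPG-to-EMG-RMS regressor
#'
#' Minimizes the L1 loss between the network output and the EMG RMS target by
#' mini-batch Adam. Inputs are standardized to zero mean per window; targets
#' are divided by their training-set mean (undone at inference), which keeps
#' the L1 scale stable across the wide dynamic range of sEMG RMS values.
#' A fraction of the pairs is held out to monitor validation loss; training
#' stops early when it no longer improves and the best weights are restored.
#'
#' @param pairs Pair tibble from [pair_study()] (columns `samples`, `r`).
#' @param config A [cnn_config()].
#' @return A trained `rms_regressor` with a per-epoch `loss_trace` tibble.
#' @export
train_rms_regressor <- function(pairs, config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  if (!is.data.frame(pairs) || nrow(pairs) == 0) {
    stop("training set is empty", call. = FALSE)
  }
  model <- build_rms_regressor(config)
  X_all <- pairs_to_tensor(pairs, config$input_len)
  r_all <- pairs$r
  scale <- mean(r_all)
  if (scale <= 0) scale <- 1
  r_sc <- r_all / scale
  n <- nrow(pairs)

  withr::with_seed(config$seed + 1L, {
    n_val <- floor(config$validation_frac * n)
    idx <- sample.int(n)
    val_idx <- if (n_val >= 1) idx[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(idx, val_idx)
    weights <- model$weights
    state <- adam_state_init(weights)
    best <- list(loss = Inf, weights = weights, epoch = 0)
    trace <- vector("list", config$epochs)
    wait <- 0
    for (epoch in seq_len(config$epochs)) {
      lr_epoch <- config$learning_rate * config$lr_decay^(epoch - 1)
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        Xb <- X_all[bi, , , drop = FALSE]
        fwd <- cnn_forward(weights, Xb, config, training = TRUE)
        loss <- l1_loss(fwd$y, r_sc[bi])
        grads <- cnn_backward(weights, Xb, fwd$y, r_sc[bi], fwd$cache, config)
        upd <- adam_update(weights, grads, state, lr_epoch)
        weights <- upd$weights
        state <- upd$state
        ep_loss <- ep_loss + loss * length(bi)
      }
      ep_loss <- ep_loss / length(ord)
      val_loss <- if (length(val_idx)) {
        fv <- cnn_forward(weights, X_all[val_idx, , , drop = FALSE], config,
                          training = FALSE)
        l1_loss(fv$y, r_sc[val_idx])
      } else NA_real_
      trace[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = ep_loss,
                                       val_loss = val_loss)
      monitor <- if (is.na(val_loss)) ep_loss else val_loss
      if (monitor < best$loss - 1e-6) {
        best <- list(loss = monitor, weights = weights, epoch = epoch)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= config$patience) break
      }
    }
    model$weights <- best$weights
    model$best_epoch <- best$epoch
    model$n_train <- length(tr_idx)
    model$loss_trace <- dplyr::bind_rows(trace[!vapply(trace, is.null, TRUE)])
  })
  model$target_scale <- scale
  model$trained <- TRUE
  model
}

#' Predict EMG RMS from PPG windows
#'
#' Runs the trained network in inference mode (dropout disabled, so output is
#' deterministic), undoes the training-set target scaling and clamps
#' predictions at zero, since an RMS is non-negative by definition.
#'
#' @param model A trained `rms_regressor`.
#' @param windows Window or pair tibble with a `samples` list-column.
#' @return Numeric vector, one non-negative RMS estimate per window.
#' @export
predict_rms <- function(model, windows) {
  stopifnot(inherits(model, "rms_regressor"))
  if (!is.data.frame(windows)) stop("windows must be a tibble", call. = FALSE)
  if (nrow(windows) == 0) return(numeric(0))
  X <- pairs_to_tensor(windows, model$config$input_len)
  fwd <- cnn_forward(model$weights, X, model$config, training = FALSE)
  pmax(fwd$y * model$target_scale, 0)
}

#' @export
print.rms_regressor <- function(x, ...) {
  cat("1-D CNN RMS regressor\n")
  cat("  blocks:", paste(x$config$conv_filters, collapse = ", "),
      "filters; kernel", x$config$kernel_size, "; pool", x$config$pool_size, "\n")
  cat("  parameters:", format(x$n_params, big.mark = ","), "\n")
  cat("  trained:", x$trained,
      if (x$trained) paste0("(best epoch ", x$best_epoch, ")"), "\n")
  invisible(x)
}
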