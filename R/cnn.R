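# 1-D convolution + max-pool stack and the fully connected sigmoid head.
# Single-sample layout: rows = positions, columns = channels.

conv1d_fwd <- function(X, W, b, ks) {
  Tn <- nrow(X)
  if (Tn < ks) {
    stop("sequence length ", Tn, " shorter than the convolution kernel (",
         ks, ")", call. = FALSE)
  }
  Tout <- Tn - ks + 1L
  X2 <- do.call(cbind, lapply(0:(ks - 1L), function(s) {
    X[(1L + s):(Tout + s), , drop = FALSE]
  }))
  Y <- sweep(X2 %*% W, 2L, b, `+`)
  list(Y = Y, X2 = X2)
}

conv1d_bwd <- function(dY, X2, W, ks, Tn, Cin) {
  dW <- crossprod(X2, dY)
  db <- colSums(dY)
  dX2 <- dY %*% t(W)
  Tout <- nrow(dY)
  dX <- matrix(0, Tn, Cin)
  for (s in 0:(ks - 1L)) {
    cols <- s * Cin + seq_len(Cin)
    dX[(1L + s):(Tout + s), ] <- dX[(1L + s):(Tout + s), ] +
      dX2[, cols, drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

maxpool2_fwd <- function(X) {
  npool <- nrow(X) %/% 2L
  if (npool < 1L) {
    stop("sequence too short to max-pool (length ", nrow(X), ")",
         call. = FALSE)
  }
  X1 <- X[seq(1L, 2L * npool, by = 2L), , drop = FALSE]
  X2 <- X[seq(2L, 2L * npool, by = 2L), , drop = FALSE]
  take1 <- X1 >= X2
  list(Y = ifelse(take1, X1, X2), take1 = take1, n_in = nrow(X))
}

maxpool2_bwd <- function(dY, cache, Cin) {
  npool <- nrow(dY)
  dX <- matrix(0, cache$n_in, Cin)
  d1 <- dY * cache$take1
  d2 <- dY * !cache$take1
  dX[seq(1L, 2L * npool, by = 2L), ] <- d1
  dX[seq(2L, 2L * npool, by = 2L), ] <- d2
  dX
}

cnn_params <- function(in_channels, filters = 64L, n_layers = 3L,
                       kernel_size = 2L, seed = 1L) {
  local_seed(seed)
  lapply(seq_len(n_layers), function(l) {
    cin <- if (l == 1L) in_channels else filters
    list(W = glorot(kernel_size * cin, filters), b = rep(0, filters))
  })
}

# conv -> relu -> maxpool(width 2, stride 2), repeated; flattened output
cnn_fwd <- function(X, params, kernel_size, keep_cache = FALSE) {
  caches <- vector("list", length(params))
  for (l in seq_along(params)) {
    cv <- conv1d_fwd(X, params[[l]]$W, params[[l]]$b, kernel_size)
    Xr <- relu(cv$Y)
    pl <- maxpool2_fwd(Xr)
    caches[[l]] <- list(X2 = cv$X2, relu_mask = cv$Y > 0, pool = pl,
                        Tn = nrow(X), Cin = ncol(X))
    X <- pl$Y
  }
  y <- as.vector(X)
  if (keep_cache) list(y = y, out_dim = dim(X), caches = caches) else y
}

cnn_bwd <- function(dy, fcache, params, kernel_size) {
  dX <- matrix(dy, fcache$out_dim[1], fcache$out_dim[2])
  grads <- vector("list", length(params))
  for (l in rev(seq_along(params))) {
    cc <- fcache$caches[[l]]
    dXr <- maxpool2_bwd(dX, cc$pool, ncol(dX))
    dY <- dXr * cc$relu_mask
    cb <- conv1d_bwd(dY, cc$X2, params[[l]]$W, kernel_size, cc$Tn, cc$Cin)
    grads[[l]] <- list(W = cb$dW, b = cb$db)
    dX <- cb$dX
  }
  list(dX = dX, grads = grads)
}

#' Run the local-feature CNN on a feature matrix
#'
#' Applies `n_layers` rounds of 1-D convolution (kernel along the
#' position axis), ReLU and width-2/stride-2 max-pooling, then flattens
#' the result into the feature vector consumed by the classifier head.
#'
#' @param X Numeric matrix, rows = positions, columns = channels.
#' @param params CNN parameters as built by the model constructors.
#' @param kernel_size Convolution kernel length (default 2).
#' @return Numeric vector of flattened features.
#' @export
cnn_head <- function(X, params, kernel_size = 2L) {
  cnn_fwd(X, params, kernel_size)
}

# ---- batched variants on stacked (B*T) x C matrices ---------------------
# Stacked layout (time-major blocks of B rows) makes the valid positions
# of a kernel-ks convolution contiguous row ranges, so the whole batch
# convolves as one matrix product; width-2/stride-2 pooling gathers the
# odd/even timestep blocks.

cnn_batch_fwd <- function(Xs, B, Tn, params, kernel_size,
                          keep_cache = FALSE) {
  caches <- vector("list", length(params))
  for (l in seq_along(params)) {
    if (Tn < kernel_size) {
      stop("sequence length ", Tn, " shorter than the convolution kernel (",
           kernel_size, ")", call. = FALSE)
    }
    Tout <- Tn - kernel_size + 1L
    X2 <- do.call(cbind, lapply(0:(kernel_size - 1L), function(s) {
      Xs[(s * B + 1L):((Tout + s) * B), , drop = FALSE]
    }))
    Y <- X2 %*% params[[l]]$W + rep(params[[l]]$b, each = B * Tout)
    Xr <- Y
    Xr[Y < 0] <- 0
    npool <- Tout %/% 2L
    if (npool < 1L) {
      stop("sequence too short to max-pool (length ", Tout, ")",
           call. = FALSE)
    }
    idx1 <- rep((seq_len(npool) * 2L - 2L) * B, each = B) + seq_len(B)
    idx2 <- idx1 + B
    X1 <- Xr[idx1, , drop = FALSE]
    X2p <- Xr[idx2, , drop = FALSE]
    take1 <- X1 >= X2p
    out <- ifelse(take1, X1, X2p)
    caches[[l]] <- list(X2 = X2, relu_mask = Y > 0, take1 = take1,
                        idx1 = idx1, idx2 = idx2, Tn = Tn, Tout = Tout,
                        Cin = ncol(Xs), n_in = B * Tout)
    Xs <- out
    Tn <- npool
  }
  # rows b + (t-1)B with columns c flatten per sample in (t, c) order,
  # matching as.vector() of a single-sample [T, C] matrix
  Ymat <- matrix(Xs, B, Tn * ncol(Xs))
  if (keep_cache) list(Y = Ymat, out_T = Tn, out_C = ncol(Xs),
                       caches = caches) else Ymat
}

cnn_batch_bwd <- function(dY, fcache, B, params, kernel_size) {
  dXs <- matrix(dY, B * fcache$out_T, fcache$out_C)
  grads <- vector("list", length(params))
  for (l in rev(seq_along(params))) {
    cc <- fcache$caches[[l]]
    dXr <- matrix(0, cc$n_in, ncol(dXs))
    dXr[cc$idx1, ] <- dXs * cc$take1
    dXr[cc$idx2, ] <- dXs * !cc$take1
    dYc <- dXr * cc$relu_mask
    grads[[l]] <- list(W = crossprod(cc$X2, dYc), b = colSums(dYc))
    dX2 <- dYc %*% t(params[[l]]$W)
    dX <- matrix(0, cc$Tn * B, cc$Cin)
    for (s in 0:(kernel_size - 1L)) {
      rows <- (s * B + 1L):((cc$Tout + s) * B)
      cols <- s * cc$Cin + seq_len(cc$Cin)
      dX[rows, ] <- dX[rows, ] + dX2[, cols, drop = FALSE]
    }
    dXs <- dX
  }
  list(dX = dXs, grads = grads)
}

# batched two-layer head: Y (B x in_dim) -> probabilities (B)
fc_batch_fwd <- function(Y, params, dropout = 0.5, training = FALSE) {
  Hpre <- Y %*% params$W1 + rep(params$b1, each = nrow(Y))
  H <- Hpre
  H[Hpre < 0] <- 0
  mask <- NULL
  if (training && dropout > 0) {
    keep <- 1 - dropout
    mask <- matrix((stats::runif(length(H)) < keep) / keep, nrow(H))
    H <- H * mask
  }
  logit <- as.vector(H %*% params$W2) + params$b2
  list(p = sigmoid(logit), Y = Y, H = H, relu_mask = Hpre > 0,
       drop_mask = mask)
}

fc_batch_bwd <- function(dlogit, cache, params) {
  dlogit <- matrix(dlogit, ncol = 1L)
  dW2 <- crossprod(cache$H, dlogit)
  db2 <- sum(dlogit)
  dH <- tcrossprod(dlogit, params$W2)
  if (!is.null(cache$drop_mask)) dH <- dH * cache$drop_mask
  dHpre <- dH * cache$relu_mask
  list(dY = tcrossprod(dHpre, params$W1),
       grads = list(W1 = crossprod(cache$Y, dHpre), b1 = colSums(dHpre),
                    W2 = dW2, b2 = db2))
}

fc_params <- function(in_dim, hidden = 64L, seed = 1L) {
  local_seed(seed)
  list(W1 = glorot(in_dim, hidden), b1 = rep(0, hidden),
       W2 = glorot(hidden, 1L), b2 = 0)
}

#' Two-layer fully connected head with sigmoid output
#'
#' `h = ReLU(y W1 + b1)`, optional inverted dropout on `h` (training mode
#' only), then `p = sigmoid(h W2 + b2)`. In evaluation mode the output is
#' deterministic.
#'
#' @param y Flattened feature vector.
#' @param params Head parameters (`W1`, `b1`, `W2`, `b2`).
#' @param dropout Dropout rate in `[0, 1)`; applied only when `training`.
#' @param training Logical; enables dropout.
#' @return Probability in `[0, 1]`.
#' @export
classify <- function(y, params, dropout = 0.5, training = FALSE) {
  fc_fwd(y, params, dropout, training)$p
}

fc_fwd <- function(y, params, dropout = 0.5, training = FALSE) {
  h_pre <- as.vector(y %*% params$W1) + params$b1
  h <- pmax(h_pre, 0)
  mask <- NULL
  if (training && dropout > 0) {
    keep <- 1 - dropout
    mask <- (stats::runif(length(h)) < keep) / keep
    h <- h * mask
  }
  logit <- sum(h * params$W2) + params$b2
  list(p = sigmoid(logit), logit = logit, h = h, relu_mask = h_pre > 0,
       drop_mask = mask, y = y)
}

fc_bwd <- function(dlogit, cache, params) {
  dW2 <- matrix(cache$h * dlogit, ncol = 1L)
  db2 <- dlogit
  dh <- as.vector(params$W2) * dlogit
  if (!is.null(cache$drop_mask)) dh <- dh * cache$drop_mask
  dh_pre <- dh * cache$relu_mask
  dW1 <- outer(cache$y, dh_pre)
  db1 <- dh_pre
  dy <- as.vector(params$W1 %*% dh_pre)
  list(dy = dy, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}
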