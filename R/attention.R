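# Scaled dot-product multi-head self-attention on a single sequence
# (rows = positions, columns = features). Used both inside the transformer
# encoder layers and as the classifier's stand-alone attention block.

mha_init <- function(d_model) {
  list(Wq = glorot(d_model, d_model), bq = rep(0, d_model),
       Wk = glorot(d_model, d_model), bk = rep(0, d_model),
       Wv = glorot(d_model, d_model), bv = rep(0, d_model),
       Wo = glorot(d_model, d_model), bo = rep(0, d_model))
}

mha_fwd <- function(X, par, n_heads) {
  d <- ncol(X)
  if (d %% n_heads != 0L) {
    stop("feature width ", d, " not divisible by n_heads = ", n_heads,
         call. = FALSE)
  }
  dh <- d %/% n_heads
  Tn <- nrow(X)
  Q <- sweep(X %*% par$Wq, 2L, par$bq, `+`)
  K <- sweep(X %*% par$Wk, 2L, par$bk, `+`)
  V <- sweep(X %*% par$Wv, 2L, par$bv, `+`)
  A <- matrix(0, Tn, d)
  attw <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    W <- softmax_rows(S)
    attw[[h]] <- W
    A[, cols] <- W %*% V[, cols, drop = FALSE]
  }
  O <- sweep(A %*% par$Wo, 2L, par$bo, `+`)
  list(O = O, cache = list(X = X, Q = Q, K = K, V = V, A = A,
                           attw = attw, n_heads = n_heads, dh = dh))
}

mha_bwd <- function(dO, cache, par) {
  X <- cache$X; Q <- cache$Q; K <- cache$K; V <- cache$V
  n_heads <- cache$n_heads; dh <- cache$dh
  dA <- dO %*% t(par$Wo)
  g <- list(Wq = NULL, bq = NULL, Wk = NULL, bk = NULL,
            Wv = NULL, bv = NULL,
            Wo = t(cache$A) %*% dO, bo = colSums(dO))
  dQ <- matrix(0, nrow(X), ncol(X))
  dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    W <- cache$attw[[h]]
    dAh <- dA[, cols, drop = FALSE]
    dW <- dAh %*% t(V[, cols, drop = FALSE])
    dV[, cols] <- t(W) %*% dAh
    # softmax backward, row-wise
    dS <- W * (dW - rowSums(dW * W))
    dQ[, cols] <- dS %*% K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- t(dS) %*% Q[, cols, drop = FALSE] / sqrt(dh)
  }
  g$Wq <- t(X) %*% dQ; g$bq <- colSums(dQ)
  g$Wk <- t(X) %*% dK; g$bk <- colSums(dK)
  g$Wv <- t(X) %*% dV; g$bv <- colSums(dV)
  dX <- dQ %*% t(par$Wq) + dK %*% t(par$Wk) + dV %*% t(par$Wv)
  list(dX = dX, grads = g)
}

# Batched variant on stacked (B*T) x d matrices (time-major blocks of B
# rows): projections run as single wide products, only the per-head score
# softmax loops over samples.
att_batch_fwd <- function(Mmat, B, Tn, par, n_heads) {
  d <- ncol(Mmat)
  if (d %% n_heads != 0L) {
    stop("feature width ", d, " not divisible by n_heads = ", n_heads,
         call. = FALSE)
  }
  Q <- Mmat %*% par$Wq + rep(par$bq, each = nrow(Mmat))
  K <- Mmat %*% par$Wk + rep(par$bk, each = nrow(Mmat))
  V <- Mmat %*% par$Wv + rep(par$bv, each = nrow(Mmat))
  sc <- att_scores_fwd(Q, K, V, B, Tn, n_heads)
  O <- sc$A %*% par$Wo + rep(par$bo, each = nrow(Mmat))
  list(O = O, cache = list(Mmat = Mmat, Q = Q, K = K, V = V, A = sc$A,
                           attw = sc$W, B = B, Tn = Tn,
                           n_heads = n_heads))
}

att_batch_bwd <- function(dO, cache, par) {
  dA <- dO %*% t(par$Wo)
  sc <- att_scores_bwd(dA, cache$Q, cache$K, cache$V, cache$attw,
                       cache$B, cache$Tn, cache$n_heads)
  grads <- list(Wq = crossprod(cache$Mmat, sc$dQ), bq = colSums(sc$dQ),
                Wk = crossprod(cache$Mmat, sc$dK), bk = colSums(sc$dK),
                Wv = crossprod(cache$Mmat, sc$dV), bv = colSums(sc$dV),
                Wo = crossprod(cache$A, dO), bo = colSums(dO))
  dM <- sc$dQ %*% t(par$Wq) + sc$dK %*% t(par$Wk) + sc$dV %*% t(par$Wv)
  list(dM = dM, grads = grads)
}

#' Stand-alone multi-head self-attention block
#'
#' Applies standard scaled dot-product multi-head self-attention to a
#' per-position feature matrix; the output has the same shape as the
#' input. This is the attention module the classifier runs on the
#' concatenated GRU branch outputs.
#'
#' @param M Numeric matrix, rows = positions, columns = features.
#' @param par Attention parameters (query/key/value/output projections)
#'   as created internally by the model constructors.
#' @param n_heads Number of attention heads; must divide `ncol(M)`.
#' @return Numeric matrix of the same shape as `M`.
#' @export
attention_block <- function(M, par, n_heads = 4L) {
  mha_fwd(M, par, n_heads)$O
}
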