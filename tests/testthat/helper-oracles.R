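# Independent straight-line reference implementations used as oracles.
# These are deliberately naive (explicit loops, no sharing with the
# package internals) so agreement is evidence of correctness.

# GRU recurrence transcribed gate by gate for a single sequence.
# X: T x din matrix; par: one layer's parameters; printed convention
# keeps old memory with weight z (standard = FALSE).
oracle_gru_layer <- function(X, par, standard = FALSE) {
  Tn <- nrow(X)
  h <- ncol(par$Wz)
  M <- matrix(0, Tn, h)
  m_prev <- rep(0, h)
  for (t in seq_len(Tn)) {
    x <- X[t, ]
    z <- 1 / (1 + exp(-(as.vector(x %*% par$Wz) + as.vector(m_prev %*% par$Uz) + par$bz)))
    r <- 1 / (1 + exp(-(as.vector(x %*% par$Wr) + as.vector(m_prev %*% par$Ur) + par$br)))
    mt <- tanh(as.vector(x %*% par$Wm) + r * as.vector(m_prev %*% par$Um) + par$bm)
    m_cur <- if (standard) (1 - z) * m_prev + z * mt else z * m_prev + (1 - z) * mt
    M[t, ] <- m_cur
    m_prev <- m_cur
  }
  M
}

oracle_gru_stack <- function(X, params, standard = FALSE) {
  for (par in params) X <- oracle_gru_layer(X, par, standard)
  X
}

# scaled dot-product multi-head self-attention with explicit loops
oracle_attention <- function(X, par, n_heads) {
  Tn <- nrow(X)
  d <- ncol(X)
  dh <- d %/% n_heads
  Q <- matrix(0, Tn, d); K <- Q; V <- Q
  for (i in seq_len(Tn)) {
    Q[i, ] <- as.vector(X[i, ] %*% par$Wq) + par$bq
    K[i, ] <- as.vector(X[i, ] %*% par$Wk) + par$bk
    V[i, ] <- as.vector(X[i, ] %*% par$Wv) + par$bv
  }
  A <- matrix(0, Tn, d)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    for (i in seq_len(Tn)) {
      s <- numeric(Tn)
      for (j in seq_len(Tn)) {
        s[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dh)
      }
      w <- exp(s - max(s)); w <- w / sum(w)
      for (c in cols) A[i, c] <- sum(w * V[, c])
    }
  }
  O <- matrix(0, Tn, d)
  for (i in seq_len(Tn)) O[i, ] <- as.vector(A[i, ] %*% par$Wo) + par$bo
  O
}

# valid 1-D convolution by sliding-window summation
oracle_conv1d <- function(X, W, b, ks) {
  Tn <- nrow(X); Cin <- ncol(X); Cout <- ncol(W)
  Tout <- Tn - ks + 1
  Y <- matrix(0, Tout, Cout)
  for (t in seq_len(Tout)) {
    for (co in seq_len(Cout)) {
      acc <- b[co]
      for (s in 0:(ks - 1)) {
        for (ci in seq_len(Cin)) {
          acc <- acc + X[t + s, ci] * W[s * Cin + ci, co]
        }
      }
      Y[t, co] <- acc
    }
  }
  Y
}

# AUC by counting over all positive-negative pairs (ties count half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Shannon entropy of one distribution, direct summation (nats)
oracle_entropy <- function(p) {
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log(pi)
  s
}

# one post-LN transformer encoder layer, straight-line
oracle_encoder_layer <- function(X, par, n_heads, eps = 1e-5) {
  ln <- function(M, g, b) {
    out <- M
    for (i in seq_len(nrow(M))) {
      mu <- mean(M[i, ])
      v <- mean((M[i, ] - mu)^2)
      out[i, ] <- (M[i, ] - mu) / sqrt(v + eps) * g + b
    }
    out
  }
  O <- oracle_attention(X, par, n_heads)
  X1 <- ln(X + O, par$ln1_g, par$ln1_b)
  FF <- matrix(0, nrow(X1), ncol(X1))
  for (i in seq_len(nrow(X1))) {
    hdn <- pmax(0, as.vector(X1[i, ] %*% par$W1) + par$b1f)
    FF[i, ] <- as.vector(hdn %*% par$W2) + par$b2f
  }
  ln(X1 + FF, par$ln2_g, par$ln2_b)
}

# confident-learning filter by recomputing means and comparing samples
oracle_cl_filter <- function(probs, labels, target) {
  in_t <- which(labels == target)
  if (length(in_t) == 0) return(list(kept = integer(0), removed = integer(0)))
  tj <- mean(probs[in_t, target + 1])
  removed <- integer(0)
  kept <- integer(0)
  for (i in in_t) {
    if (probs[i, target + 1] < tj) removed <- c(removed, i)
    else kept <- c(kept, i)
  }
  list(kept = kept, removed = removed, threshold = tj)
}

# small random window tibble for pipeline tests
make_toy_windows <- function(n_pos = 20, n_neg = 40, k = 5, seed = 1) {
  generate_synth(synth_config(n_pos = n_pos, n_neg = n_neg, k = k,
                              enrichment = c(A = 2, K = 2, R = 2, V = 2),
                              decay = 0.2),
                 seed = seed)
}

# tiny configuration that exercises every component quickly
tiny_config <- function(k = 5, ...) {
  model_config(k = k,
               encoder = encoder_config(n_layers = 2, d_model = 16,
                                        n_heads = 2, ffn_dim = 32,
                                        max_len = 2 * k + 1),
               gru_hidden = 16, gru_layers = 2, n_heads = 2,
               cnn_layers = 2, filters = 8, fc_hidden = 8,
               mlm = list(epochs = 1, batch_size = 16),
               train = list(epochs = 2, batch_size = 32,
                            val_fraction = 0.25),
               ...)
}
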