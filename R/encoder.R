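#' Transformer encoder configuration
#'
#' The encoder is a stack of identical transformer blocks, each applying
#' multi-head self-attention and a position-wise feed-forward network,
#' both wrapped in residual connections with post-layer normalization
#' (`Output = LayerNorm(x + Sublayer(x))`; the feed-forward part is
#' `FFN(x) = max(0, x W1 + b1) W2 + b2`). The `"desk"` profile (4 layers,
#' 64 dimensions) is sized for CPU work; the `"paper"` profile mirrors a
#' BERT-base-scale stack (12 layers, 768 dimensions).
#'
#' @param n_layers Number of encoder layers.
#' @param d_model Embedding width per token.
#' @param n_heads Attention heads; must divide `d_model`.
#' @param ffn_dim Hidden width of the position-wise feed-forward network.
#' @param max_len Maximum sequence length the positional table supports.
#' @param profile Convenience preset; explicit arguments override it.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = NULL, d_model = NULL, n_heads = NULL,
                           ffn_dim = NULL, max_len = 64L,
                           profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  preset <- switch(profile,
    desk  = list(n_layers = 4L, d_model = 64L, n_heads = 4L),
    paper = list(n_layers = 12L, d_model = 768L, n_heads = 12L))
  n_layers <- as.integer(n_layers %||% preset$n_layers)
  d_model <- as.integer(d_model %||% preset$d_model)
  n_heads <- as.integer(n_heads %||% preset$n_heads)
  ffn_dim <- as.integer(ffn_dim %||% (4L * d_model))
  stopifnot(n_layers >= 1L, d_model >= 1L, n_heads >= 1L,
            ffn_dim >= 1L, max_len >= 1L)
  if (d_model %% n_heads != 0L) {
    stop("d_model must be divisible by n_heads", call. = FALSE)
  }
  structure(list(n_layers = n_layers, d_model = d_model, n_heads = n_heads,
                 ffn_dim = ffn_dim, max_len = as.integer(max_len)),
            class = "encoder_config")
}

#' Initialize encoder parameters
#'
#' Token embeddings, learned positional embeddings, per-layer attention /
#' feed-forward / LayerNorm weights, and the masked-language-model output
#' bias. The MLM output projection is tied to the token embedding matrix.
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed for the random initialization.
#' @return A nested list of parameter matrices (class `encoder_params`).
#' @export
encoder_init <- function(config, seed = 1L) {
  local_seed(seed)
  d <- config$d_model
  f <- config$ffn_dim
  V <- vocab_size()
  layers <- lapply(seq_len(config$n_layers), function(l) {
    c(mha_init(d),
      list(ln1_g = rep(1, d), ln1_b = rep(0, d),
           W1 = glorot(d, f), b1f = rep(0, f),
           W2 = glorot(f, d), b2f = rep(0, d),
           ln2_g = rep(1, d), ln2_b = rep(0, d)))
  })
  structure(list(E = matrix(stats::rnorm(V * d, sd = 0.02), V, d),
                 P = matrix(stats::rnorm(config$max_len * d, sd = 0.02),
                            config$max_len, d),
                 layers = layers,
                 b_mlm = rep(0, V)),
            class = "encoder_params")
}

# forward through one encoder layer; caches everything backward needs
encoder_layer_fwd <- function(X, par, n_heads) {
  att <- mha_fwd(X, par, n_heads)
  R1 <- X + att$O
  ln1 <- layernorm_fwd(R1, par$ln1_g, par$ln1_b)
  H1 <- sweep(ln1$y %*% par$W1, 2L, par$b1f, `+`)
  Hr <- relu(H1)
  Ff <- sweep(Hr %*% par$W2, 2L, par$b2f, `+`)
  R2 <- ln1$y + Ff
  ln2 <- layernorm_fwd(R2, par$ln2_g, par$ln2_b)
  list(out = ln2$y,
       cache = list(att = att$cache, ln1 = ln1, ln2 = ln2,
                    X1 = ln1$y, Hr = Hr, relu_mask = H1 > 0))
}

encoder_layer_bwd <- function(dY, cache, par) {
  ln2b <- layernorm_bwd(dY, cache$ln2, par$ln2_g)
  dR2 <- ln2b$dx
  dFf <- dR2
  dHr <- dFf %*% t(par$W2)
  dH1 <- dHr * cache$relu_mask
  dX1 <- dR2 + dH1 %*% t(par$W1)
  ln1b <- layernorm_bwd(dX1, cache$ln1, par$ln1_g)
  dR1 <- ln1b$dx
  attb <- mha_bwd(dR1, cache$att, par)
  grads <- c(attb$grads,
             list(ln1_g = ln1b$dg, ln1_b = ln1b$db,
                  W1 = t(cache$X1) %*% dH1, b1f = colSums(dH1),
                  W2 = t(cache$Hr) %*% dFf, b2f = colSums(dFf),
                  ln2_g = ln2b$dg, ln2_b = ln2b$db))
  list(dX = dR1 + attb$dX, grads = grads)
}

#' Run the encoder and return every layer's output
#'
#' Embeds a token sequence (token + positional embeddings) and applies the
#' full encoder stack, returning the per-layer hidden-state matrices
#' rather than only the final layer — the entropy-weighted aggregation
#' consumes all of them.
#'
#' @param tokens Integer vector of 0-based token ids (see [tokenize()]).
#' @param params Encoder parameters from [encoder_init()] or
#'   [pretrain_mlm()].
#' @param config The matching [encoder_config()].
#' @param keep_cache Keep forward intermediates (used internally for the
#'   MLM backward pass).
#' @return A list with `layers` (list of `length(tokens) x d_model`
#'   matrices, one per encoder layer) and, if requested, `cache`.
#' @export
encode_layers <- function(tokens, params, config, keep_cache = FALSE) {
  Tn <- length(tokens)
  if (Tn == 0L) stop("cannot encode an empty sequence", call. = FALSE)
  if (Tn > config$max_len) {
    stop("sequence length ", Tn, " exceeds max_len ", config$max_len,
         call. = FALSE)
  }
  X <- params$E[tokens + 1L, , drop = FALSE] +
    params$P[seq_len(Tn), , drop = FALSE]
  X0 <- X
  layers <- vector("list", config$n_layers)
  caches <- if (keep_cache) vector("list", config$n_layers) else NULL
  for (l in seq_len(config$n_layers)) {
    step <- encoder_layer_fwd(X, params$layers[[l]], config$n_heads)
    X <- step$out
    layers[[l]] <- X
    if (keep_cache) caches[[l]] <- step$cache
  }
  out <- list(layers = layers)
  if (keep_cache) out$cache <- list(layer_caches = caches, X0 = X0,
                                    tokens = tokens)
  out
}

# ---- masked-language-model pretraining ----------------------------------

#' Mask a token sequence for masked-language-model training
#'
#' Selects `max(1, round(rate * n))` of the non-pad positions (none if the
#' sequence is all padding). Of the selected positions, 80% are replaced
#' by the `[MASK]` token, 10% keep their original token, and 10% receive a
#' random residue token (deterministic proportional split, largest share
#' first).
#'
#' @param tokens Integer vector of 0-based token ids.
#' @param rate Masking rate in (0, 1); default 0.15.
#' @param seed Integer seed; the same seed reproduces the same batch.
#' @return A list with `input_ids`, `target_ids` (original tokens at the
#'   masked positions) and `mask_positions` (1-based indices).
#' @export
mask_for_mlm <- function(tokens, rate = 0.15, seed = 1L) {
  stopifnot(rate > 0, rate < 1, length(tokens) > 0L)
  local_seed(seed)
  eligible <- which(tokens != pad_id())
  if (length(eligible) == 0L) {
    return(list(input_ids = tokens, target_ids = integer(0),
                mask_positions = integer(0)))
  }
  m <- max(1L, round(rate * length(eligible)))
  sel <- if (length(eligible) == 1L) eligible else
    sample(eligible, min(m, length(eligible)))
  m <- length(sel)
  n_mask <- round(0.8 * m)
  n_keep <- round(0.1 * m)
  n_rand <- m - n_mask - n_keep
  input <- tokens
  input[sel[seq_len(n_mask)]] <- mask_id()
  if (n_rand > 0) {
    rnd_pos <- sel[(n_mask + n_keep + 1L):m]
    input[rnd_pos] <- residue_ids()[sample.int(20L, n_rand, replace = TRUE)]
  }
  list(input_ids = input, target_ids = tokens[sel], mask_positions = sel)
}

# forward + backward of the masked-token cross-entropy for one sequence;
# returns summed loss over masked positions plus parameter gradients
mlm_seq_grad <- function(batch, params, config) {
  enc <- encode_layers(batch$input_ids, params, config, keep_cache = TRUE)
  XL <- enc$layers[[config$n_layers]]
  mp <- batch$mask_positions
  Hm <- XL[mp, , drop = FALSE]
  logits <- sweep(Hm %*% t(params$E), 2L, params$b_mlm, `+`)
  P <- softmax_rows(logits)
  idx <- cbind(seq_along(mp), batch$target_ids + 1L)
  loss <- -sum(log(pmax(P[idx], 1e-12)))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  # head (tied to E)
  dE_head <- t(dlogits) %*% Hm
  db_mlm <- colSums(dlogits)
  dXL <- matrix(0, nrow(XL), ncol(XL))
  dXL[mp, ] <- dlogits %*% params$E
  # back through the layer stack
  layer_grads <- vector("list", config$n_layers)
  dX <- dXL
  for (l in rev(seq_len(config$n_layers))) {
    bl <- encoder_layer_bwd(dX, enc$cache$layer_caches[[l]],
                            params$layers[[l]])
    layer_grads[[l]] <- bl$grads
    dX <- bl$dX
  }
  dE <- dE_head
  toks <- enc$cache$tokens + 1L
  for (i in seq_along(toks)) dE[toks[i], ] <- dE[toks[i], ] + dX[i, ]
  dP <- matrix(0, nrow(params$P), ncol(params$P))
  dP[seq_len(nrow(dX)), ] <- dX
  list(loss = loss, n = length(mp),
       grads = list(E = dE, P = dP, layers = layer_grads, b_mlm = db_mlm))
}

#' Pretrain the encoder with a masked language model
#'
#' Trains the full encoder stack (embeddings, transformer layers and the
#' tied output head) to predict masked residues over a corpus of token
#' sequences, using Adam on the masked-token cross-entropy. A uniform
#' predictor scores `log(vocab_size())` nats per masked token; any
#' learning drives the loss below that baseline.
#'
#' @param corpus List of integer token-id vectors (e.g. tokenized
#'   windows).
#' @param config An [encoder_config()].
#' @param params Optional warm-start parameters; fresh ones are drawn when
#'   `NULL`.
#' @param epochs,batch_size,lr Training schedule.
#' @param rate Masking rate (see [mask_for_mlm()]).
#' @param seed Integer seed controlling initialization, shuffling and
#'   masking; runs are reproducible.
#' @return A list with `params` (trained `encoder_params`), `config` and
#'   `log` (tibble of per-epoch mean masked-token cross-entropy, nats).
#' @export
pretrain_mlm <- function(corpus, config, params = NULL, epochs = 3L,
                         batch_size = 16L, lr = 1e-3, rate = 0.15,
                         seed = 1L) {
  stopifnot(length(corpus) > 0L)
  if (is.null(params)) params <- encoder_init(config, seed = sub_seed(seed, 1L))
  opt <- adam_init(params[c("E", "P", "layers", "b_mlm")], lr = lr)
  local_seed(sub_seed(seed, 2L))
  n <- length(corpus)
  log_rows <- vector("list", epochs)
  mask_counter <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_tok <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      grads <- NULL
      b_loss <- 0; b_tok <- 0L
      for (i in idx) {
        mask_counter <- mask_counter + 1L
        mb <- mask_for_mlm(corpus[[i]], rate = rate,
                           seed = sub_seed(seed, 1000L + mask_counter))
        if (length(mb$mask_positions) == 0L) next
        sg <- mlm_seq_grad(mb, params, config)
        b_loss <- b_loss + sg$loss
        b_tok <- b_tok + sg$n
        grads <- if (is.null(grads)) sg$grads else tree_add(grads, sg$grads)
      }
      if (is.null(grads)) next
      grads <- tree_scale(grads, 1 / b_tok)
      assert_finite(b_loss, "MLM loss")
      sub <- params[c("E", "P", "layers", "b_mlm")]
      upd <- adam_step(sub, grads, opt)
      opt <- upd$state
      params$E <- upd$params$E
      params$P <- upd$params$P
      params$layers <- upd$params$layers
      params$b_mlm <- upd$params$b_mlm
      ep_loss <- ep_loss + b_loss
      ep_tok <- ep_tok + b_tok
    }
    log_rows[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss / ep_tok)
  }
  list(params = params, config = config, log = dplyr::bind_rows(log_rows))
}

#' Masked-token cross-entropy on a held-out corpus
#'
#' @param corpus List of token-id vectors.
#' @param params,config Trained encoder.
#' @param rate Masking rate.
#' @param seed Seed for the evaluation masking.
#' @return Mean cross-entropy per masked token, in nats.
#' @export
mlm_eval_loss <- function(corpus, params, config, rate = 0.15, seed = 99L) {
  tot <- 0; ntok <- 0L
  for (i in seq_along(corpus)) {
    mb <- mask_for_mlm(corpus[[i]], rate = rate, seed = sub_seed(seed, i))
    if (length(mb$mask_positions) == 0L) next
    enc <- encode_layers(mb$input_ids, params, config)
    H <- enc$layers[[config$n_layers]][mb$mask_positions, , drop = FALSE]
    P <- softmax_rows(sweep(H %*% t(params$E), 2L, params$b_mlm, `+`))
    idx <- cbind(seq_along(mb$mask_positions), mb$target_ids + 1L)
    tot <- tot - sum(log(pmax(P[idx], 1e-12)))
    ntok <- ntok + length(mb$mask_positions)
  }
  tot / ntok
}

# ---- information-entropy layer aggregation ------------------------------

#' Shannon entropy of a layer's residue distribution
#'
#' Projects a layer's hidden states through the (tied) masked-LM output
#' head to obtain a residue-vocabulary distribution at every position and
#' returns the mean positional Shannon entropy in nats. The uniform
#' distribution attains the maximum `log(V)`; a one-hot distribution
#' attains 0. Entropies feed [entropy_weights()], where the logarithm base
#' cancels, so weights are identical under `log2` and natural log.
#'
#' @param layer Numeric matrix of hidden states (positions x d_model).
#' @param head List with `W` (d_model x vocab projection) and `b` (bias);
#'   pass `mlm_head(params)` for the tied head.
#' @return Non-negative scalar entropy (nats).
#' @export
layer_entropy <- function(layer, head) {
  logits <- sweep(layer %*% head$W, 2L, head$b, `+`)
  P <- softmax_rows(logits)
  if (!all(is.finite(P))) stop("non-finite head probabilities", call. = FALSE)
  mean(-rowSums(ifelse(P > 0, P * log(P), 0)))
}

#' @rdname layer_entropy
#' @param params Encoder parameters; returns their tied MLM head.
#' @export
mlm_head <- function(params) list(W = t(params$E), b = params$b_mlm)

#' Entropy weights across encoder layers
#'
#' Normalizes per-layer entropies to weights `w_i = H_i / sum(H)`. Weights
#' are non-negative, preserve layer order and sum to 1. When every entropy
#' is (numerically) zero the ratio is 0/0 and the symmetric completion —
#' uniform weights — is returned.
#'
#' @param entropies Numeric vector of non-negative per-layer entropies.
#' @param tol Threshold below which the entropy total counts as zero.
#' @return Numeric weight vector of the same length.
#' @export
entropy_weights <- function(entropies, tol = 1e-12) {
  stopifnot(length(entropies) >= 1L, all(is.finite(entropies)),
            all(entropies >= 0))
  s <- sum(entropies)
  if (s <= tol) return(rep(1 / length(entropies), length(entropies)))
  entropies / s
}

#' Entropy-weighted sum of layer outputs
#'
#' Computes the aggregated embedding `L = sum_i w_i * L_i` over the
#' per-layer hidden-state matrices.
#'
#' @param layers List of equally shaped numeric matrices.
#' @param weights Numeric weights, one per layer.
#' @return Matrix of the common layer shape.
#' @export
aggregate_layers <- function(layers, weights) {
  stopifnot(length(layers) == length(weights))
  dims <- lapply(layers, dim)
  if (length(unique(dims)) != 1L) {
    stop("layer matrices must share one shape", call. = FALSE)
  }
  out <- layers[[1]] * weights[1]
  for (i in seq_along(layers)[-1]) out <- out + layers[[i]] * weights[i]
  out
}

# Batched entropy-aggregated encoding of n equal-length sequences.
# tok_mat: n x T integer matrix of token ids. Works on stacked
# (n*T) x d matrices (time-major blocks of n rows) so the projections
# and FFN run as single wide products; only the per-head attention
# softmax loops over sequences. Returns an [n, T, d_model] array of
# aggregated embeddings.
ie_encode_batch <- function(tok_mat, params, config, chunk = 1024L) {
  n_all <- nrow(tok_mat)
  Tn <- ncol(tok_mat)
  if (Tn > config$max_len) {
    stop("sequence length ", Tn, " exceeds max_len ", config$max_len,
         call. = FALSE)
  }
  d <- config$d_model
  out <- array(0, c(n_all, Tn, d))
  for (start in seq(1L, n_all, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_all)
    n <- length(idx)
    toks <- tok_mat[idx, , drop = FALSE]
    # stacked embedding: row i + (t-1)*n holds sequence i, position t
    X <- params$E[as.vector(toks) + 1L, , drop = FALSE] +
      params$P[rep(seq_len(Tn), each = n), , drop = FALSE]
    H <- matrix(0, n, config$n_layers)
    layers <- vector("list", config$n_layers)
    for (l in seq_len(config$n_layers)) {
      par <- params$layers[[l]]
      att <- att_batch_fwd(X, n, Tn, par, config$n_heads)
      ln1 <- layernorm_fwd(X + att$O, par$ln1_g, par$ln1_b)
      Hf <- relu(ln1$y %*% par$W1 + rep(par$b1f, each = n * Tn))
      Ff <- Hf %*% par$W2 + rep(par$b2f, each = n * Tn)
      X <- layernorm_fwd(ln1$y + Ff, par$ln2_g, par$ln2_b)$y
      layers[[l]] <- X
      # per-sequence mean positional entropy under the tied MLM head
      P <- softmax_rows(X %*% t(params$E) + rep(params$b_mlm, each = n * Tn))
      h_row <- -rowSums(ifelse(P > 0, P * log(P), 0))
      H[, l] <- rowsum(h_row, rep(seq_len(n), Tn))[, 1] / Tn
    }
    w <- H / rowSums(H)
    unif <- rowSums(H) <= 1e-12
    if (any(unif)) w[unif, ] <- 1 / config$n_layers
    agg <- matrix(0, n * Tn, d)
    seq_of_row <- rep(seq_len(n), Tn)
    for (l in seq_len(config$n_layers)) {
      agg <- agg + layers[[l]] * w[seq_of_row, l]
    }
    out[idx, , ] <- array(agg, c(n, Tn, d))
  }
  out
}

#' Entropy-aggregated encoding of one token sequence (IE-BERT)
#'
#' Runs the encoder, scores every layer's output by its mean positional
#' entropy under the tied MLM head, converts entropies to weights and
#' returns the weighted-sum embedding together with all intermediates.
#'
#' @param tokens Integer token-id vector.
#' @param params,config Trained encoder.
#' @return An object of class `layer_stack`: list with `layers`,
#'   `entropies`, `weights` and `aggregated`.
#' @export
ie_encode <- function(tokens, params, config) {
  enc <- encode_layers(tokens, params, config)
  head <- mlm_head(params)
  H <- vapply(enc$layers, layer_entropy, numeric(1), head = head)
  w <- entropy_weights(H)
  structure(list(layers = enc$layers, entropies = H, weights = w,
                 aggregated = aggregate_layers(enc$layers, w)),
            class = "layer_stack")
}
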