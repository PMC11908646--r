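#' Full model configuration
#'
#' Bundles every tunable of the pipeline: window radius, reading
#' orientation, encoder shape, GRU/attention/CNN/head hyperparameters and
#' the training schedule. Defaults are the desk-scale profile: a 4-layer
#' 64-dimensional encoder feeding three 3-layer 128-unit GRUs, 4 attention
#' heads, a kernel-2 3-layer CNN and a 2-layer sigmoid head with dropout
#' 0.5, under the `RLL` orientation.
#'
#' @param k Window radius (window length `2k + 1`).
#' @param direction 3-letter reading-orientation code; see
#'   [direction_codes()].
#' @param encoder An [encoder_config()].
#' @param gru_hidden,gru_layers GRU width and depth per branch.
#' @param n_heads Attention heads of the classifier's attention block.
#' @param cnn_layers,kernel_size,filters CNN depth, kernel length and
#'   channel count.
#' @param dropout Dropout rate on the head's hidden layer.
#' @param fc_hidden Width of the head's hidden layer.
#' @param standard_gru_gates Use the textbook GRU update-gate convention
#'   instead of the printed one (see [gru_forward()]).
#' @param mlm List of MLM pretraining settings: `epochs`, `batch_size`,
#'   `lr`, `rate`.
#' @param train List of classifier training settings: `epochs`,
#'   `batch_size`, `lr`, `patience`, `val_fraction`.
#' @return Object of class `model_config`.
#' @export
model_config <- function(k = 15L, direction = "RLL",
                         encoder = encoder_config(),
                         gru_hidden = 128L, gru_layers = 3L,
                         n_heads = 4L, cnn_layers = 3L, kernel_size = 2L,
                         filters = 64L, dropout = 0.5, fc_hidden = 64L,
                         standard_gru_gates = FALSE,
                         mlm = list(), train = list()) {
  assert_direction_code(direction)
  stopifnot(dropout >= 0, dropout < 1, kernel_size >= 1L,
            gru_hidden %% n_heads == 0L)
  mlm <- utils::modifyList(
    list(epochs = 2L, batch_size = 16L, lr = 1e-3, rate = 0.15), mlm)
  train <- utils::modifyList(
    list(epochs = 8L, batch_size = 64L, lr = 1e-3, patience = 5L,
         val_fraction = 0.15), train)
  structure(list(k = as.integer(k), direction = direction, encoder = encoder,
                 gru_hidden = as.integer(gru_hidden),
                 gru_layers = as.integer(gru_layers),
                 n_heads = as.integer(n_heads),
                 cnn_layers = as.integer(cnn_layers),
                 kernel_size = as.integer(kernel_size),
                 filters = as.integer(filters), dropout = dropout,
                 fc_hidden = as.integer(fc_hidden),
                 standard_gru_gates = isTRUE(standard_gru_gates),
                 mlm = mlm, train = train),
            class = "model_config")
}

#' Read / write a model configuration as YAML
#'
#' @param path YAML file path.
#' @return [model_config()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  enc <- do.call(encoder_config, y$encoder %||% list())
  y$encoder <- NULL
  do.call(model_config, c(y, list(encoder = enc)))
}

#' @rdname read_model_config
#' @param config A [model_config()].
#' @export
write_model_config <- function(config, path) {
  x <- unclass(config)
  x$encoder <- unclass(x$encoder)
  yaml::write_yaml(x, path)
  invisible(path)
}

# position count after the CNN stack for input length Tn
cnn_out_len <- function(Tn, kernel_size, n_layers) {
  for (l in seq_len(n_layers)) {
    Tn <- Tn - kernel_size + 1L
    if (Tn < 2L) {
      stop("sequence shorter than the CNN receptive field", call. = FALSE)
    }
    Tn <- Tn %/% 2L
  }
  Tn
}

net_init <- function(config, seed = 1L) {
  k <- config$k
  d <- config$encoder$d_model
  h <- config$gru_hidden
  t_total <- 2L * (k + 1L) + (2L * k + 1L)
  fc_in <- cnn_out_len(t_total, config$kernel_size, config$cnn_layers) *
    config$filters
  local_seed(seed)
  list(gru_left = gru_params(d, h, config$gru_layers, seed = sub_seed(seed, 11L)),
       gru_right = gru_params(d, h, config$gru_layers, seed = sub_seed(seed, 12L)),
       gru_full = gru_params(d, h, config$gru_layers, seed = sub_seed(seed, 13L)),
       att = mha_init(h),
       cnn = cnn_params(2L * h, config$filters, config$cnn_layers,
                        config$kernel_size, seed = sub_seed(seed, 14L)),
       fc = fc_params(fc_in, config$fc_hidden, seed = sub_seed(seed, 15L)))
}

#' Run the three directional GRU branches
#'
#' Three independent (unshared-parameter) GRUs process the oriented left,
#' right and full segment embeddings.
#'
#' @param left,right,full Embedded segments: `[time, feature]` matrices or
#'   `[batch, time, feature]` arrays.
#' @param params Network parameters holding `gru_left`, `gru_right`,
#'   `gru_full`.
#' @param standard_gates See [gru_forward()].
#' @return List with per-branch memory matrices/arrays `M_left`,
#'   `M_right`, `M_full`.
#' @export
multi_branch_forward <- function(left, right, full, params,
                                 standard_gates = FALSE) {
  list(M_left = gru_forward(left, params$gru_left, standard_gates),
       M_right = gru_forward(right, params$gru_right, standard_gates),
       M_full = gru_forward(full, params$gru_full, standard_gates))
}

# forward over a batch of embedded segments; feats = list(left, right,
# full) arrays [B, T, d_model]. All per-position matrices live in the
# stacked (B*T) x h layout (time-major blocks of B rows); the three
# branches concatenate along the position axis by row-binding, and
# per-sample views are strided row gathers.
net_fwd <- function(feats, params, config, training = FALSE,
                    keep_cache = FALSE) {
  std <- config$standard_gru_gates
  B <- dim(feats$left)[1]
  tl <- dim(feats$left)[2]; tr <- dim(feats$right)[2]
  tf <- dim(feats$full)[2]
  gl <- gru_forward_stacked(matrix(feats$left, B * tl, dim(feats$left)[3]),
                            B, tl, params$gru_left, std)
  gr <- gru_forward_stacked(matrix(feats$right, B * tr, dim(feats$right)[3]),
                            B, tr, params$gru_right, std)
  gf <- gru_forward_stacked(matrix(feats$full, B * tf, dim(feats$full)[3]),
                            B, tf, params$gru_full, std)
  h <- ncol(gl$M)
  Ttot <- tl + tr + tf
  Mcat <- rbind(gl$M, gr$M, gf$M)
  ab <- att_batch_fwd(Mcat, B, Ttot, params$att, config$n_heads)
  Zs <- cbind(Mcat, ab$O)
  cb <- cnn_batch_fwd(Zs, B, Ttot, params$cnn, config$kernel_size,
                      keep_cache = keep_cache)
  Ymat <- if (keep_cache) cb$Y else cb
  fb <- fc_batch_fwd(Ymat, params$fc, config$dropout, training)
  out <- list(p = fb$p)
  if (keep_cache) {
    out$cache <- list(gl = gl, gr = gr, gf = gf, B = B,
                      t_splits = c(tl, tr, tf), att = ab$cache,
                      cnn = cb, fc = fb)
  }
  out
}

net_bwd <- function(dlogit, cache, params, config) {
  B <- cache$B
  ts <- cache$t_splits
  h <- config$gru_hidden
  fb <- fc_batch_bwd(dlogit, cache$fc, params$fc)
  cb <- cnn_batch_bwd(fb$dY, cache$cnn, B, params$cnn,
                      config$kernel_size)
  dMcat <- cb$dX[, seq_len(h), drop = FALSE]
  ab <- att_batch_bwd(cb$dX[, h + seq_len(h), drop = FALSE], cache$att,
                      params$att)
  dMcat <- dMcat + ab$dM
  rl <- seq_len(B * ts[1])
  rr <- B * ts[1] + seq_len(B * ts[2])
  rf <- B * (ts[1] + ts[2]) + seq_len(B * ts[3])
  bl <- gru_backward(dMcat[rl, , drop = FALSE], cache$gl$caches,
                     params$gru_left)
  br <- gru_backward(dMcat[rr, , drop = FALSE], cache$gr$caches,
                     params$gru_right)
  bf <- gru_backward(dMcat[rf, , drop = FALSE], cache$gf$caches,
                     params$gru_full)
  list(gru_left = bl$grads, gru_right = br$grads, gru_full = bf$grads,
       att = ab$grads, cnn = cb$grads, fc = fb$grads)
}

subset_feats <- function(feats, idx) {
  list(left = feats$left[idx, , , drop = FALSE],
       right = feats$right[idx, , , drop = FALSE],
       full = feats$full[idx, , , drop = FALSE])
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Adam training with early stopping on validation loss
train_net <- function(feats, labels, config, seed = 1L,
                      val_feats = NULL, val_labels = NULL,
                      verbose = FALSE) {
  tr <- config$train
  params <- net_init(config, seed = sub_seed(seed, 21L))
  opt <- adam_init(params, lr = tr$lr)
  n <- length(labels)
  local_seed(sub_seed(seed, 22L))
  has_val <- !is.null(val_feats) && length(val_labels) > 0
  best <- list(loss = Inf, params = params, epoch = 0L)
  patience_left <- tr$patience
  log_rows <- list()
  for (ep in seq_len(tr$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = tr$batch_size)) {
      idx <- ord[start:min(start + tr$batch_size - 1L, n)]
      fb <- subset_feats(feats, idx)
      yb <- labels[idx]
      fwd <- net_fwd(fb, params, config, training = TRUE, keep_cache = TRUE)
      loss <- bce_loss(fwd$p, yb)
      assert_finite(loss, "training loss")
      dlogit <- (fwd$p - yb) / length(yb)
      grads <- net_bwd(dlogit, fwd$cache, params, config)
      upd <- adam_step(params, grads, opt)
      params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    val_loss <- NA_real_
    if (has_val) {
      vp <- predict_net(val_feats, params, config)
      val_loss <- bce_loss(vp, val_labels)
    }
    log_rows[[ep]] <- tibble::tibble(epoch = ep,
                                     train_loss = ep_loss / nb,
                                     val_loss = val_loss)
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %s", ep, ep_loss / nb,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
    }
    if (has_val) {
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = params, epoch = ep)
        patience_left <- tr$patience
      } else {
        patience_left <- patience_left - 1L
        if (patience_left <= 0L) break
      }
    } else {
      best <- list(loss = ep_loss / nb, params = params, epoch = ep)
    }
  }
  list(params = best$params, best_epoch = best$epoch,
       log = dplyr::bind_rows(log_rows))
}

predict_net <- function(feats, params, config, batch_size = 256L) {
  n <- dim(feats$left)[1]
  p <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    p[idx] <- net_fwd(subset_feats(feats, idx), params, config)$p
  }
  p
}
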