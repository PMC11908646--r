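# Batched multi-layer GRU.
#
# Gate equations follow the model description exactly as printed:
#   z_t = sigmoid(W(z) L_t + U(z) M_{t-1})
#   r_t = sigmoid(W(r) L_t + U(r) M_{t-1})
#   Mtil_t = tanh(W(m) L_t + r_t * (U(m) M_{t-1}))
#   M_t = z_t * M_{t-1} + (1 - z_t) * Mtil_t
# Note the update-gate roles: old memory is kept with weight z_t, which is
# the SWAP of the textbook GRU convention. `standard_gates = TRUE` flips
# back to the textbook roles (M_t = (1-z)*M_{t-1} + z*Mtil).
#
# The input-side projections are computed as wide matrix products in R;
# the sequential recurrence runs in compiled code (src/gru_ops.cpp) on
# (B*T) x h stacked matrices, time-major blocks of B rows. A [B, T, d]
# array flattens to exactly that layout, so reshapes are plain copies.

#' Initialize multi-layer GRU parameters
#'
#' @param input_dim Width of the per-position input features.
#' @param hidden_dim Hidden state width (default 128).
#' @param n_layers Number of stacked GRU layers (default 3).
#' @param seed Integer seed.
#' @return List of per-layer parameter lists (`Wz`, `Uz`, `Wr`, `Ur`,
#'   `Wm`, `Um`, biases `bz`, `br`, `bm`), class `gru_params`.
#' @export
gru_params <- function(input_dim, hidden_dim = 128L, n_layers = 3L,
                       seed = 1L) {
  local_seed(seed)
  layers <- lapply(seq_len(n_layers), function(l) {
    din <- if (l == 1L) input_dim else hidden_dim
    list(Wz = glorot(din, hidden_dim), Uz = glorot(hidden_dim, hidden_dim),
         Wr = glorot(din, hidden_dim), Ur = glorot(hidden_dim, hidden_dim),
         Wm = glorot(din, hidden_dim), Um = glorot(hidden_dim, hidden_dim),
         bz = rep(0, hidden_dim), br = rep(0, hidden_dim),
         bm = rep(0, hidden_dim))
  })
  structure(layers, class = "gru_params")
}

as_bT_array <- function(X) {
  if (is.matrix(X)) array(X, dim = c(1L, nrow(X), ncol(X))) else X
}

# forward one layer; Xmat (B*T x din, stacked) -> list(M (B*T x h), cache)
gru_layer_fwd <- function(Xmat, par, B, Tn, standard_gates = FALSE) {
  din <- ncol(Xmat)
  if (nrow(par$Wz) != din) {
    stop("GRU input width ", din, " does not match parameters (",
         nrow(par$Wz), ")", call. = FALSE)
  }
  n <- nrow(Xmat)
  Az <- Xmat %*% par$Wz + rep(par$bz, each = n)
  Ar <- Xmat %*% par$Wr + rep(par$br, each = n)
  Am <- Xmat %*% par$Wm + rep(par$bm, each = n)
  core <- gru_fwd_core(Az, Ar, Am, par$Uz, par$Ur, par$Um, B, Tn,
                       standard_gates)
  list(M = core$M,
       cache = c(core, list(Xmat = Xmat, B = B, Tn = Tn,
                            standard_gates = standard_gates)))
}

# backward one layer; dM (B*T x h) -> list(dX (B*T x din), grads)
gru_layer_bwd <- function(dM, cache, par) {
  B <- cache$B; Tn <- cache$Tn
  h <- ncol(dM)
  core <- gru_bwd_core(dM, cache$M, cache$Z, cache$R, cache$Htil,
                       cache$UmM, par$Uz, par$Ur, par$Um, B, Tn,
                       cache$standard_gates)
  # M_{t-1} stacked in the same (B*T) x h layout (zeros at t = 1)
  Mpmat <- rbind(matrix(0, B, h),
                 cache$M[seq_len(B * (Tn - 1L)), , drop = FALSE])
  grads <- list(
    Wz = crossprod(cache$Xmat, core$dAz), Uz = crossprod(Mpmat, core$dAz),
    Wr = crossprod(cache$Xmat, core$dAr), Ur = crossprod(Mpmat, core$dAr),
    Wm = crossprod(cache$Xmat, core$dAm), Um = crossprod(Mpmat, core$dAmr),
    bz = colSums(core$dAz), br = colSums(core$dAr), bm = colSums(core$dAm))
  dXmat <- cbind(core$dAz, core$dAr, core$dAm) %*%
    rbind(t(par$Wz), t(par$Wr), t(par$Wm))
  list(dX = dXmat, grads = grads)
}

#' Run a multi-layer GRU over per-position features
#'
#' Processes the sequence left-to-right from a zero initial memory; any
#' reading-direction handling happens upstream via [apply_direction()],
#' so a branch fed a reversed segment reads it right-to-left.
#'
#' @param X Input features: a `[time, feature]` matrix (one sample) or a
#'   `[batch, time, feature]` array.
#' @param params A [gru_params()] object.
#' @param standard_gates Use the textbook update-gate convention instead
#'   of the printed one (see source); default `FALSE`.
#' @param keep_cache Keep intermediates for the backward pass.
#' @return Per-position memory of the last layer, shaped like the input
#'   (matrix in, matrix out); with `keep_cache`, a list with `M` (a
#'   `[batch, time, hidden]` array) and `caches`.
#' @export
gru_forward <- function(X, params, standard_gates = FALSE,
                        keep_cache = FALSE) {
  was_matrix <- is.matrix(X)
  X <- as_bT_array(X)
  B <- dim(X)[1]; Tn <- dim(X)[2]
  st <- gru_forward_stacked(matrix(X, B * Tn, dim(X)[3]), B, Tn, params,
                            standard_gates)
  h <- ncol(st$M)
  M <- array(st$M, c(B, Tn, h))
  if (was_matrix) M <- matrix(M[1, , ], Tn, h)
  if (keep_cache) list(M = M, caches = st$caches) else M
}

# stacked-layout entry point used by the classifier internals
gru_forward_stacked <- function(Xmat, B, Tn, params,
                                standard_gates = FALSE) {
  caches <- vector("list", length(params))
  for (l in seq_along(params)) {
    step <- gru_layer_fwd(Xmat, params[[l]], B, Tn, standard_gates)
    Xmat <- step$M
    caches[[l]] <- step$cache
  }
  list(M = Xmat, caches = caches)
}

# full-stack backward w.r.t. the last layer's output; dM may be a
# [B,T,h] array or a stacked (B*T) x h matrix. dX is returned stacked.
gru_backward <- function(dM, caches, params) {
  B <- caches[[1]]$B; Tn <- caches[[1]]$Tn
  if (!is.matrix(dM)) dM <- matrix(dM, B * Tn, dim(dM)[3])
  grads <- vector("list", length(params))
  for (l in rev(seq_along(params))) {
    step <- gru_layer_bwd(dM, caches[[l]], params[[l]])
    grads[[l]] <- step$grads
    dM <- step$dX
  }
  list(dX = dM, grads = grads)
}
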