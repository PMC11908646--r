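# Low-level numeric helpers shared by the encoder and classifier.
# All parameter collections are nested named lists of numeric matrices /
# vectors; the Adam optimizer walks those trees generically.

sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise softmax, numerically stabilized (max.col is C-level)
softmax_rows <- function(x) {
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - mx)
  e / rowSums(e)
}

relu <- function(x) pmax(x, 0)

# Run code under a temporary RNG state; restores the caller's stream.
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  do.call(on.exit, list(bquote((.(restore))()), add = TRUE), envir = env)
  invisible(seed)
}

# derive a distinct 32-bit sub-seed from a base seed and a stream tag
# (double arithmetic: exact below 2^53, result fits in an R integer)
sub_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(tag) * 104729) %%
               2147483647)
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# LayerNorm over the feature axis (rows = positions). Returns the output
# plus the cache needed for the backward pass.
layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2L, g, `*`)
  y <- sweep(y, 2L, b, `+`)
  list(y = y, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  inv <- cache$inv
  dxhat <- sweep(dy, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# ---- tree helpers and flat-vector Adam ----------------------------------

tree_add <- function(a, b) {
  if (is.list(a)) return(mapply(tree_add, a, b, SIMPLIFY = FALSE))
  a + b
}

tree_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, tree_scale, s = s))
  a * s
}

# flatten a parameter tree to one numeric vector (leaf order = unlist's)
flatten_tree <- function(tree) unlist(tree, use.names = FALSE)

# rebuild a tree of the template's shapes from a flat vector
unflatten_tree <- function(vec, template) {
  offset <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- vec[(offset + 1L):(offset + n)]
    offset <<- offset + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  out <- walk(template)
  stopifnot(offset == length(vec))
  out
}

# Adam on the flattened parameter vector; the tree structure is only
# materialized for the forward/backward passes.
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  n <- length(flatten_tree(params))
  list(m = numeric(n), v = numeric(n), t = 0L, lr = lr,
       beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(params, grads, state) {
  p <- flatten_tree(params)
  g <- flatten_tree(grads)
  stopifnot(length(p) == length(g), length(p) == length(state$m))
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * g
  state$v <- state$beta2 * state$v + (1 - state$beta2) * g * g
  c1 <- 1 - state$beta1^state$t
  c2 <- 1 - state$beta2^state$t
  p <- p - state$lr * (state$m / c1) / (sqrt(state$v / c2) + state$eps)
  list(params = unflatten_tree(p, params), state = state)
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop("non-finite values in ", what, "; training diverged", call. = FALSE)
  }
  invisible(x)
}
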