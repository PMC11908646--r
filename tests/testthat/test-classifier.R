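test_that("zero head weights output probability one half, bias shifts it", {
  params <- list(W1 = matrix(0, 6, 4), b1 = rep(0, 4),
                 W2 = matrix(0, 4, 1), b2 = 0)
  y <- rnorm(6)
  expect_equal(classify(y, params), 0.5)
  up <- params; up$b2 <- 1
  dn <- params; dn$b2 <- -1
  expect_gt(classify(y, up), 0.5)
  expect_lt(classify(y, dn), 0.5)
  # monotone in the final bias
  probs <- vapply(seq(-2, 2, by = 0.5), function(b) {
    p <- params; p$b2 <- b; classify(y, p)
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("evaluation mode is deterministic, training dropout is not", {
  set.seed(51)
  params <- sulfsite:::fc_params(10, hidden = 8, seed = 3)
  y <- rnorm(10)
  p1 <- classify(y, params, dropout = 0.5, training = FALSE)
  p2 <- classify(y, params, dropout = 0.5, training = FALSE)
  expect_identical(p1, p2)
  ps <- replicate(20, classify(y, params, dropout = 0.5, training = TRUE))
  expect_gt(stats::sd(ps), 0)
})

test_that("identical branch inputs and parameters give identical outputs", {
  set.seed(52)
  params <- list(gru_left = gru_params(6, 8, 2, seed = 9),
                 gru_right = gru_params(6, 8, 2, seed = 9),
                 gru_full = gru_params(6, 8, 2, seed = 9))
  X <- matrix(rnorm(5 * 6), 5, 6)
  out <- multi_branch_forward(X, X, X, params)
  expect_equal(out$M_left, out$M_right)
  expect_equal(out$M_left, out$M_full)
})

test_that("reversal equivariance: R on s equals L on reverse(s)", {
  set.seed(53)
  par <- list(gru_left = gru_params(4, 6, 1, seed = 1),
              gru_right = gru_params(4, 6, 1, seed = 2),
              gru_full = gru_params(4, 6, 1, seed = 3))
  X <- matrix(rnorm(6 * 4), 6, 4)
  Xrev <- X[6:1, ]
  a <- multi_branch_forward(Xrev, X, X, par)$M_left
  b <- multi_branch_forward(X[6:1, ], X, X, par)$M_left
  expect_equal(a, b)
  # a palindromic segment is orientation-invariant
  pal <- rbind(X[1:3, ], X[3:1, ])
  expect_equal(multi_branch_forward(pal, X, X, par)$M_left,
               multi_branch_forward(pal[6:1, ], X, X, par)$M_left,
               tolerance = 1e-12)
})

test_that("classifier output is invariant to batch order in eval mode", {
  set.seed(54)
  cfg <- tiny_config()
  params <- sulfsite:::net_init(cfg, seed = 5)
  B <- 7
  d <- cfg$encoder$d_model
  feats <- list(left = array(rnorm(B * 6 * d), c(B, 6, d)),
                right = array(rnorm(B * 6 * d), c(B, 6, d)),
                full = array(rnorm(B * 11 * d), c(B, 11, d)))
  p <- sulfsite:::net_fwd(feats, params, cfg)$p
  perm <- sample(B)
  p_perm <- sulfsite:::net_fwd(sulfsite:::subset_feats(feats, perm),
                               params, cfg)$p
  expect_equal(p_perm, p[perm], tolerance = 1e-12)
})

test_that("training on separable toy features drives loss below chance", {
  set.seed(55)
  cfg <- tiny_config()
  cfg$train$epochs <- 6L
  cfg$train$batch_size <- 16L
  B <- 60
  d <- cfg$encoder$d_model
  y <- rep(c(0, 1), length.out = B)
  shift <- array(rep(y * 2 - 1, 6 * d), c(B, 6, d))
  feats <- list(left = array(rnorm(B * 6 * d), c(B, 6, d)) + shift,
                right = array(rnorm(B * 6 * d), c(B, 6, d)) + shift,
                full = array(rnorm(B * 11 * d), c(B, 11, d)))
  fit <- sulfsite:::train_net(feats, y, cfg, seed = 4)
  final <- utils::tail(fit$log$train_loss, 1)
  expect_lt(final, log(2))
  # reproducibility of the full training log
  fit2 <- sulfsite:::train_net(feats, y, cfg, seed = 4)
  expect_identical(fit$log, fit2$log)
})

test_that("model configurations round-trip through YAML", {
  cfg <- model_config(k = 7, direction = "RRL", gru_hidden = 32,
                      encoder = encoder_config(n_layers = 2, d_model = 32,
                                               n_heads = 4, max_len = 20),
                      mlm = list(epochs = 5), train = list(lr = 5e-4))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(cfg, path)
  back <- read_model_config(path)
  expect_equal(back, cfg)
  expect_error(model_config(direction = "XLL"), "direction code")
  expect_error(model_config(gru_hidden = 10, n_heads = 4))
})
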