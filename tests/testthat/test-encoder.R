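desk16 <- function(layers = 1L) {
  encoder_config(n_layers = layers, d_model = 16, n_heads = 2,
                 ffn_dim = 32, max_len = 12)
}

test_that("encode_layers returns one deterministic output per layer", {
  cfg <- desk16(3)
  par <- encoder_init(cfg, seed = 2)
  toks <- tokenize("ACDCK")
  out <- encode_layers(toks, par, cfg)
  expect_length(out$layers, 3L)
  expect_true(all(vapply(out$layers, function(x) all(dim(x) == c(5, 16)),
                         logical(1))))
  expect_identical(out, encode_layers(toks, par, cfg))
  expect_error(encode_layers(integer(0), par, cfg), "empty")
  expect_error(encode_layers(rep(0L, 13), par, cfg), "max_len")
})

test_that("one encoder layer matches a straight-line transcription", {
  set.seed(41)
  cfg <- desk16(1)
  for (rep in 1:5) {
    par <- encoder_init(cfg, seed = rep)
    toks <- tokenize("KCR")
    got <- encode_layers(toks, par, cfg)$layers[[1]]
    X0 <- par$E[toks + 1L, ] + par$P[1:3, ]
    expect_equal(got, oracle_encoder_layer(X0, par$layers[[1]], cfg$n_heads),
                 tolerance = 1e-5)
  }
})

test_that("layer entropy hits its analytic extremes", {
  V <- vocab_size()
  layer <- matrix(rnorm(4 * 8), 4, 8)
  # zero head -> uniform distribution at every position -> H = log V
  head_unif <- list(W = matrix(0, 8, V), b = rep(0, V))
  expect_equal(layer_entropy(layer, head_unif), log(V), tolerance = 1e-12)
  # a huge bias on one token -> (near) one-hot -> H ~ 0
  b1 <- rep(-1e4, V); b1[3] <- 1e4
  expect_equal(layer_entropy(matrix(0, 4, 8), list(W = matrix(0, 8, V), b = b1)),
               0, tolerance = 1e-8)
  # two equal logits, rest suppressed -> H = log 2, matching direct summation
  b2 <- rep(-1e4, V); b2[c(1, 5)] <- 0
  expect_equal(layer_entropy(matrix(0, 4, 8), list(W = matrix(0, 8, V), b = b2)),
               log(2), tolerance = 1e-8)
  expect_equal(oracle_entropy(c(0.5, 0.5, rep(0, V - 2))), log(2))
})

test_that("entropy weights normalize, fall back, and ignore the log base", {
  expect_equal(entropy_weights(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(entropy_weights(c(log(2), 0)), c(1, 0))
  expect_equal(entropy_weights(c(0, 0)), c(0.5, 0.5))
  h <- c(0.3, 1.2, 0.01, 2)
  expect_equal(entropy_weights(h), entropy_weights(h * log2(exp(1))))
  expect_error(entropy_weights(c(-1, 1)))
})

test_that("aggregate_layers is the elementwise weighted sum", {
  set.seed(42)
  layers <- lapply(1:3, function(i) matrix(rnorm(12), 3, 4))
  expect_equal(aggregate_layers(layers, c(0, 1, 0)), layers[[2]])
  same <- list(layers[[1]], layers[[1]], layers[[1]])
  expect_equal(aggregate_layers(same, rep(1 / 3, 3)), layers[[1]])
  w <- c(0.2, 0.5, 0.3)
  manual <- matrix(0, 3, 4)
  for (i in 1:3) for (r in 1:3) for (c in 1:4) {
    manual[r, c] <- manual[r, c] + w[i] * layers[[i]][r, c]
  }
  expect_equal(aggregate_layers(layers, w), manual, tolerance = 1e-9)
  expect_error(aggregate_layers(list(matrix(0, 2, 2), matrix(0, 3, 2)),
                                c(0.5, 0.5)), "shape")
})

test_that("entropy weights are a simplex for random inputs", {
  cfg <- desk16(4)
  par <- encoder_init(cfg, seed = 3)
  set.seed(43)
  for (i in 1:100) {
    toks <- sample(0:21, sample(3:11, 1), replace = TRUE)
    st <- ie_encode(toks, par, cfg)
    expect_true(all(st$weights >= 0))
    expect_equal(sum(st$weights), 1, tolerance = 1e-9)
    expect_true(all(st$entropies >= 0))
    expect_true(all(st$entropies <= log(vocab_size()) + 1e-9))
    expect_equal(st$aggregated,
                 aggregate_layers(st$layers, st$weights), tolerance = 1e-12)
  }
})

test_that("the batched encoder agrees with the per-sequence path", {
  cfg <- desk16(3)
  par <- encoder_init(cfg, seed = 6)
  set.seed(45)
  tok_mat <- matrix(sample(0:21, 8 * 7, replace = TRUE), 8, 7)
  batch <- sulfsite:::ie_encode_batch(tok_mat, par, cfg, chunk = 3L)
  for (i in 1:8) {
    single <- ie_encode(tok_mat[i, ], par, cfg)
    expect_equal(matrix(batch[i, , ], 7, 16), single$aggregated,
                 tolerance = 1e-10)
  }
})

test_that("masking selects the right count, split and never pads", {
  toks <- tokenize(strrep("ACDK", 25))  # 100 non-pad tokens
  mb <- mask_for_mlm(toks, rate = 0.15, seed = 7)
  expect_length(mb$mask_positions, 15L)
  expect_identical(mask_for_mlm(toks, rate = 0.15, seed = 7), mb)
  # deterministic 80/10/10 split within the selection
  n_masktok <- sum(mb$input_ids[mb$mask_positions] == aa_vocab()[["[MASK]"]])
  n_keep <- sum(mb$input_ids[mb$mask_positions] ==
                  toks[mb$mask_positions])
  expect_equal(n_masktok, 12L)
  expect_equal(n_keep + (15L - n_masktok - n_keep), 3L)
  # unmasked positions are untouched
  expect_equal(mb$input_ids[-mb$mask_positions], toks[-mb$mask_positions])
  expect_equal(mb$target_ids, toks[mb$mask_positions])

  all_pad <- tokenize("----")
  expect_length(mask_for_mlm(all_pad, 0.15, seed = 1)$mask_positions, 0L)
  part_pad <- tokenize("--ACDK--")
  for (s in 1:20) {
    sel <- mask_for_mlm(part_pad, 0.5, seed = s)$mask_positions
    expect_true(all(part_pad[sel] != aa_vocab()[["-"]]))
  }
})

test_that("MLM pretraining beats the uniform baseline on a repetitive corpus", {
  cfg <- desk16(2)
  # near-uniform loss from small random initialization
  par0 <- encoder_init(cfg, seed = 1)
  set.seed(44)
  rand_corpus <- lapply(1:30, function(i) sample(0:19, 10, replace = TRUE))
  expect_equal(mlm_eval_loss(rand_corpus, par0, cfg), log(vocab_size()),
               tolerance = 0.05)
  # a highly repetitive corpus is learnable within a couple of epochs
  corpus <- lapply(1:60, function(i) tokenize("ACACACACKR"))
  fit <- pretrain_mlm(corpus, cfg, epochs = 3, batch_size = 16, seed = 2)
  held <- lapply(1:20, function(i) tokenize("ACACACACKR"))
  expect_lt(mlm_eval_loss(held, fit$params, cfg, seed = 5),
            log(vocab_size()))
  expect_true(all(diff(fit$log$loss) < 0))
  # seed reproducibility of the whole training run
  fit2 <- pretrain_mlm(corpus, cfg, epochs = 3, batch_size = 16, seed = 2)
  expect_identical(fit$log, fit2$log)
})
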