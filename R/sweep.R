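#' Direction-code ablation sweep
#'
#' Trains and evaluates the classifier under each reading-orientation
#' code on a shared protein-grouped train/test split, reusing one
#' MLM-pretrained encoder (orientation only affects the classifier's
#' inputs, not the unsupervised pretraining). Produces one metric row per
#' code, mirroring the usual orientation-comparison table layout.
#'
#' @param windows Labeled window tibble.
#' @param config A [model_config()]; its `direction` field is overridden
#'   per code.
#' @param codes Direction codes to sweep (default all 8).
#' @param test_fraction Held-out protein fraction for evaluation.
#' @param seed Integer seed shared across codes, so rows differ only by
#'   orientation.
#' @return Tibble with columns `code`, `Sn`, `Sp`, `Pre`, `Acc`, `MCC`,
#'   `AUC`, class `direction_sweep`.
#' @export
direction_sweep <- function(windows, config = model_config(),
                            codes = direction_codes(),
                            test_fraction = 0.2, seed = 1L) {
  for (code in codes) assert_direction_code(code)
  corpus <- lapply(windows$window, tokenize)
  mlm <- pretrain_mlm(corpus, config$encoder, epochs = config$mlm$epochs,
                      batch_size = config$mlm$batch_size,
                      lr = config$mlm$lr, rate = config$mlm$rate,
                      seed = sub_seed(seed, 51L))
  encoder <- list(params = mlm$params, config = config$encoder)
  split <- split_by_protein(windows, test_fraction,
                            seed = sub_seed(seed, 52L))
  rows <- lapply(codes, function(code) {
    cfg <- config
    cfg$direction <- code
    fit <- sulf_fit(split$train, cfg, seed = sub_seed(seed, 53L),
                    encoder = encoder)
    pred <- stats::predict(fit, split$test)
    dplyr::mutate(evaluate_predictions(pred$probability, split$test$label),
                  code = code, .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("direction_sweep", class(out))
  out
}
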