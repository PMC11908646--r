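# Confident-learning (C_confusion) removal of probable mislabeled
# negatives. Out-of-fold class probabilities are compared against
# per-class mean self-confidence thresholds
#   t_j = mean over samples labeled j of P[i][j];
# a sample labeled j with P[i][j] strictly below t_j is flagged as a
# probable label error. The pipeline applies this to the negative class
# only: experiments can verify S-sulfhydration but never its absence, so
# label noise lives in the negative pool.

#' Out-of-fold class probabilities for confident learning
#'
#' Pretrains the encoder once on all window sequences (unsupervised; no
#' label enters), then refits the classifier `n_folds` times on
#' stratified protein-grouped folds so that every sample's probabilities
#' come from a model that never saw its label.
#'
#' @param windows Labeled window tibble.
#' @param config A [model_config()]; fold models use its training
#'   schedule without early stopping.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @param encoder Optional pre-trained encoder to reuse.
#' @return Object of class `prediction_matrix`: list with `probs`
#'   (n x 2 matrix, columns = classes 0 and 1, rows sum to 1),
#'   `given_labels`, and the `windows` the rows refer to.
#' @export
out_of_fold_probs <- function(windows, config = model_config(),
                              n_folds = 5L, seed = 1L, encoder = NULL) {
  stopifnot(n_folds >= 2L)
  if (length(unique(windows$label)) < 2L) {
    stop("both classes must be present for out-of-fold estimation",
         call. = FALSE)
  }
  if (is.null(encoder)) {
    corpus <- lapply(windows$window, tokenize)
    mlm <- pretrain_mlm(corpus, config$encoder, epochs = config$mlm$epochs,
                        batch_size = config$mlm$batch_size,
                        lr = config$mlm$lr, rate = config$mlm$rate,
                        seed = sub_seed(seed, 41L))
    encoder <- list(params = mlm$params, config = config$encoder)
  }
  feats <- window_features(windows, encoder, config$direction)
  fold <- grouped_folds(windows$protein_id, windows$label, n_folds,
                        seed = sub_seed(seed, 42L))
  p1 <- rep(NA_real_, nrow(windows))
  for (f in seq_len(n_folds)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    fit <- train_net(subset_feats(feats, tr_idx), windows$label[tr_idx],
                     config, seed = sub_seed(seed, 43L + f))
    p1[te_idx] <- predict_net(subset_feats(feats, te_idx), fit$params,
                              config)
  }
  structure(list(probs = cbind(`0` = 1 - p1, `1` = p1),
                 given_labels = windows$label,
                 windows = windows),
            class = "prediction_matrix")
}

#' Per-class self-confidence thresholds
#'
#' For every class `j` with at least one labeled sample, the threshold is
#' the mean predicted probability of class `j` over the samples whose
#' given (possibly noisy) label is `j`.
#'
#' @param pm A `prediction_matrix` (see [out_of_fold_probs()]), or any
#'   list with `probs` (n x 2, columns named `"0"`, `"1"`) and
#'   `given_labels`.
#' @return Named numeric vector of thresholds (`NA` for a class with no
#'   labeled samples).
#' @export
class_thresholds <- function(pm) {
  probs <- pm$probs
  labels <- pm$given_labels
  stopifnot(ncol(probs) == 2L, nrow(probs) == length(labels))
  if (max(abs(rowSums(probs) - 1)) > 1e-6) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  vapply(c(0L, 1L), function(j) {
    in_j <- labels == j
    if (!any(in_j)) return(NA_real_)
    mean(probs[in_j, as.character(j)])
  }, numeric(1)) |> stats::setNames(c("0", "1"))
}

#' Flag probable mislabeled samples of one class
#'
#' Among samples whose given label equals `target_class`, removes those
#' whose out-of-fold probability for that class falls strictly below the
#' class threshold; a probability equal to the threshold is kept. Kept
#' and removed indices partition the labeled set.
#'
#' @param pm A `prediction_matrix`.
#' @param target_class Class whose labels are audited (default 0, the
#'   negative pool).
#' @param thresholds Optional precomputed [class_thresholds()].
#' @return List with integer index vectors `kept` and `removed` (row
#'   indices into `pm$probs`), and the `threshold` used.
#' @export
filter_mislabeled <- function(pm, target_class = 0L, thresholds = NULL) {
  stopifnot(target_class %in% c(0L, 1L))
  in_class <- which(pm$given_labels == target_class)
  if (length(in_class) == 0L) {
    return(list(kept = integer(0), removed = integer(0),
                threshold = NA_real_))
  }
  if (is.null(thresholds)) thresholds <- class_thresholds(pm)
  t_j <- thresholds[[as.character(target_class)]]
  if (is.na(t_j)) stop("threshold undefined for class ", target_class,
                       call. = FALSE)
  p_self <- pm$probs[in_class, as.character(target_class)]
  removed <- in_class[p_self < t_j]
  list(kept = setdiff(in_class, removed), removed = removed,
       threshold = t_j)
}

#' Confident-learning cleanup of the negative class
#'
#' Convenience wrapper: estimates out-of-fold probabilities, computes the
#' class thresholds, and drops negatives flagged as probable label
#' errors.
#'
#' @inheritParams out_of_fold_probs
#' @return List with `windows` (the retained rows), `removed` (report
#'   tibble: `protein_id`, `position`, `p_class0`, `threshold`), and the
#'   `prediction_matrix`.
#' @export
confident_filter <- function(windows, config = model_config(),
                             n_folds = 5L, seed = 1L, encoder = NULL) {
  pm <- out_of_fold_probs(windows, config, n_folds, seed, encoder)
  fl <- filter_mislabeled(pm, target_class = 0L)
  removed <- tibble::tibble(
    protein_id = windows$protein_id[fl$removed],
    position = windows$position[fl$removed],
    p_class0 = pm$probs[fl$removed, "0"],
    threshold = fl$threshold)
  list(windows = windows[setdiff(seq_len(nrow(windows)), fl$removed), ,
                         drop = FALSE],
       removed = removed, prediction_matrix = pm)
}

#' Write the removed-sample report as TSV
#'
#' @param removed Report tibble from [confident_filter()].
#' @param path Output path.
#' @export
write_removed_report <- function(removed, path) {
  utils::write.table(removed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
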