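# High-level fit / predict pipeline tying the modules together.

# Tokenize the oriented (left, right, full) parts of every window.
# Returns list of three integer-id matrices (rows = samples).
tokenize_segments <- function(windows, direction) {
  seg <- apply_direction(segment_window(windows), direction)
  list(left = t(vapply(seg$left, tokenize, integer(nchar(seg$left[1])))),
       right = t(vapply(seg$right, tokenize, integer(nchar(seg$right[1])))),
       full = t(vapply(seg$full, tokenize, integer(nchar(seg$full[1])))))
}

#' Entropy-aggregated embeddings for a window set
#'
#' Segments each window, applies the reading orientation, and encodes
#' every part with the entropy-weighted encoder (the batched equivalent
#' of [ie_encode()]).
#'
#' @param windows Window tibble.
#' @param encoder List with `params` and `config` (a trained encoder,
#'   e.g. from [pretrain_mlm()]).
#' @param direction Reading-orientation code.
#' @return List of three `[n, time, d_model]` arrays (`left`, `right`,
#'   `full`).
#' @export
window_features <- function(windows, encoder, direction = "RLL") {
  toks <- tokenize_segments(windows, direction)
  lapply(toks, ie_encode_batch, params = encoder$params,
         config = encoder$config)
}

#' Fit the S-sulfhydration site classifier
#'
#' Runs the full pipeline on a labeled window set: (1) masked-LM
#' pretraining of the transformer encoder on the window sequences
#' themselves; (2) optional confident-learning removal of probable
#' mislabeled negatives; (3) entropy-aggregated embedding of the oriented
#' left/right/full segments with the frozen encoder; (4) training of the
#' three-branch GRU + attention + CNN + sigmoid head on binary
#' cross-entropy with Adam and early stopping on a protein-grouped
#' validation split.
#'
#' @param windows Window tibble with `protein_id`, `position`, `window`,
#'   `label` (from [extract_windows()] or [generate_synth()]).
#' @param config A [model_config()].
#' @param seed Integer seed; the whole fit is reproducible.
#' @param filter_negatives Apply the confident-learning filter to the
#'   negative class before training (see [confident_filter()]).
#' @param encoder Optional pre-trained encoder (list with `params`,
#'   `config`) to reuse; when `NULL` one is pretrained here.
#' @param cl_folds Cross-validation folds for the confident-learning
#'   probability estimates.
#' @param validate Hold out a protein-grouped validation split for early
#'   stopping (the default). With `FALSE`, the classifier trains on all
#'   windows for the configured number of epochs — lower variance when
#'   the schedule is already known to be adequate.
#' @param verbose Print per-epoch progress.
#' @return Object of class `sulf_model`.
#' @export
sulf_fit <- function(windows, config = model_config(), seed = 1L,
                     filter_negatives = FALSE, encoder = NULL,
                     cl_folds = 5L, validate = TRUE, verbose = FALSE) {
  stopifnot(all(c("protein_id", "window", "label") %in% names(windows)))
  if (is.null(encoder)) {
    corpus <- lapply(windows$window, tokenize)
    mlm <- pretrain_mlm(corpus, config$encoder,
                        epochs = config$mlm$epochs,
                        batch_size = config$mlm$batch_size,
                        lr = config$mlm$lr, rate = config$mlm$rate,
                        seed = sub_seed(seed, 31L))
    encoder <- list(params = mlm$params, config = config$encoder,
                    log = mlm$log)
  }
  removed <- NULL
  if (filter_negatives) {
    cl <- confident_filter(windows, config, n_folds = cl_folds,
                           seed = sub_seed(seed, 32L), encoder = encoder)
    removed <- cl$removed
    windows <- cl$windows
  }
  if (validate) {
    split <- split_by_protein(windows, config$train$val_fraction,
                              seed = sub_seed(seed, 33L))
    tr_feats <- window_features(split$train, encoder, config$direction)
    va_feats <- window_features(split$test, encoder, config$direction)
    fit <- train_net(tr_feats, split$train$label, config,
                     seed = sub_seed(seed, 34L),
                     val_feats = va_feats, val_labels = split$test$label,
                     verbose = verbose)
    val_p <- predict_net(va_feats, fit$params, config)
    val_metrics <- evaluate_predictions(val_p, split$test$label)
    n_train <- nrow(split$train)
    n_val <- nrow(split$test)
  } else {
    tr_feats <- window_features(windows, encoder, config$direction)
    fit <- train_net(tr_feats, windows$label, config,
                     seed = sub_seed(seed, 34L), verbose = verbose)
    val_metrics <- tibble::tibble(Sn = NA_real_, Sp = NA_real_,
                                  Pre = NA_real_, Acc = NA_real_,
                                  MCC = NA_real_, AUC = NA_real_)
    n_train <- nrow(windows)
    n_val <- 0L
  }
  structure(list(encoder = encoder[c("params", "config")],
                 net = fit$params, config = config,
                 log = fit$log, best_epoch = fit$best_epoch,
                 mlm_log = encoder$log, removed = removed,
                 n_train = n_train, n_val = n_val,
                 val_metrics = val_metrics),
            class = "sulf_model")
}

#' Predict site probabilities for new windows
#'
#' @param object A fitted [sulf_fit()] model.
#' @param newdata Window tibble with `protein_id`, `position`, `window`.
#' @param threshold Decision threshold for the `predicted` column.
#' @param ... Unused.
#' @return Tibble `protein_id`, `position`, `probability`, `predicted`.
#' @export
predict.sulf_model <- function(object, newdata, threshold = 0.5, ...) {
  feats <- window_features(newdata, object$encoder, object$config$direction)
  p <- predict_net(feats, object$net, object$config)
  tibble::tibble(protein_id = newdata$protein_id,
                 position = newdata$position,
                 probability = p,
                 predicted = as.integer(p >= threshold))
}

#' @export
print.sulf_model <- function(x, ...) {
  cat("S-sulfhydration site classifier\n")
  cat(sprintf("  direction %s | window 2*%d+1 | encoder %d x %d | GRU %d x %d\n",
              x$config$direction, x$config$k, x$encoder$config$n_layers,
              x$encoder$config$d_model, x$config$gru_layers,
              x$config$gru_hidden))
  cat(sprintf("  trained on %d windows (%d validation), best epoch %d\n",
              x$n_train, x$n_val, x$best_epoch))
  if (!is.null(x$removed)) {
    cat(sprintf("  confident learning removed %d negatives\n",
                nrow(x$removed)))
  }
  vm <- x$val_metrics
  cat(sprintf("  validation: Acc %.3f | MCC %s | AUC %.3f\n",
              vm$Acc, ifelse(is.na(vm$MCC), "NA", sprintf("%.3f", vm$MCC)),
              vm$AUC))
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' A checkpoint holds the encoder (with its vocabulary implicitly fixed
#' by the package), the classifier parameters and the full configuration
#' in one file.
#'
#' @param model A `sulf_model`.
#' @param path Checkpoint file path.
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sulf_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "sulf_model"))
  model
}
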