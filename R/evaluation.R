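#' Confusion counts at a probability threshold
#'
#' A probability greater than or equal to the threshold is called
#' positive.
#'
#' @param probabilities Numeric vector of predicted site probabilities.
#' @param labels Binary vector of true labels (same length).
#' @param threshold Decision threshold in (0, 1).
#' @return Object of class `confusion_counts`: list with `TP`, `FP`,
#'   `TN`, `FN`.
#' @examples
#' confusion(c(0.9, 0.1), c(1, 0))
#' @export
confusion <- function(probabilities, labels, threshold = 0.5) {
  if (length(probabilities) == 0L) {
    stop("cannot build a confusion table from empty input", call. = FALSE)
  }
  stopifnot(length(probabilities) == length(labels),
            threshold > 0, threshold < 1, all(labels %in% c(0, 1)))
  pred <- as.integer(probabilities >= threshold)
  structure(list(TP = sum(pred == 1L & labels == 1),
                 FP = sum(pred == 1L & labels == 0),
                 TN = sum(pred == 0L & labels == 0),
                 FN = sum(pred == 0L & labels == 1)),
            class = "confusion_counts")
}

#' Threshold classification metrics
#'
#' Computes sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`,
#' precision `Pre = TP/(TP+FP)`, accuracy `Acc = (TP+TN)/n` and the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric with a zero denominator is reported as `NA`, never silently
#' zeroed.
#'
#' @param counts A [confusion()] object, or a list with `TP`, `FP`, `TN`,
#'   `FN`.
#' @return One-row tibble with columns `Sn`, `Sp`, `Pre`, `Acc`, `MCC`.
#' @examples
#' site_metrics(list(TP = 3, FN = 1, TN = 3, FP = 1))
#' @export
site_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  stopifnot(all(c(TP, FP, TN, FN) >= 0))
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  tibble::tibble(
    Sn = safe_div(TP, TP + FN),
    Sp = safe_div(TN, TN + FP),
    Pre = safe_div(TP, TP + FP),
    Acc = safe_div(TP + TN, TP + FP + TN + FN),
    MCC = if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the probability that a
#' random positive scores above a random negative, counting ties as one
#' half.
#'
#' @param probabilities Numeric score vector.
#' @param labels Binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(probabilities)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metric panel for a prediction set
#'
#' @param probabilities,labels,threshold As in [confusion()].
#' @return One-row tibble `Sn, Sp, Pre, Acc, MCC, AUC`.
#' @export
evaluate_predictions <- function(probabilities, labels, threshold = 0.5) {
  m <- site_metrics(confusion(probabilities, labels, threshold))
  m$AUC <- auc_score(probabilities, labels)
  m
}

# ---- protein-grouped stratified splitting --------------------------------

# Assign each row to one of k folds such that no protein spans folds and
# positive/negative proteins are dealt evenly. A protein counts positive
# if any of its sites is labeled positive.
grouped_folds <- function(protein_ids, labels, k, seed = 1L) {
  stopifnot(k >= 2L)
  local_seed(seed)
  prot_pos <- tapply(labels, protein_ids, function(x) any(x == 1))
  prots <- names(prot_pos)
  fold_of <- stats::setNames(integer(length(prots)), prots)
  dealt <- 0L  # continue dealing across classes so fold sizes stay even
  for (cls in c(TRUE, FALSE)) {
    members <- prots[prot_pos == cls]
    if (length(members) == 0L) next
    members <- sample(members)
    fold_of[members] <- ((seq_along(members) - 1L + dealt) %% k) + 1L
    dealt <- dealt + length(members)
  }
  fold <- unname(fold_of[protein_ids])
  tab <- table(factor(fold, levels = seq_len(k)), factor(labels, levels = c(0, 1)))
  if (any(tab == 0L)) {
    stop("stratified ", k, "-fold split infeasible: a fold lacks one class",
         call. = FALSE)
  }
  fold
}

#' Grouped stratified train/test split of a window set
#'
#' Splits by protein id (no protein appears on both sides), keeping the
#' class balance approximately equal across sides.
#'
#' @param windows Window tibble with `protein_id` and `label`.
#' @param test_fraction Fraction of proteins assigned to the test side.
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles.
#' @export
split_by_protein <- function(windows, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  k <- max(2L, round(1 / test_fraction))
  fold <- grouped_folds(windows$protein_id, windows$label, k, seed)
  list(train = windows[fold != 1L, , drop = FALSE],
       test = windows[fold == 1L, , drop = FALSE])
}

#' Write a metrics table as TSV or JSON
#'
#' @param metrics A metrics tibble (e.g. from [evaluate_predictions()]
#'   or [direction_sweep()]).
#' @param path Output path; the extension picks the format (`.json`
#'   writes JSON, anything else tab-separated text).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a prediction table as TSV
#'
#' @param predictions Tibble from [predict.sulf_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(
    predictions[, c("protein_id", "position", "probability", "predicted")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Protein-grouped stratified k-fold cross-validation
#'
#' Fits the full pipeline on each training split and evaluates on the
#' held-out fold. Folds are stratified by label and grouped by protein id
#' so no protein contributes windows to two folds.
#'
#' @param windows Window tibble (see [extract_windows()] /
#'   [generate_synth()]).
#' @param config A [model_config()].
#' @param k Number of folds.
#' @param seed Integer seed (fold assignment and every fit).
#' @return List with `folds` (tibble, one metric row per fold) and
#'   `summary` (mean of the fold metrics).
#' @export
cross_validate <- function(windows, config = model_config(), k = 10L,
                           seed = 1L) {
  fold <- grouped_folds(windows$protein_id, windows$label, k, seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    train <- windows[fold != f, , drop = FALSE]
    test <- windows[fold == f, , drop = FALSE]
    fit <- sulf_fit(train, config, seed = sub_seed(seed, 100L + f))
    pred <- stats::predict(fit, test)
    rows[[f]] <- dplyr::mutate(
      evaluate_predictions(pred$probability, test$label), fold = f,
      .before = 1L)
  }
  folds <- dplyr::bind_rows(rows)
  list(folds = folds,
       summary = dplyr::summarise(folds, dplyr::across(
         c("Sn", "Sp", "Pre", "Acc", "MCC", "AUC"),
         ~ mean(.x, na.rm = TRUE))))
}
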