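test_that("confusion counts follow the >= decision rule", {
  cc <- confusion(c(0.9, 0.1), c(1, 0))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  low <- confusion(c(0.2, 0.3, 0.1), c(1, 0, 0))
  expect_equal(low$TP + low$FP, 0L)
  tie <- confusion(0.5, 0, threshold = 0.5)
  expect_equal(tie$FP, 1L)  # exactly at threshold counts positive
  expect_error(confusion(numeric(0), numeric(0)), "empty")
})

test_that("the five threshold metrics match their printed formulas", {
  m <- site_metrics(list(TP = 3, FN = 1, TN = 3, FP = 1))
  expect_equal(unlist(m), c(Sn = 0.75, Sp = 0.75, Pre = 0.75, Acc = 0.75,
                            MCC = 0.5))
  perfect <- site_metrics(list(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_equal(unname(unlist(perfect)), rep(1, 5))
  degen <- site_metrics(list(TP = 0, FN = 2, TN = 3, FP = 0))
  expect_true(is.na(degen$Pre))
  expect_true(is.na(degen$MCC))
  expect_equal(degen$Sp, 1)
})

test_that("metrics match direct formula evaluation on random tables", {
  set.seed(61)
  for (i in 1:50) {
    cc <- list(TP = sample(0:20, 1), FP = sample(0:20, 1),
               TN = sample(0:20, 1), FN = sample(0:20, 1))
    if (sum(unlist(cc)) == 0) next
    m <- site_metrics(cc)
    with(cc, {
      if (TP + FN > 0) expect_equal(m$Sn, TP / (TP + FN))
      if (TN + FP > 0) expect_equal(m$Sp, TN / (TN + FP))
      if (TP + FP > 0) expect_equal(m$Pre, TP / (TP + FP))
      expect_equal(m$Acc, (TP + TN) / (TP + FP + TN + FN))
      den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
      if (den > 0) expect_equal(m$MCC, (TP * TN - FP * FN) / den)
    })
  }
})

test_that("AUC equals the pairwise counting oracle, ties counted half", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # one inversion among four samples
  expect_equal(auc_score(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0)),
               oracle_auc(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0)))
  set.seed(62)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2)  # coarse grid so ties occur
    expect_identical(auc_score(scores, labels), oracle_auc(scores, labels))
  }
  expect_error(auc_score(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("grouped stratified folds never split a protein", {
  set.seed(63)
  ids <- rep(sprintf("p%02d", 1:20), each = 3)
  labels <- rep(rep(c(1, 0), 10), each = 3)
  for (k in c(2, 4)) {
    fold <- sulfsite:::grouped_folds(ids, labels, k, seed = k)
    expect_true(all(tapply(fold, ids, function(x) length(unique(x))) == 1))
    expect_true(all(table(fold, labels) > 0))
  }
  fold <- sulfsite:::grouped_folds(ids, labels, 2, seed = 9)
  expect_identical(fold, sulfsite:::grouped_folds(ids, labels, 2, seed = 9))
  # a balanced 10-protein set splits 5/5 by protein
  ids10 <- sprintf("q%d", 1:10)
  lab10 <- rep(c(1, 0), 5)
  f <- sulfsite:::grouped_folds(ids10, lab10, 2, seed = 1)
  expect_equal(sort(as.integer(table(f))), c(5L, 5L))
  # stratification infeasible with a single positive protein and k = 2...
  expect_error(sulfsite:::grouped_folds(c("a", "b"), c(1, 0), 2, seed = 1),
               "infeasible")
})

test_that("split_by_protein respects fraction and grouping", {
  d <- generate_synth(synth_config(n_pos = 30, n_neg = 70, k = 4), seed = 8)
  sp <- split_by_protein(d, 0.2, seed = 2)
  expect_equal(nrow(sp$train) + nrow(sp$test), 100L)
  expect_length(intersect(sp$train$protein_id, sp$test$protein_id), 0L)
  expect_gt(nrow(sp$test), 10L)
  expect_lt(nrow(sp$test), 30L)
  expect_true(all(c(0, 1) %in% sp$test$label))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(64)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- runif(n)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_score(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("metrics and predictions export to TSV and JSON", {
  m <- evaluate_predictions(c(0.9, 0.2, 0.7, 0.4), c(1, 0, 1, 0))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_metrics(m, tsv)
  expect_equal(utils::read.delim(tsv)$AUC, m$AUC)
  js <- withr::local_tempfile(fileext = ".json")
  write_metrics(m, js)
  expect_equal(jsonlite::read_json(js)[[1]]$AUC, m$AUC)

  pred <- tibble::tibble(protein_id = "p1", position = 8L,
                         probability = 0.73, predicted = 1L)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(pred, out)
  expect_equal(utils::read.delim(out)$probability, 0.73)
})

test_that("evaluate_predictions assembles the six-metric panel", {
  probs <- c(0.9, 0.8, 0.3, 0.6, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  m <- evaluate_predictions(probs, labels)
  expect_named(m, c("Sn", "Sp", "Pre", "Acc", "MCC", "AUC"))
  expect_equal(m$Sn, 2 / 3)
  expect_equal(m$Sp, 2 / 3)
  expect_equal(m$AUC, oracle_auc(probs, labels))
})
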