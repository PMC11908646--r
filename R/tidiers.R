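#' Tidy a fitted site classifier
#'
#' Returns the per-epoch training log (binary cross-entropy on the
#' training batches and the protein-grouped validation split).
#'
#' @param x A `sulf_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss`.
#' @method tidy sulf_model
#' @export
tidy.sulf_model <- function(x, ...) {
  x$log
}

#' Glance at a fitted site classifier
#'
#' @param x A `sulf_model`.
#' @param ... Unused.
#' @return One-row tibble summarizing the fit and its validation metrics.
#' @method glance sulf_model
#' @export
glance.sulf_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(direction = x$config$direction, k = x$config$k,
                   n_train = x$n_train, n_val = x$n_val,
                   n_removed = if (is.null(x$removed)) 0L else nrow(x$removed),
                   best_epoch = x$best_epoch),
    x$val_metrics)
}

#' Plot the training curves of a fitted model
#'
#' @param object A `sulf_model`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss by epoch.
#' @method autoplot sulf_model
#' @export
autoplot.sulf_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a direction-sweep metric table
#'
#' @param object A [direction_sweep()] result.
#' @param metric Metric column to display.
#' @param ... Unused.
#' @return A ggplot bar chart, one bar per orientation code.
#' @method autoplot direction_sweep
#' @export
autoplot.direction_sweep <- function(object, metric = "AUC", ...) {
  stopifnot(metric %in% names(object))
  df <- tibble::as_tibble(object)
  df$code <- factor(df$code, levels = df$code)
  ggplot2::ggplot(df, ggplot2::aes(.data$code, .data[[metric]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "direction code", y = metric) +
    ggplot2::theme_minimal()
}

#' ROC curve for a prediction set
#'
#' @param probabilities,labels Scores and binary labels.
#' @return A ggplot of the ROC curve with the AUC in the subtitle.
#' @export
plot_roc <- function(probabilities, labels) {
  ord <- order(probabilities, decreasing = TRUE)
  y <- labels[ord]
  tpr <- c(0, cumsum(y == 1) / sum(y == 1))
  fpr <- c(0, cumsum(y == 0) / sum(y == 0))
  df <- tibble::tibble(fpr = fpr, tpr = tpr)
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f",
                                     auc_score(probabilities, labels))) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
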