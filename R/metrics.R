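#' Predictive performance metrics
#'
#' Accuracy for any number of classes; for binary outcomes additionally
#' precision, recall and F1 with respect to a positive class:
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels (same length; no labels outside the true
#'   label set).
#' @param positive positive class for the binary metrics; default the
#'   second level (lexicographically second label).
#' @return An object of class `prediction_report`: list with `accuracy`,
#'   `n`, and for binary problems `precision`, `recall`, `f1`, `tp`, `fp`,
#'   `fn` and the `positive` class.
#' @examples
#' evaluate(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
#' @export
evaluate <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  y_true <- factor(y_true)
  y_pred <- factor(as.character(y_pred), levels = levels(y_true))
  if (anyNA(y_pred)) stop("predictions contain labels unseen in the truth")
  out <- list(accuracy = mean(y_pred == y_true), n = length(y_true),
              y_true = y_true, y_pred = y_pred)
  if (nlevels(y_true) == 2L) {
    if (is.null(positive)) positive <- levels(y_true)[2L]
    if (!positive %in% levels(y_true)) stop("unknown positive class: ", positive)
    tp <- sum(y_pred == positive & y_true == positive)
    fp <- sum(y_pred == positive & y_true != positive)
    fn <- sum(y_pred != positive & y_true == positive)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    out <- c(out, list(positive = positive, tp = tp, fp = fp, fn = fn,
                       precision = precision, recall = recall, f1 = f1))
  }
  structure(out, class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("prediction report (n = %d)\n", x$n))
  cat(sprintf("  accuracy : %.4f\n", x$accuracy))
  if (!is.null(x$f1)) {
    cat(sprintf("  precision: %.4f  recall: %.4f  F1: %.4f  (positive = %s)\n",
                x$precision, x$recall, x$f1, x$positive))
    cat(sprintf("  TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  }
  invisible(x)
}

#' Write predictions and metrics to disk
#'
#' Predictions as a TSV (sample_id, true, predicted) and metrics as JSON.
#'
#' @param report a `prediction_report`.
#' @param prefix output path prefix; writes `<prefix>_predictions.tsv` and
#'   `<prefix>_metrics.json`.
#' @param sample_ids optional sample ids.
#' @export
write_prediction_report <- function(report, prefix, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- seq_along(report$y_true)
  utils::write.table(
    data.frame(sample_id = sample_ids, true = report$y_true,
               predicted = report$y_pred),
    paste0(prefix, "_predictions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  metrics <- report[intersect(c("accuracy", "precision", "recall", "f1",
                                "tp", "fp", "fn", "n", "positive"),
                              names(report))]
  jsonlite::write_json(metrics, paste0(prefix, "_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
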