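#' Multiclass confusion matrix
#'
#' @param y_true,y_pred integer vectors of 0-based labels.
#' @param n_classes number of classes `C`.
#' @return an integer `C x C` matrix; rows index the true class, columns the
#'   predicted class.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  stopifnot(length(y_true) == length(y_pred), n_classes >= 1L)
  if (any(y_true < 0L | y_true >= n_classes) ||
      any(y_pred < 0L | y_pred >= n_classes)) {
    stop("labels must lie in [0, n_classes)")
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    r <- y_true[i] + 1L
    c <- y_pred[i] + 1L
    cm[r, c] <- cm[r, c] + 1L
  }
  cm
}

#' Overall accuracy from a confusion matrix
#'
#' The fraction of samples on the diagonal, `trace / N`.
#'
#' @param cm confusion matrix (rows = true).
#' @return accuracy in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  n <- sum(cm)
  if (n < 1) stop("confusion matrix is empty")
  sum(diag(cm)) / n
}

#' Per-class precision and recall
#'
#' `P_c = TP_c / (TP_c + FP_c)` and `R_c = TP_c / (TP_c + FN_c)`. A class
#' whose denominator is zero (never predicted, or never present) gets value 0
#' by convention.
#'
#' @param cm confusion matrix (rows = true).
#' @return list with numeric vectors `precision` and `recall`.
#' @export
per_class_precision_recall <- function(cm) {
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  true_tot <- rowSums(cm)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  recall <- ifelse(true_tot > 0, tp / true_tot, 0)
  list(precision = as.numeric(precision), recall = as.numeric(recall))
}

#' Macro-averaged precision, recall and F1
#'
#' Each class contributes equally regardless of its size; F1 is the per-class
#' harmonic mean of precision and recall (0 where both are 0), averaged.
#'
#' @param precision,recall per-class vectors from
#'   [per_class_precision_recall()].
#' @return list with `precision_macro`, `recall_macro`, `f1_macro`.
#' @export
macro_metrics <- function(precision, recall) {
  stopifnot(length(precision) == length(recall), length(precision) >= 1L)
  denom <- precision + recall
  f1 <- ifelse(denom > 0, 2 * precision * recall / denom, 0)
  list(precision_macro = mean(precision), recall_macro = mean(recall),
       f1_macro = mean(f1))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p0 - pe) / (1 - pe)` with observed agreement
#' `p0 = trace / N` and expected agreement
#' `pe = sum_c row_c * col_c / N^2`.
#'
#' @param cm confusion matrix (rows = true).
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm) {
  n <- sum(cm)
  if (n < 1) stop("confusion matrix is empty")
  p0 <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) {
    stop("Cohen's kappa undefined: expected agreement pe = 1 ",
         "(a single class on both axes)")
  }
  (p0 - pe) / (1 - pe)
}

#' Full classification report
#'
#' Computes the confusion matrix and the five evaluation metrics used
#' throughout: overall accuracy, macro precision, macro recall, macro F1 and
#' Cohen's kappa.
#'
#' @param y_true,y_pred integer vectors of 0-based labels.
#' @param n_classes number of classes.
#' @return an object of class `metrics_report`.
#' @export
metrics_report <- function(y_true, y_pred, n_classes) {
  cm <- confusion_matrix(y_true, y_pred, n_classes)
  pr <- per_class_precision_recall(cm)
  mm <- macro_metrics(pr$precision, pr$recall)
  n <- sum(cm)
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  structure(
    list(
      confusion = cm,
      overall_accuracy = overall_accuracy(cm),
      per_class_precision = pr$precision,
      per_class_recall = pr$recall,
      precision_macro = mm$precision_macro,
      recall_macro = mm$recall_macro,
      f1_macro = mm$f1_macro,
      kappa = cohens_kappa(cm),
      observed_agreement = overall_accuracy(cm),
      expected_agreement = pe,
      n_samples = n,
      n_classes = n_classes
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("<metrics_report> ", x$n_samples, " samples, ", x$n_classes,
      " classes\n", sep = "")
  cat(sprintf("  accuracy        %.*f\n", digits, x$overall_accuracy))
  cat(sprintf("  precision macro %.*f\n", digits, x$precision_macro))
  cat(sprintf("  recall macro    %.*f\n", digits, x$recall_macro))
  cat(sprintf("  F1 macro        %.*f\n", digits, x$f1_macro))
  cat(sprintf("  Cohen's kappa   %.*f\n", digits, x$kappa))
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param report a [metrics_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  out <- unclass(report)
  out$confusion <- unname(report$confusion)  # serialized row-major
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
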