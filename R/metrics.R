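#' Multi-class confusion matrix
#'
#' Rows are true classes, columns predicted classes, in `class_names` order.
#'
#' @param y_true,y_pred equal-length label vectors; every label must appear
#'   in `class_names`.
#' @param class_names ordered class names.
#' @return An integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(y_true, y_pred, class_names) {
  if (!length(y_true)) stop("empty label vectors")
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length")
  }
  unknown <- setdiff(unique(c(y_true, y_pred)), class_names)
  if (length(unknown)) {
    stop("label(s) not in class_names: ", paste(unknown, collapse = ", "))
  }
  ft <- factor(y_true, levels = class_names)
  fp <- factor(y_pred, levels = class_names)
  cm <- table(true = ft, predicted = fp)
  cm <- matrix(as.integer(cm), nrow = length(class_names),
               dimnames = list(true = class_names, predicted = class_names))
  class(cm) <- c("confusion_matrix", "matrix")
  cm
}

#' Macro, weighted and per-class classification metrics
#'
#' From an `N x N` confusion matrix with `TP_i = counts[i, i]`,
#' `FP_i = colSums - TP_i`, `FN_i = rowSums - TP_i`:
#' per-class precision `TP_i/(TP_i+FP_i)`, recall `TP_i/(TP_i+FN_i)` and F1
#' (their harmonic mean); macro metrics are unweighted class means; weighted
#' metrics are support-weighted with weights `(TP_i+FN_i)/total`; accuracy is
#' `sum(TP_i)/total`. Any 0/0 term is defined as 0 (with a warning).
#' `precision_weighted` uses true-class support (conventional);
#' `precision_weighted_eq3` additionally reports the predicted-support
#' weighting `(TP_i+FP_i)/total`.
#'
#' @param cm a [confusion_matrix()] (any non-negative square matrix with
#'   dimnames is accepted).
#' @return A list of class `metrics_report`: `per_class` data.frame plus the
#'   scalar fields `precision_macro`, `precision_weighted`,
#'   `precision_weighted_eq3`, `recall_macro`, `recall_weighted`,
#'   `f1_macro`, `f1_weighted`, `accuracy`.
#' @export
compute_metrics <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warning("0/0 encountered; defining the affected metric term as 0")
    }
    out
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  support <- tp + fn
  pred_support <- tp + fp
  report <- list(
    per_class = data.frame(
      class = rownames(cm) %||% paste0("class", seq_along(tp)),
      support = as.integer(support),
      precision = unname(precision),
      recall = unname(recall),
      f1 = unname(f1),
      stringsAsFactors = FALSE
    ),
    precision_macro = mean(precision),
    precision_weighted = sum(support * precision) / total,
    precision_weighted_eq3 = sum(pred_support * precision) / total,
    recall_macro = mean(recall),
    recall_weighted = sum(support * recall) / total,
    f1_macro = mean(f1),
    f1_weighted = sum(support * f1) / total,
    accuracy = sum(tp) / total
  )
  class(report) <- "metrics_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-class metrics:\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf(paste0(
    "precision  macro %.4f | weighted %.4f (eq3 %.4f)\n",
    "recall     macro %.4f | weighted %.4f\n",
    "F1         macro %.4f | weighted %.4f\n",
    "accuracy   %.4f\n"),
    x$precision_macro, x$precision_weighted, x$precision_weighted_eq3,
    x$recall_macro, x$recall_weighted, x$f1_macro, x$f1_weighted,
    x$accuracy))
  invisible(x)
}
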