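# Confusion-matrix construction and one-vs-rest classification metrics:
# precision, recall, specificity, F1 per class, overall accuracy, macro
# averages.

#' Confusion matrix
#'
#' @param y_true,y_pred integer labels in `1..K` (or factors/characters
#'   sharing `levels`).
#' @param K number of classes.
#' @param levels optional class names for dimnames.
#' @return `K x K` integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, K, levels = NULL) {
  if (!is.numeric(y_true)) y_true <- match(as.character(y_true), levels)
  if (!is.numeric(y_pred)) y_pred <- match(as.character(y_pred), levels)
  if (length(y_true) != length(y_pred))
    stop("confusion_matrix: length mismatch")
  if (anyNA(y_true) || anyNA(y_pred) ||
      any(y_true < 1 | y_true > K | y_pred < 1 | y_pred > K))
    stop("confusion_matrix: labels out of range 1..K")
  cm <- matrix(0L, K, K)
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  if (!is.null(levels)) dimnames(cm) <- list(true = levels, pred = levels)
  cm
}

#' One-vs-rest metrics for a single class
#'
#' Reduces the K-class confusion matrix to the four binary cells for class
#' `k` (TP = diagonal entry, FP = rest of the column, FN = rest of the
#' row, TN = remainder) and applies `P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`. Specificity defaults to the standard true-negative
#' rate `TN/(TN+FP)`; `specificity_denominator = "fn"` switches to
#' `TN/(TN+FN)` for literal reproduction of sources that print that
#' variant. Degenerate 0/0 ratios are defined as 0 with a warning.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @param k class index.
#' @param specificity_denominator `"fp"` (standard) or `"fn"`.
#' @return named numeric vector `(P, R, S, F1)`.
#' @export
per_class_metrics <- function(cm, k, specificity_denominator = c("fp", "fn")) {
  sd <- match.arg(specificity_denominator)
  TP <- cm[k, k]
  FP <- sum(cm[, k]) - TP
  FN <- sum(cm[k, ]) - TP
  TN <- sum(cm) - TP - FP - FN
  ratio <- function(num, den, what) {
    if (den == 0) { warning("degenerate ", what, " for class ", k,
                            " (0/0); defined as 0"); 0 } else num / den
  }
  P <- ratio(TP, TP + FP, "precision")
  R <- ratio(TP, TP + FN, "recall")
  S <- if (sd == "fp") ratio(TN, TN + FP, "specificity")
       else ratio(TN, TN + FN, "specificity")
  F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  c(P = P, R = R, S = S, F1 = F1)
}

#' Overall accuracy
#'
#' Trace over total: the fraction of correctly categorized samples (the
#' multi-class form of `(TP+TN)/(TP+FP+TN+FN)`).
#'
#' @param cm confusion matrix.
#' @return accuracy in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  if (sum(cm) == 0) stop("overall_accuracy: empty confusion matrix")
  sum(diag(cm)) / sum(cm)
}

#' Full metrics report
#'
#' Per-class precision / recall / specificity / F1, macro averages, and
#' overall accuracy.
#'
#' @param cm confusion matrix.
#' @param specificity_denominator see [per_class_metrics()].
#' @return a `metrics_report`: list with `per_class` (K x 4 matrix),
#'   `macro` (named means), `accuracy`, and the `confusion` matrix.
#' @export
metrics_report <- function(cm, specificity_denominator = "fp") {
  K <- nrow(cm)
  per <- t(vapply(seq_len(K), function(k)
    per_class_metrics(cm, k, specificity_denominator), numeric(4)))
  rownames(per) <- rownames(cm) %||% paste0("class", seq_len(K))
  structure(list(per_class = per, macro = colMeans(per),
                 accuracy = overall_accuracy(cm), confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-class metrics:\n")
  print(round(x$per_class, 4))
  cat(sprintf("Macro: P=%.4f R=%.4f S=%.4f F1=%.4f\n",
              x$macro["P"], x$macro["R"], x$macro["S"], x$macro["F1"]))
  cat(sprintf("Overall accuracy: %.4f\n", x$accuracy))
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report a [metrics_report()].
#' @param path output file.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(list(per_class = as.data.frame(report$per_class),
                            macro = as.list(report$macro),
                            accuracy = report$accuracy,
                            confusion = report$confusion),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
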