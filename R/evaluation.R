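#' Confusion matrix
#'
#' @param truth vector of true labels.
#' @param predicted vector of predicted labels (same length).
#' @param class_order character vector fixing row/column order.
#' @return A `K x K` integer matrix, rows = true class, columns =
#'   predicted class.
#' @export
confusion_matrix <- function(truth, predicted,
                             class_order = sort(unique(truth))) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  class_order <- as.character(class_order)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  unknown <- setdiff(unique(c(truth, predicted)), class_order)
  unknown <- unknown[!is.na(unknown)]
  if (length(unknown))
    stop("label(s) not in class_order: ", paste(unknown, collapse = ", "))
  K <- length(class_order)
  cm <- matrix(0L, K, K, dimnames = list(true = class_order,
                                         predicted = class_order))
  for (i in seq_along(truth)) {
    if (is.na(predicted[i])) next  # unclassifiable: counted in totals only
    cm[truth[i], predicted[i]] <- cm[truth[i], predicted[i]] + 1L
  }
  cm
}

#' Recognition metrics from a confusion matrix
#'
#' Per class `c` in one-vs-rest terms (TP the diagonal entry, FN the rest
#' of row `c`, FP the rest of column `c`, TN the remainder):
#' recall `TP/(TP+FN)`, specificity `1 - FP/(FP+TN)`.  Overall accuracy is
#' `trace/total`; macro values are unweighted means over classes, with
#' undefined (0/0) classes excluded and flagged.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @return A list of class `eval_report`: `confusion`, `per_class`
#'   (data.frame with recall and specificity), `accuracy`,
#'   `macro_recall`, `macro_specificity`, `undefined` (labels excluded
#'   from macros).
#' @export
eval_metrics <- function(cm) {
  cm <- as.matrix(cm)
  K <- nrow(cm)
  if (K < 2L || K != ncol(cm)) stop("need a square confusion matrix, K >= 2")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  labels <- rownames(cm)
  if (is.null(labels)) labels <- as.character(seq_len(K))
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  specificity <- ifelse(fp + tn > 0, 1 - fp / (fp + tn), NA_real_)
  per_class <- data.frame(label = labels, recall = recall,
                          specificity = specificity,
                          row.names = NULL)
  undefined <- labels[is.na(recall) | is.na(specificity)]
  structure(list(confusion = cm, per_class = per_class,
                 accuracy = sum(tp) / total,
                 macro_recall = mean(recall, na.rm = TRUE),
                 macro_specificity = mean(specificity, na.rm = TRUE),
                 undefined = undefined),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$confusion)
  cat(sprintf("accuracy: %.4f  macro recall: %.4f  macro specificity: %.4f\n",
              x$accuracy, x$macro_recall, x$macro_specificity))
  if (length(x$undefined))
    cat("undefined (excluded from macros):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  obj <- list(confusion = report$confusion,
              labels = report$per_class$label,
              per_class = report$per_class,
              accuracy = report$accuracy,
              macro_recall = report$macro_recall,
              macro_specificity = report$macro_specificity)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
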