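#' Build a confusion matrix from true and predicted class indices
#'
#' @param y_true,y_pred Integer class indices in `[1, n_classes]`, equal
#'   length.
#' @param n_classes Number of classes `m`.
#' @param labels Optional character class labels (length `m`); defaults to
#'   `"class_1" ...`.
#' @return An m x m integer matrix of class `"confusion_matrix"`; rows are
#'   true classes, columns predicted classes.
#' @export
#' @examples
#' confusion(c(1, 1, 2), c(1, 2, 2), n_classes = 2)
confusion <- function(y_true, y_pred, n_classes, labels = NULL) {
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) &&
      (min(y_true, y_pred) < 1L || max(y_true, y_pred) > n_classes))
    stop("class indices must lie in [1, ", n_classes, "]", call. = FALSE)
  if (is.null(labels)) labels <- paste0("class_", seq_len(n_classes))
  if (length(labels) != n_classes)
    stop("`labels` must have length `n_classes`", call. = FALSE)
  cm <- matrix(0L, n_classes, n_classes, dimnames = list(true = labels,
                                                         pred = labels))
  for (k in seq_along(y_true))
    cm[y_true[k], y_pred[k]] <- cm[y_true[k], y_pred[k]] + 1L
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

# One-vs-rest counts per class; TP + FP + FN + TN = total for every class.
ovr_counts <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  data.frame(label = rownames(cm), tp = tp, fp = fp, fn = fn, tn = tn,
             support = rowSums(cm), row.names = NULL)
}

safe_div <- function(num, den, what) {
  out <- ifelse(den > 0, num / den, 0)
  if (any(den == 0))
    warning("zero denominator in ", what, " for class(es) ",
            paste(which(den == 0), collapse = ", "),
            "; reporting 0", call. = FALSE)
  out
}

#' Per-class and averaged classification report
#'
#' Computes overall accuracy (`trace / total`), per-class one-vs-rest
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic mean F1,
#' plus macro (unweighted) and support-weighted averages. Zero-denominator
#' cases report 0 with a warning.
#'
#' @param cm A [confusion()] matrix (or any square count matrix, rows =
#'   true).
#' @return An object of class `"class_report"`: a list with `accuracy`,
#'   `per_class` (data frame with precision/recall/f1/support), `macro_avg`,
#'   `weighted_avg`, and `n` (total samples).
#' @export
#' @examples
#' cm <- matrix(c(9, 2, 1, 8), 2, 2)  # TP=9 FP=1 FN=2 TN=8 for class 1
#' class_report(cm)$accuracy          # 0.85
class_report <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop("`cm` must be a square matrix", call. = FALSE)
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  if (is.null(rownames(cm)))
    dimnames(cm) <- rep(list(paste0("class_", seq_len(nrow(cm)))), 2)
  counts <- ovr_counts(cm)
  precision <- safe_div(counts$tp, counts$tp + counts$fp, "precision")
  recall <- safe_div(counts$tp, counts$tp + counts$fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "f1")
  per_class <- data.frame(label = counts$label, precision = precision,
                          recall = recall, f1 = f1,
                          support = counts$support)
  w <- counts$support / sum(counts$support)
  avg <- function(x, weights = NULL) {
    if (is.null(weights)) mean(x) else sum(x * weights)
  }
  structure(list(
    accuracy = sum(diag(cm)) / sum(cm),
    per_class = per_class,
    macro_avg = list(precision = avg(precision), recall = avg(recall),
                     f1 = avg(f1)),
    weighted_avg = list(precision = avg(precision, w),
                        recall = avg(recall, w), f1 = avg(f1, w)),
    n = sum(cm)
  ), class = "class_report")
}

#' @export
print.class_report <- function(x, digits = 4, ...) {
  cat(sprintf("<class_report> n = %d, accuracy = %.4f\n", x$n, x$accuracy))
  pc <- x$per_class
  pc[c("precision", "recall", "f1")] <-
    lapply(pc[c("precision", "recall", "f1")], round, digits)
  print(pc, row.names = FALSE)
  cat(sprintf("macro avg:    P = %.4f  R = %.4f  F1 = %.4f\n",
              x$macro_avg$precision, x$macro_avg$recall, x$macro_avg$f1))
  cat(sprintf("weighted avg: P = %.4f  R = %.4f  F1 = %.4f\n",
              x$weighted_avg$precision, x$weighted_avg$recall,
              x$weighted_avg$f1))
  invisible(x)
}

#' Serialise a class report to JSON
#'
#' @param report A [class_report()] object.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly if written to `path`.
#' @export
report_to_json <- function(report, path = NULL) {
  per_class <- stats::setNames(
    lapply(seq_len(nrow(report$per_class)), function(i) {
      r <- report$per_class[i, ]
      list(precision = r$precision, recall = r$recall, f1 = r$f1,
           support = r$support)
    }),
    report$per_class$label)
  obj <- list(accuracy = report$accuracy, per_class = per_class,
              macro_avg = report$macro_avg,
              weighted_avg = report$weighted_avg)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
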