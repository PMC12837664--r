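## Confusion-matrix metrics with one-vs-rest macro averaging.

#' Build a 4-class confusion table
#'
#' @param y_true,y_pred equal-length label vectors in 0..3.
#' @param classes class names (rows = truth, columns = prediction).
#' @return object of class `confusion_table` (integer 4 x 4 matrix).
#' @export
confusion_table <- function(y_true, y_pred,
                            classes = c("class0", "class1", "class2", "class3")) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% 0:3) || !all(y_pred %in% 0:3)) stop("labels out of range 0..3")
  counts <- matrix(0L, 4L, 4L, dimnames = list(truth = classes, pred = classes))
  for (i in seq_along(y_true))
    counts[y_true[i] + 1L, y_pred[i] + 1L] <- counts[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  structure(counts, class = c("confusion_table", "matrix"))
}

.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning("undefined ", what, " (zero denominator); reporting 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Macro-averaged one-vs-rest metrics from a confusion table
#'
#' Per class (one vs rest): Acc = (TP+TN)/(TP+TN+FP+FN), Prec = TP/(TP+FP),
#' Sens = TP/(TP+FN), Spec = TN/(TN+FP), NPV = TN/(TN+FN),
#' F1 = 2TP/(2TP+FP+FN); the macro value is the unweighted mean over the
#' four classes. Ratios with zero denominator are reported as 0 with a
#' warning.
#'
#' @param table a [confusion_table()].
#' @return list(macro = named numeric, per_class = data.frame).
#' @export
macro_metrics <- function(table) {
  counts <- unclass(table)
  n <- sum(counts)
  if (n == 0) stop("empty confusion table")
  per <- lapply(seq_len(4L), function(k) {
    tp <- counts[k, k]
    fn <- sum(counts[k, ]) - tp
    fp <- sum(counts[, k]) - tp
    tn <- n - tp - fn - fp
    c(acc  = .safe_ratio(tp + tn, n, "accuracy"),
      prec = .safe_ratio(tp, tp + fp, "precision"),
      sens = .safe_ratio(tp, tp + fn, "sensitivity"),
      spec = .safe_ratio(tn, tn + fp, "specificity"),
      npv  = .safe_ratio(tn, tn + fn, "NPV"),
      f1   = .safe_ratio(2 * tp, 2 * tp + fp + fn, "F1"))
  })
  per_class <- do.call(rbind, per)
  rownames(per_class) <- rownames(counts)
  list(macro = colMeans(per_class),
       per_class = as.data.frame(per_class))
}

#' Write a metric report (CSV) and confusion table (CSV)
#' @param metrics output of [macro_metrics()]; @param table the confusion table;
#' @param dir output directory; @param prefix file-name prefix.
#' @export
write_metric_report <- function(metrics, table, dir, prefix = "metrics") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(metric = names(metrics$macro),
                              value = as.numeric(metrics$macro)),
                   file.path(dir, paste0(prefix, "_macro.csv")), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(table)),
                   file.path(dir, paste0(prefix, "_confusion.csv")))
  invisible(dir)
}
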