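# Confusion-matrix metric suite: precision, recall, F1 and mean IoU over
# pixel label masks. Metrics accumulate one global confusion matrix over a
# split (elementwise sum of per-image matrices), so they are invariant to
# how images are batched. A class absent from both prediction and truth
# (TP = FP = FN = 0) is excluded from the macro averages rather than
# contributing an undefined 0/0 term.

#' Pixel confusion matrix
#'
#' `M[i, j]` counts pixels of true class `i - 1` predicted as class `j - 1`
#' (labels 0..k, 0 = background). Accumulate over a dataset by adding the
#' per-image matrices.
#'
#' @param pred,truth integer label masks of identical shape, values in 0..k.
#' @param k number of instrument classes (labels run 0..k).
#' @return A (k+1) x (k+1) integer matrix with dimnames giving the labels.
#' @examples
#' confusion_matrix(matrix(c(0, 1, 1, 1), 2), matrix(c(0, 0, 1, 1), 2), k = 1)
#' @export
confusion_matrix <- function(pred, truth, k) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) stop("pred and truth shapes differ")
  kk <- as.integer(k) + 1L
  if (any(pred < 0L | pred >= kk) || any(truth < 0L | truth >= kk)) {
    stop("labels must lie in 0..", k)
  }
  m <- matrix(tabulate(pred + truth * kk + 1L, nbins = kk * kk),
              nrow = kk, ncol = kk, byrow = TRUE)
  dimnames(m) <- list(truth = 0:k, pred = 0:k)
  m
}

cm_counts <- function(cm) {
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  list(tp = tp, fn = fn, fp = fp, present = (tp + fn + fp) > 0)
}

#' Precision, recall and F1 from a confusion matrix
#'
#' Per class: precision TP/(TP+FP), recall TP/(TP+FN), F1 the harmonic mean
#' (equivalently 2TP/(2TP+FP+FN)). Macro means average over the classes
#' that occur in prediction or truth.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @return List with `per_class` (data.frame: class, tp, fp, fn, precision,
#'   recall, f1, iou, present) and `macro` (named vector: precision, recall,
#'   f1, miou).
#' @export
precision_recall_f1 <- function(cm) {
  ct <- cm_counts(cm)
  prec <- ct$tp / (ct$tp + ct$fp)
  rec <- ct$tp / (ct$tp + ct$fn)
  f1 <- 2 * ct$tp / (2 * ct$tp + ct$fp + ct$fn)
  iou <- ct$tp / (ct$tp + ct$fn + ct$fp)
  per <- data.frame(class = as.integer(rownames(cm)),
                    tp = as.numeric(ct$tp), fp = as.numeric(ct$fp),
                    fn = as.numeric(ct$fn),
                    precision = prec, recall = rec, f1 = f1, iou = iou,
                    present = ct$present, row.names = NULL)
  pres <- ct$present
  macro <- c(precision = mean(prec[pres]), recall = mean(rec[pres]),
             f1 = mean(f1[pres]), miou = mean(iou[pres]))
  list(per_class = per, macro = macro)
}

#' Mean intersection over union
#'
#' Average over classes of TP/(TP+FN+FP); classes absent from both
#' prediction and truth are excluded from the average.
#'
#' @inheritParams precision_recall_f1
#' @return Scalar in `[0, 1]`.
#' @export
mean_iou <- function(cm) {
  unname(precision_recall_f1(cm)$macro["miou"])
}

#' Full metrics report
#'
#' @inheritParams precision_recall_f1
#' @return An `endoseg_metrics` list: `confusion`, `per_class`, `macro`.
#' @export
metrics_report <- function(cm) {
  pr <- precision_recall_f1(cm)
  structure(list(confusion = cm, per_class = pr$per_class, macro = pr$macro),
            class = "endoseg_metrics")
}

#' @export
print.endoseg_metrics <- function(x, ...) {
  cat("<endoseg_metrics>\n")
  print(round(x$macro, 4))
  invisible(x)
}
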