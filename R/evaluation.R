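# Per-residue evaluation: confusion counts, the CASP-style scalar
# metrics (sensitivity, specificity, FPR, accuracy, balanced accuracy)
# and ROC/AUC by full threshold sweep with trapezoidal integration.
# Evaluation pools residues over all proteins in a test set.

#' Confusion counts from binary calls and truth
#'
#' @param calls Integer/logical vector of predicted labels (1 = MoRF).
#' @param truth Integer/logical vector of true labels, same length and
#'   order (aligned by protein and position).
#'
#' @return An object of class `confusion_counts`: list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_counts <- function(calls, truth) {
  calls <- as.integer(calls)
  truth <- as.integer(truth)
  if (length(calls) != length(truth))
    stop(sprintf("calls (%d) and truth (%d) have different lengths",
                 length(calls), length(truth)))
  if (anyNA(calls) || anyNA(truth)) stop("calls/truth contain NA")
  if (!all(calls %in% 0:1) || !all(truth %in% 0:1))
    stop("calls and truth must be 0/1")
  structure(list(tp = sum(calls == 1L & truth == 1L),
                 tn = sum(calls == 0L & truth == 0L),
                 fp = sum(calls == 1L & truth == 0L),
                 fn = sum(calls == 0L & truth == 1L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Scalar classification metrics
#'
#' Computes sensitivity (TPR), specificity, FPR, plain accuracy and
#' balanced accuracy ACC = (sensitivity + specificity) / 2.  A metric
#' whose denominator is zero is reported as `NA` with a warning rather
#' than forced to 0.
#'
#' @param counts A [confusion_counts()] object.
#' @return List with `sensitivity`, `specificity`, `fpr`, `accuracy`,
#'   `balanced_accuracy`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", what))
      return(NA_real_)
    }
    num / den
  }
  sens <- ratio(counts$tp, counts$tp + counts$fn, "sensitivity")
  spec <- ratio(counts$tn, counts$tn + counts$fp, "specificity")
  list(sensitivity = sens,
       specificity = spec,
       fpr = if (is.na(spec)) NA_real_ else 1 - spec,
       accuracy = ratio(counts$tp + counts$tn,
                        counts$tp + counts$tn + counts$fp + counts$fn,
                        "accuracy"),
       balanced_accuracy = (sens + spec) / 2)
}

#' ROC curve and AUC from real-valued scores
#'
#' Sweeps every distinct score as a threshold (tied scores grouped into
#' one ROC vertex), anchors the curve at (0, 0) and (1, 1), and
#' integrates by the trapezoidal rule — equivalent to the probability
#' that a random positive outscores a random negative, ties counting
#' one half.
#'
#' @param scores Numeric vector, larger = more positive-like.
#' @param truth 0/1 labels, same length; both classes must be present.
#'
#' @return List with `points` (data frame of `fpr`, `tpr`, monotone
#'   non-decreasing, anchored) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth))
    stop("scores and truth have different lengths")
  if (anyNA(scores) || anyNA(truth)) stop("scores/truth contain NA")
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC requires both classes in the truth labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  run_end <- which(c(s[-1] != s[-length(s)], TRUE)) # last index of each tie group
  tpr <- c(0, cumsum(t)[run_end] / n_pos, 1)
  fpr <- c(0, cumsum(1 - t)[run_end] / n_neg, 1)
  pts <- unique(data.frame(fpr = fpr, tpr = tpr))
  rownames(pts) <- NULL
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  list(points = pts, auc = auc)
}

#' Full evaluation report for per-residue predictions
#'
#' Pools predictions over proteins and computes confusion counts, the
#' scalar metrics at the stored calls, and ROC/AUC from the scores.
#'
#' @param predictions Data frame with columns `score` and `call` (as
#'   produced by [predict.morf_model()], possibly row-bound over many
#'   proteins).
#' @param truth 0/1 vector aligned with `predictions` rows.
#'
#' @return An object of class `evaluation_report`: list with `counts`,
#'   `metrics`, `roc` (points data frame) and `auc`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  stopifnot(is.data.frame(predictions),
            all(c("score", "call") %in% names(predictions)))
  counts <- confusion_counts(predictions$call, truth)
  roc <- roc_auc(predictions$score, truth)
  structure(list(counts = counts,
                 metrics = classification_metrics(counts),
                 roc = roc$points,
                 auc = roc$auc),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<evaluation_report> TP=%d TN=%d FP=%d FN=%d | ",
                     "TPR=%.3f FPR=%.3f ACC=%.3f AUC=%.3f\n"),
              x$counts$tp, x$counts$tn, x$counts$fp, x$counts$fn,
              m$sensitivity, m$fpr, m$balanced_accuracy, x$auc))
  invisible(x)
}
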