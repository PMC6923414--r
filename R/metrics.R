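#' Binary confusion counts
#'
#' Tallies TP/FP/TN/FN for one positive class. Counts are stored as doubles so
#' the MCC products cannot overflow for counts up to 1e9.
#'
#' @param truth,estimate Vectors of class labels (coerced to character).
#' @param positive The label treated as positive.
#' @return A `confusion_counts` list with elements `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(c("a", "a", "b"), c("a", "b", "b"), positive = "a")
#' @export
confusion_counts <- function(truth, estimate, positive) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  stopifnot(length(truth) == length(estimate))
  t_pos <- truth == positive
  e_pos <- estimate == positive
  new_confusion_counts(
    tp = sum(t_pos & e_pos), fp = sum(!t_pos & e_pos),
    tn = sum(!t_pos & !e_pos), fn = sum(t_pos & !e_pos)
  )
}

#' @rdname confusion_counts
#' @param tp,fp,tn,fn Nonnegative counts.
#' @export
new_confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || anyNA(counts)) {
    stop("Confusion counts must be nonnegative", call. = FALSE)
  }
  structure(as.list(as.numeric(counts)), names = names(counts),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts: TP =", x$tp, "FP =", x$fp,
      "TN =", x$tn, "FN =", x$fn, "\n")
  invisible(x)
}

#' Classification accuracy
#'
#' `(TP + TN) / (FN + TP + TN + FP)`.
#'
#' @param counts A [confusion_counts()] object.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total < 1) stop("Accuracy undefined on zero examples", call. = FALSE)
  (counts$tp + counts$tn) / total
}

#' Sensitivity (true positive rate)
#'
#' `TP / (FN + TP)`. Errors (rather than returning 0) when there are no
#' positives, so degenerate folds are surfaced, not silently absorbed.
#'
#' @inheritParams accuracy
#' @return TPR in `[0, 1]`.
#' @export
sensitivity <- function(counts) {
  denom <- counts$tp + counts$fn
  if (denom < 1) stop("Sensitivity undefined: no positive examples",
                      call. = FALSE)
  counts$tp / denom
}

#' Specificity (true negative rate)
#'
#' `TN / (TN + FP)`.
#'
#' @inheritParams accuracy
#' @return TNR in `[0, 1]`.
#' @export
specificity <- function(counts) {
  denom <- counts$tn + counts$fp
  if (denom < 1) stop("Specificity undefined: no negative examples",
                      call. = FALSE)
  counts$tn / denom
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the standard
#' convention that a zero denominator factor gives MCC 0 — this keeps model
#' selection well defined on degenerate folds.
#'
#' @inheritParams accuracy
#' @return MCC in `[-1, 1]`.
#' @examples
#' mcc(new_confusion_counts(tp = 6, fp = 2, tn = 3, fn = 1))
#' @export
mcc <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Micro-averaged multiclass MCC
#'
#' One-vs-rest TP/FP/TN/FN are computed for every class from a single
#' prediction run, summed across classes, and the binary MCC formula is
#' applied to the summed counts.
#'
#' @param truth,estimate Label vectors of equal length.
#' @param levels Optional class levels; defaults to the union observed.
#' @return Micro-averaged MCC in `[-1, 1]`.
#' @export
micro_mcc <- function(truth, estimate, levels = NULL) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  stopifnot(length(truth) == length(estimate))
  if (is.null(levels)) levels <- sort(unique(c(truth, estimate)))
  per_class <- purrr::map(levels, function(cl) {
    confusion_counts(truth, estimate, positive = cl)
  })
  summed <- new_confusion_counts(
    tp = sum(purrr::map_dbl(per_class, "tp")),
    fp = sum(purrr::map_dbl(per_class, "fp")),
    tn = sum(purrr::map_dbl(per_class, "tn")),
    fn = sum(purrr::map_dbl(per_class, "fn"))
  )
  mcc(summed)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' outscores a random negative, with ties counted 1/2.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels; `positive` marks the positive class.
#' @param positive Positive label (default `1`). Logical labels use `TRUE`.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' @export
roc_auc <- function(scores, labels, positive = if (is.logical(labels)) TRUE else 1) {
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-row metrics report for a binary prediction run
#'
#' @param truth,estimate Label vectors.
#' @param positive Positive class label.
#' @param scores Optional numeric scores for AUC.
#' @return A one-row tibble with `acc`, `tpr`, `tnr`, `mcc` and (if scores
#'   are given) `auc`.
#' @export
metrics_report <- function(truth, estimate, positive, scores = NULL) {
  counts <- confusion_counts(truth, estimate, positive)
  out <- tibble::tibble(
    acc = accuracy(counts),
    tpr = sensitivity(counts),
    tnr = specificity(counts),
    mcc = mcc(counts)
  )
  if (!is.null(scores)) {
    out$auc <- roc_auc(scores, as.character(truth) == positive, positive = TRUE)
  }
  out
}
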