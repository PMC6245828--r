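#' ROC curve of a continuous tortuosity score against binary labels
#'
#' Builds the ROC curve over all distinct score thresholds (score >= t
#' predicts the positive, symptomatic class; equal scores form a single
#' threshold) plus the two trivial endpoints, and the area under it by the
#' trapezoid rule. With the grouped-ties convention, the trapezoid AUC is
#' exactly the Mann-Whitney pair probability (ties counted one half), so
#' [auc_oracle()] must agree with it to machine precision.
#'
#' @param scores Numeric vector of per-image scores (optionally named by
#'   image id).
#' @param labels Binary labels (0/1 or logical), positive = symptomatic,
#'   aligned with `scores` (or named by image id).
#' @return A `roc_curve`: list with `fpr`, `tpr` (non-decreasing, from
#'   (0,0) to (1,1)), `thresholds` and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  al <- align_scores_labels(scores, labels)
  scores <- al$scores; labels <- al$labels
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    stop_degenerate("reference labels must contain both classes")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nn, numeric(1))
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  if (fpr[length(fpr)] != 1 || tpr[length(tpr)] != 1) {
    fpr <- c(fpr, 1); tpr <- c(tpr, 1)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, thresholds = c(Inf, thr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: %d operating points, AUC = %.4f>\n",
              length(x$fpr), x$auc))
  invisible(x)
}

#' Pairwise-probability AUC oracle
#'
#' The probability that a randomly chosen positive image scores higher than
#' a randomly chosen negative one, ties counted one half — the Mann-Whitney
#' statistic. Serves as an independent check of the trapezoid AUC.
#'
#' @inheritParams roc_curve
#' @return AUC in [0, 1].
#' @export
auc_oracle <- function(scores, labels) {
  al <- align_scores_labels(scores, labels)
  pos <- al$scores[al$labels == 1L]
  neg <- al$scores[al$labels == 0L]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop_degenerate("reference labels must contain both classes")
  }
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

#' Single ROC-space point of a binary (expert) prediction
#'
#' An expert's binary rating admits no threshold sweep, so its performance
#' against the consensus reference is a single point in ROC space.
#'
#' @param pred Binary predictions (0/1), positive = symptomatic.
#' @param ref Binary reference labels, aligned (or both named by image id).
#' @return An `expert_roc_point`: list with `sensitivity`, `specificity`
#'   and the 2x2 counts `tp`, `fp`, `tn`, `fn`.
#' @export
expert_roc_point <- function(pred, ref) {
  al <- align_scores_labels(pred, ref)
  pred <- as.integer(al$scores); ref <- al$labels
  if (!all(pred %in% 0:1)) stop_invalid("predictions must be binary")
  if (sum(ref == 1L) == 0L || sum(ref == 0L) == 0L) {
    stop_degenerate("reference labels must contain both classes")
  }
  tp <- sum(pred == 1L & ref == 1L); fn <- sum(pred == 0L & ref == 1L)
  tn <- sum(pred == 0L & ref == 0L); fp <- sum(pred == 1L & ref == 0L)
  structure(list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "expert_roc_point")
}

align_scores_labels <- function(scores, labels) {
  if (!is.null(names(scores)) && !is.null(names(labels))) {
    if (!setequal(names(scores), names(labels))) {
      missing_in_labels <- setdiff(names(scores), names(labels))
      missing_in_scores <- setdiff(names(labels), names(scores))
      stop_invalid(paste0("score/label image ids do not match; ",
        if (length(missing_in_labels)) paste("missing labels for:",
          paste(missing_in_labels, collapse = ", ")) else "",
        if (length(missing_in_scores)) paste(" missing scores for:",
          paste(missing_in_scores, collapse = ", ")) else ""))
    }
    labels <- labels[names(scores)]
  } else if (length(scores) != length(labels)) {
    stop_invalid("scores and labels must have equal length")
  }
  lab <- as.integer(as.logical(labels) | labels == 1)
  if (any(!is.finite(scores))) stop_invalid("scores must be finite")
  list(scores = as.numeric(scores), labels = lab)
}
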