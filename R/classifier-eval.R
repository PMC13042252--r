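## Classifier evaluation: threshold-conditional confusion matrices and the
## binary sweep-vs-unselected ROC / precision-recall summaries.

#' Confusion matrix at a sweep-probability threshold
#'
#' The assigned class is the posterior argmax, except that examples whose
#' argmax is hard or soft but whose combined sweep probability
#' (p_hard + p_soft) falls below the threshold are treated as uncertain and
#' counted as omitted rather than assigned. `threshold = NULL` gives the
#' pure argmax matrix with no omissions.
#'
#' @param posteriors n x 5 matrix of class posteriors (columns
#'   [sweepClasses()]).
#' @param truths Character vector of true classes.
#' @param threshold Combined sweep-probability threshold in \[0, 1\], or
#'   NULL.
#' @return List with `threshold`, `counts` (5 x 5 true x assigned integer
#'   matrix) and `omitted` (per-true-class counts); for every true class,
#'   assigned counts plus omissions equal the class size.
#' @export
confusionAtThreshold <- function(posteriors, truths, threshold = NULL) {
  classes <- sweepClasses()
  stopifnot(nrow(posteriors) == length(truths))
  amax <- classes[max.col(posteriors, ties.method = "first")]
  combined <- posteriors[, "hard"] + posteriors[, "soft"]
  omittedFlag <- if (is.null(threshold)) rep(FALSE, length(truths))
    else amax %in% c("hard", "soft") & combined < threshold
  counts <- matrix(0L, 5, 5, dimnames = list(true = classes,
                                             assigned = classes))
  omitted <- setNames(integer(5), classes)
  for (i in seq_along(truths)) {
    if (omittedFlag[i]) omitted[truths[i]] <- omitted[truths[i]] + 1L
    else counts[truths[i], amax[i]] <- counts[truths[i], amax[i]] + 1L
  }
  list(threshold = threshold, counts = counts, omitted = omitted)
}

#' ROC and precision-recall curves for the binary sweep task
#'
#' Scores each example by its combined hard+soft posterior and evaluates
#' the binary task of separating sweeps (true class hard or soft) from
#' unselected regions (neutral or linked). The ROC area is computed by the
#' trapezoid rule; average precision by step-wise summation over the
#' precision-recall curve.
#'
#' @param posteriors n x 5 matrix of class posteriors.
#' @param truths Character vector of true classes; both a positive and a
#'   negative example must be present.
#' @return List with `roc` (data.frame fpr/tpr), `pr` (data.frame
#'   recall/precision), `auc` and `averagePrecision`.
#' @export
binarySweepCurves <- function(posteriors, truths) {
  score <- posteriors[, "hard"] + posteriors[, "soft"]
  pos <- truths %in% c("hard", "soft")
  if (!any(pos) || all(pos))
    stop("need both sweep and unselected examples")
  o <- order(score, decreasing = TRUE)
  pos <- pos[o]; score <- score[o]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  ## collapse tied scores to one operating point
  last <- c(score[-1] != score[-length(score)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  nP <- sum(pos); nN <- length(pos) - nP
  tpr <- c(0, tp / nP)
  fpr <- c(0, fp / nN)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  recall <- tp / nP
  precision <- tp / (tp + fp)
  ap <- sum(diff(c(0, recall)) * precision)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = recall, precision = precision),
       auc = auc, averagePrecision = ap)
}
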