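## Post-classification inference: simulation-null false discovery rates and
## q-values for candidate sweeps, and a conservative confusion-matrix
## correction of the soft-sweep fraction.

#' False discovery rate at a sweep-probability threshold
#'
#' Compares the expected number of neutral windows misclassified as sweeps
#' at threshold `t` — the neutral-simulation exceedance rate scaled to the
#' number of analyzed genomic windows — to the number of real windows at or
#' above `t`:
#' FDR(t) = min(1, nWindows * P(null >= t) / max(1, #\{real >= t\})).
#' Scaling by the full window count assumes all windows could be neutral
#' (pi0 = 1), which is conservative.
#'
#' @param t Threshold in \[0, 1\].
#' @param realProbs Combined sweep probabilities of the scanned windows.
#' @param nullProbs Combined sweep probabilities of neutral test-set
#'   replicates (the simulation null); must be nonempty.
#' @param nWindows Number of analyzed genomic windows.
#' @return FDR in \[0, 1\].
#' @export
fdrAtThreshold <- function(t, realProbs, nullProbs, nWindows) {
  if (length(nullProbs) == 0) stop("empty null distribution")
  if (t < 0 || t > 1) stop("threshold must be in [0, 1]")
  expectedFalse <- nWindows * mean(nullProbs >= t)
  nReal <- sum(realProbs >= t)
  min(1, expectedFalse / max(1, nReal))
}

#' q-values for candidate sweeps
#'
#' Each candidate's sweep probability is treated as a threshold; its
#' q-value is the smallest FDR over all candidate thresholds at or below
#' its own probability (a cumulative minimum over candidates sorted by
#' probability), so q is nonincreasing in the candidate's probability.
#'
#' @param candidateProbs Combined sweep probabilities of the called
#'   candidate sweeps (a subset of `realProbs`).
#' @param realProbs Combined sweep probabilities of all scanned windows.
#' @param nullProbs Neutral-simulation sweep probabilities.
#' @param nWindows Number of analyzed genomic windows.
#' @return Numeric vector of q-values, in `candidateProbs` order.
#' @export
sweepQvalues <- function(candidateProbs, realProbs, nullProbs, nWindows) {
  if (length(candidateProbs) == 0) return(numeric(0))
  fdr <- vapply(candidateProbs, fdrAtThreshold, numeric(1),
                realProbs = realProbs, nullProbs = nullProbs,
                nWindows = nWindows)
  o <- order(candidateProbs)              # ascending probability
  q <- numeric(length(fdr))
  q[o] <- cummin(fdr[o])
  q
}

#' Conservative soft-sweep fraction corrected for classification error
#'
#' Starts from the raw counts of called hard and soft sweeps and applies
#' two conservative corrections: (i) all expected false discoveries
#' (q-value times the number of calls) are assumed to be soft calls and are
#' subtracted from the soft count; (ii) the confusion matrix at the same
#' threshold provides the rate at which true hard sweeps are called soft —
#' the implied number of hard-as-soft calls (estimated true hard count =
#' raw hard / hard recall, times the hard-to-soft rate) is subtracted as
#' well. Soft sweeps misclassified as hard are deliberately ignored, so the
#' estimate is a lower bound on the soft fraction.
#'
#' @param rawHard,rawSoft Numbers of windows called hard and soft at the
#'   threshold.
#' @param q q-value at the threshold.
#' @param confusion Confusion matrix from [confusionAtThreshold()] at the
#'   matching threshold.
#' @return List with the intermediate quantities (`falseDiscoveries`,
#'   `hardAsSoft`) and `softFraction`.
#' @export
correctedSoftFraction <- function(rawHard, rawSoft, q, confusion) {
  if (rawHard < 0 || rawSoft < 0) stop("counts must be >= 0")
  counts <- confusion$counts
  hardRow <- counts["hard", ]
  assigned <- sum(hardRow)
  a <- if (assigned > 0) hardRow[["hard"]] / assigned else 0
  cc <- if (assigned > 0) hardRow[["soft"]] / assigned else 0
  if (a == 0 && rawHard > 0)
    stop("hard-sweep recall is zero; correction undefined")
  nCalls <- rawHard + rawSoft
  falseDisc <- q * nCalls
  soft1 <- max(0, rawSoft - falseDisc)
  trueHard <- if (rawHard > 0) rawHard / a else 0
  hardAsSoft <- trueHard * cc
  soft2 <- max(0, soft1 - hardAsSoft)
  denom <- nCalls - falseDisc
  frac <- if (denom > 0) soft2 / denom else 0
  list(rawHard = rawHard, rawSoft = rawSoft,
       falseDiscoveries = falseDisc, hardRecall = a, hardAsSoftRate = cc,
       hardAsSoft = hardAsSoft, softFraction = frac)
}
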