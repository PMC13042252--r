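## Linkage-disequilibrium statistics for unphased data, all built on the
## Rogers-Huff genotype-correlation estimator of r^2 (squared Pearson
## correlation of dosage vectors), which requires no phase information.

#' Rogers-Huff r^2 between two sites
#'
#' Squared Pearson correlation of the two dosage vectors over individuals
#' with non-missing genotypes at both sites. Returns 0 when fewer than two
#' complete pairs remain or when either vector has zero variance.
#'
#' @param x,y Dosage vectors of equal length (values 0/1/2 or NA).
#' @return r^2 in \[0, 1\].
#' @export
rogersHuffR2 <- function(x, y) {
  if (length(x) != length(y)) stop("dosage vectors must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)^2
}

## internal: full S x S matrix of pairwise Rogers-Huff r^2 values, with the
## degenerate-pair convention (0) applied; diagonal zeroed.
.r2Matrix <- function(d) {
  S <- ncol(d)
  if (S == 0) return(matrix(0, 0, 0))
  if (!anyNA(d)) {
    suppressWarnings(R <- cor(d))
  } else {
    suppressWarnings(R <- cor(d, use = "pairwise.complete.obs"))
  }
  R[!is.finite(R)] <- 0
  R <- R^2
  diag(R) <- 0
  R
}

#' Kelly's Zns
#'
#' The mean Rogers-Huff r^2 over all pairs of sites in the window. Returns 0
#' when fewer than two sites are present.
#'
#' @param gm A [GenotypeMatrix-class].
#' @return Zns in \[0, 1\].
#' @export
kellyZns <- function(gm) {
  .znsFromR2(.r2Matrix(dosages(gm)))
}

.znsFromR2 <- function(R) {
  S <- ncol(R)
  if (S < 2) return(0)
  sum(R) / (S * (S - 1))   # diagonal is zero; symmetric matrix
}

#' Maximum of the omega statistic
#'
#' For each split point l, omega contrasts the average LD within the left
#' (sites 1..l) and right (sites l+1..S) flanks against the average LD
#' between them:
#' omega(l) = \[(C(l,2) + C(S-l,2))^-1 (sum r^2 within left + within right)\]
#' / \[(l(S-l))^-1 sum r^2 across\].
#' The statistic is maximized over l in \[minSplit, S - minSplit\]; splits
#' whose across-flank sum is zero are skipped. Elevated values flag the
#' LD structure expected at the edges of a sweep. Returns 0 when fewer than
#' 2 * minSplit sites are present or no valid split exists.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param minSplit Minimum number of sites per flank (default 3).
#' @return max omega over split points (>= 0).
#' @export
omegaMax <- function(gm, minSplit = 3) {
  .omegaFromR2(.r2Matrix(dosages(gm)), minSplit)
}

.omegaFromR2 <- function(R, minSplit = 3) {
  S <- ncol(R)
  if (S < 2 * minSplit) return(0)
  ## cumulative pair sums: within-left, cross, within-right for every split
  colUp <- vapply(seq_len(S), function(j)
    if (j == 1) 0 else sum(R[seq_len(j - 1), j]), numeric(1))
  withinL <- cumsum(colUp)                 # sum of pairs inside 1..l
  total <- withinL[S]
  rowTot <- cumsum(rowSums(R))             # 2*within + cross contributions
  ls <- seq(minSplit, S - minSplit)
  across <- rowTot[ls] - 2 * withinL[ls]
  withinR <- total - withinL[ls] - across
  nL <- choose(ls, 2)
  nR <- choose(S - ls, 2)
  num <- (withinL[ls] + withinR) / (nL + nR)
  den <- across / (ls * (S - ls))
  ok <- across > 0
  if (!any(ok)) return(0)
  max(num[ok] / den[ok])
}
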