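## Diversity and site-frequency statistics on unphased diploid dosages.
## All statistics handle missing genotypes by per-site sample-size
## adjustment and define explicit conventions for degenerate inputs, so that
## every feature is finite on arbitrary windows.

## internal: per-site non-missing allele counts (2 * non-missing genotypes)
## and alternate-allele counts
.siteCounts <- function(d) {
  nonmiss <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  list(m = 2 * nonmiss, alt = alt)
}

## internal: number of segregating sites among non-missing genotypes
.segSites <- function(d) {
  if (ncol(d) == 0) return(0L)
  sc <- .siteCounts(d)
  sum(sc$alt > 0 & sc$alt < sc$m)
}

## internal: modal non-missing allele count across sites (0 if no sites)
.modalAlleleCount <- function(d) {
  if (ncol(d) == 0) return(0)
  m <- 2 * colSums(!is.na(d))
  tab <- table(m)
  as.numeric(names(tab)[which.max(tab)])
}

#' Nucleotide diversity from unphased dosages
#'
#' Sum over sites of the unbiased per-site heterozygosity
#' 2*p*q*m/(m-1), where p is the alternate-allele frequency among the m
#' non-missing alleles at the site. Sites with fewer than two non-missing
#' alleles are skipped; an empty matrix gives 0. Equivalent to the average
#' number of pairwise differences between the sampled (haploid) alleles.
#'
#' @param gm A [GenotypeMatrix-class].
#' @return Nucleotide diversity (absolute over the window, not per bp).
#' @export
nucleotideDiversity <- function(gm) {
  d <- dosages(gm)
  if (ncol(d) == 0) return(0)
  sc <- .siteCounts(d)
  keep <- sc$m >= 2
  if (!any(keep)) return(0)
  m <- sc$m[keep]
  p <- sc$alt[keep] / m
  sum(2 * p * (1 - p) * m / (m - 1))
}

#' Watterson's theta from unphased dosages
#'
#' S / a_{m-1}, where S is the number of segregating sites (among non-missing
#' genotypes) and a_{m-1} is the harmonic number for the modal non-missing
#' allele count m. Empty input gives 0.
#'
#' @param gm A [GenotypeMatrix-class].
#' @return Watterson's estimator (absolute over the window).
#' @export
wattersonTheta <- function(gm) {
  d <- dosages(gm)
  S <- .segSites(d)
  if (S == 0) return(0)
  m <- .modalAlleleCount(d)
  if (m < 2) return(0)
  S / sum(1 / seq_len(m - 1))
}

#' Tajima's D from unphased dosages
#'
#' The standardized difference between nucleotide diversity and Watterson's
#' theta, with the variance constants computed from the modal non-missing
#' allele count. Returns 0 when there are no segregating sites (convention)
#' or when the variance term vanishes.
#'
#' @param gm A [GenotypeMatrix-class].
#' @return Tajima's D.
#' @export
tajimasD <- function(gm) {
  d <- dosages(gm)
  S <- .segSites(d)
  if (S == 0) return(0)
  n <- .modalAlleleCount(d)
  if (n < 3) return(0)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(0)
  (nucleotideDiversity(gm) - S / a1) / sqrt(v)
}

#' Moments of the pairwise-difference distribution
#'
#' For every pair of individuals, the number of pairwise dosage differences
#' d_ij = sum_sites |dosage_i - dosage_j| over sites where both genotypes
#' are non-missing. Returns the population variance, skewness and
#' (non-excess) kurtosis of the distribution of d_ij over all pairs; a
#' zero-variance distribution gives (0, 0, 0).
#'
#' @param gm A [GenotypeMatrix-class] with at least two individuals.
#' @return Named numeric vector (variance, skewness, kurtosis).
#' @export
pairwiseDiffMoments <- function(gm) {
  d <- dosages(gm)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 individuals")
  if (ncol(d) == 0) {
    dd <- numeric(n * (n - 1) / 2)
  } else if (!anyNA(d)) {
    dd <- as.numeric(stats::dist(d, method = "manhattan"))
  } else {
    dd <- numeric(0)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        both <- !is.na(d[i, ]) & !is.na(d[j, ])
        dd <- c(dd, sum(abs(d[i, both] - d[j, both])))
      }
    }
  }
  mu <- mean(dd)
  v <- mean((dd - mu)^2)
  if (v == 0) return(c(variance = 0, skewness = 0, kurtosis = 0))
  m3 <- mean((dd - mu)^3)
  m4 <- mean((dd - mu)^4)
  c(variance = v, skewness = m3 / v^1.5, kurtosis = m4 / v^2)
}
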