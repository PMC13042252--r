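#' Names and order of the twelve summary statistics
#'
#' The fixed row order of every feature matrix: nucleotide diversity (pi),
#' Watterson's theta, Tajima's D, number of distinct multilocus genotypes,
#' H1, H12, H2/H1, Kelly's Zns, max omega, and the variance, skewness and
#' kurtosis of the pairwise-difference distribution.
#'
#' @return Character vector of length 12.
#' @export
statNames <- function() {
  c("pi", "theta_w", "tajimas_d", "n_distinct_mlg", "h1", "h12", "h2_h1",
    "zns", "omega_max", "pwdiff_var", "pwdiff_skew", "pwdiff_kurt")
}

#' Compute the full statistic vector for one window
#'
#' Evaluates the twelve summary statistics (see [statNames()]) on a
#' genotype matrix, applying each statistic's degenerate-input convention.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param minSplit Minimum flank size for the omega statistic.
#' @return Named numeric vector of length 12.
#' @export
statVector <- function(gm, minSplit = 3) {
  d <- dosages(gm)
  R <- .r2Matrix(d)
  mlg <- mlgSpectrum(gm)
  pw <- pairwiseDiffMoments(gm)
  out <- c(nucleotideDiversity(gm), wattersonTheta(gm), tajimasD(gm),
           mlg[["nDistinct"]], mlg[["h1"]], mlg[["h12"]], mlg[["h2h1"]],
           .znsFromR2(R), .omegaFromR2(R, minSplit),
           pw[["variance"]], pw[["skewness"]], pw[["kurtosis"]])
  names(out) <- statNames()
  out
}
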