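## Mask transfer: simulated windows inherit the missing-data footprint of
## randomly chosen empirical windows, so that heterogeneous data quality
## affects training data the same way it affects the real scan.

## internal: remove variants of gm that fall inside the profile's masked
## intervals, rescaling the profile onto gm's interval when lengths differ
.applyMask <- function(gm, profile) {
  m <- profile@masked
  if (nrow(m) == 0) return(gm)
  scale <- (gm@end - gm@start) / (profile@end - profile@start)
  m0 <- (m - profile@start) * scale + gm@start
  keep <- rep(TRUE, length(gm@positions))
  for (i in seq_len(nrow(m0)))
    keep <- keep & !(gm@positions >= m0[i, 1] & gm@positions < m0[i, 2])
  GenotypeMatrix(gm@chrom, gm@start, gm@end, gm@positions[keep],
                 gm@dosages[, keep, drop = FALSE])
}

#' Transfer an empirical masking profile onto a simulated replicate
#'
#' Chooses one profile uniformly at random from the library, rescales its
#' masked intervals proportionally onto the replicate's interval, removes
#' the variants that fall inside them, and records the profile on the
#' result.
#'
#' @param replicate A [LabeledReplicate-class] (or a [GenotypeMatrix-class]
#'   together with `params`).
#' @param maskLibrary Nonempty list of [MaskProfile-class] objects.
#' @param params A [SimParams-class], required when `replicate` is a bare
#'   genotype matrix.
#' @return A [LabeledReplicate-class] with the mask applied and recorded.
#' @export
applyMaskTransfer <- function(replicate, maskLibrary, params = NULL) {
  if (length(maskLibrary) == 0) stop("mask library is empty")
  if (is(replicate, "LabeledReplicate")) {
    params <- replicate@params
    gm <- replicate@genotypes
  } else {
    if (is.null(params)) stop("params required for a bare genotype matrix")
    gm <- replicate
  }
  profile <- maskLibrary[[sample.int(length(maskLibrary), 1)]]
  new("LabeledReplicate", params = params, genotypes = .applyMask(gm, profile),
      mask = profile)
}

#' Build a mask-profile library from a mask BED
#'
#' Intersects the masked intervals of a BED-derived table with each window
#' and returns one [MaskProfile-class] per window.
#'
#' @param maskBed data.frame with chrom, start, end (0-based half-open) of
#'   masked intervals.
#' @param windows data.frame of windows (chrom, start, end).
#' @return List of [MaskProfile-class], one per window row.
#' @export
maskProfilesFromBed <- function(maskBed, windows) {
  lapply(seq_len(nrow(windows)), function(i) {
    ch <- windows$chrom[i]; s <- windows$start[i]; e <- windows$end[i]
    sub <- maskBed[maskBed$chrom == ch & maskBed$end > s & maskBed$start < e,
                   , drop = FALSE]
    m <- if (nrow(sub)) .mergeIntervals(pmax(sub$start, s), pmin(sub$end, e))
         else matrix(0, 0, 2)
    MaskProfile(ch, s, e, m)
  })
}
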