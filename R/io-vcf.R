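#' Read a window of unphased diploid genotypes from a VCF
#'
#' Reads the biallelic SNPs of one genomic interval into a
#' [GenotypeMatrix-class]. Multiallelic records and indels are skipped;
#' genotypes whose quality (GQ) is below `minGq` are set to missing, the
#' default threshold of 20 matching the usual genotype-quality mask for
#' resequencing data. When the FORMAT of a record carries no GQ field its
#' genotypes are treated as passing. Sites left with no non-missing genotype
#' are dropped. VCF positions (1-based) are converted to the internal
#' 0-based convention.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @param chrom Chromosome name.
#' @param start,end Interval bounds, 0-based half-open.
#' @param minGq Genotype-quality threshold; genotypes with GQ < minGq are
#'   masked (default 20).
#' @return A [GenotypeMatrix-class]; an interval overlapping no record gives
#'   a 0-site matrix (not an error).
#' @export
readVcfWindow <- function(path, chrom, start, end, minGq = 20) {
  .checkInterval(chrom, start, end)
  if (minGq < 0) stop("minGq must be >= 0")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0)
    return(GenotypeMatrix(chrom, start, end, numeric(0),
                          matrix(integer(0), nrow = 0, ncol = 0)))
  nInd <- ncol(vcf@gt) - 1L
  pos0 <- as.numeric(fix[, "POS"]) - 1
  snp <- !is.na(fix[, "ALT"]) & !grepl(",", fix[, "ALT"], fixed = TRUE) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  keep <- fix[, "CHROM"] == chrom & pos0 >= start & pos0 < end & snp
  if (!any(keep))
    return(GenotypeMatrix(chrom, start, end, numeric(0),
                          matrix(integer(0), nrow = nInd, ncol = 0)))
  vcf <- vcf[keep, ]
  pos0 <- pos0[keep]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ## dosage = number of alternate alleles in the unphased genotype
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  core <- sub(":.*$", "", gt)
  dos[core %in% c("0/0", "0|0")] <- 0L
  dos[core %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[core %in% c("1/1", "1|1")] <- 2L
  gq <- suppressWarnings(
    tryCatch(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE),
             error = function(e) NULL))
  if (!is.null(gq)) dos[!is.na(gq) & gq < minGq] <- NA_integer_
  dos <- t(dos)  # individuals x sites
  o <- order(pos0)
  pos0 <- pos0[o]
  dos <- dos[, o, drop = FALSE]
  dup <- duplicated(pos0)
  pos0 <- pos0[!dup]
  dos <- dos[, !dup, drop = FALSE]
  informative <- colSums(!is.na(dos)) > 0
  GenotypeMatrix(chrom, start, end, pos0[informative],
                 dos[, informative, drop = FALSE])
}
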