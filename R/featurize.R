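## Featurization: a feature window is split into k adjacent subwindows, the
## twelve statistics are computed in each, and each statistic's row is
## normalized to sum to one so that only the spatial pattern, not the
## absolute level, is presented to the classifier.  This makes the features
## robust to genome-wide shifts in diversity caused by demography.

#' Slice a GenotypeMatrix to a sub-interval
#'
#' Returns the genotype matrix restricted to sites with
#' start <= position < end (half-open: a site exactly on the boundary
#' belongs to the right-hand subwindow).
#'
#' @param gm A [GenotypeMatrix-class].
#' @param start,end Sub-interval bounds (0-based half-open), which must lie
#'   within the matrix interval.
#' @return A [GenotypeMatrix-class] over \[start, end).
#' @export
sliceGenotypes <- function(gm, start, end) {
  if (start < gm@start || end > gm@end || start >= end)
    stop("slice must be a nonempty sub-interval of the genotype matrix")
  keep <- gm@positions >= start & gm@positions < end
  GenotypeMatrix(gm@chrom, start, end, gm@positions[keep],
                 gm@dosages[, keep, drop = FALSE])
}

#' Partition a window into equal adjacent subwindows
#'
#' @param chrom Chromosome name.
#' @param start,end Window bounds (0-based half-open); the length must be
#'   divisible by `k`.
#' @param k Number of subwindows; the central subwindow has 0-based index
#'   (k-1)/2.
#' @return data.frame with columns chrom, start, end — `k` adjacent equal
#'   intervals exactly covering the window.
#' @examples
#' subwindowPartition("chr2", 0, 2.75e6, 11)   # eleven 250 kb subwindows
#' @export
subwindowPartition <- function(chrom, start, end, k = 11) {
  .checkInterval(chrom, start, end)
  len <- end - start
  if (len %% k != 0)
    stop("window length ", len, " is not divisible by k = ", k)
  w <- len / k
  s <- start + w * (seq_len(k) - 1)
  .windowFrame(rep(chrom, k), s, s + w)
}

#' Raw statistic matrix over subwindows
#'
#' Computes [statVector()] on the genotype submatrix of each subwindow.
#'
#' @param gm A [GenotypeMatrix-class] covering all subwindows.
#' @param subwindows data.frame of subwindows (from [subwindowPartition()]).
#' @return 12 x k numeric matrix (rows: [statNames()]).
#' @export
rawStatMatrix <- function(gm, subwindows) {
  k <- nrow(subwindows)
  vapply(seq_len(k), function(j)
    statVector(sliceGenotypes(gm, subwindows$start[j], subwindows$end[j])),
    numeric(12))
}

#' Row-normalize a raw statistic matrix
#'
#' Per row: if the smallest value is negative, its absolute value is added
#' to every entry (shift to nonnegative); the row is then divided by its
#' sum. Rows whose entries are all zero after the shift become the uniform
#' row 1/k. The shift is applied before division since dividing by a
#' negative or zero row sum is ill-defined.
#'
#' @param raw 12 x k numeric matrix of raw statistics.
#' @return 12 x k matrix in which every row is nonnegative and sums to 1.
#' @export
normalizeRows <- function(raw) {
  if (any(!is.finite(raw))) stop("raw statistic matrix must be finite")
  k <- ncol(raw)
  t(apply(raw, 1, function(row) {
    mn <- min(row)
    if (mn < 0) row <- row - mn
    s <- sum(row)
    if (s == 0) rep(1 / k, k) else row / s
  }))
}

#' Featurize one window
#'
#' Partitions the window into `k` subwindows, computes the raw statistic
#' matrix and row-normalizes it.
#'
#' @param gm A [GenotypeMatrix-class] covering the window.
#' @param start,end Window bounds (defaults: the matrix interval); the
#'   length must be divisible by `k`.
#' @param k Number of subwindows (default 11).
#' @param maskedFraction Masked fraction to record on the result.
#' @return A [FeatureMatrix-class].
#' @export
featurizeWindow <- function(gm, start = gm@start, end = gm@end, k = 11,
                            maskedFraction = 0) {
  sw <- subwindowPartition(gm@chrom, start, end, k)
  raw <- rawStatMatrix(gm, sw)
  vals <- normalizeRows(raw)
  rownames(vals) <- statNames()
  colnames(vals) <- paste0("sw", seq_len(k) - 1)
  new("FeatureMatrix", values = vals, chrom = gm@chrom,
      start = as.numeric(start), end = as.numeric(end),
      maskedFraction = maskedFraction)
}

#' Flatten feature matrices into a feature table
#'
#' Converts a list of [FeatureMatrix-class] objects (or of
#' [LabeledReplicate-class] objects, which are featurized first) into the
#' n x (12 k) numeric matrix consumed by the classifier, with columns named
#' `stat_subwindowIndex`.
#'
#' @param x List of FeatureMatrix or LabeledReplicate objects.
#' @param k Number of subwindows (used when featurizing replicates).
#' @return List with `features` (n x 12k matrix) and, when `x` holds labeled
#'   replicates, `labels` (character vector).
#' @export
featureTable <- function(x, k = 11) {
  if (length(x) == 0) stop("empty input")
  labels <- NULL
  if (is(x[[1]], "LabeledReplicate")) {
    labels <- vapply(x, classLabel, character(1))
    x <- lapply(x, function(rep) {
      gm <- genotypes(rep)
      mf <- if (is.null(rep@mask)) 0 else rep@mask@maskedFraction
      featurizeWindow(gm, k = k, maskedFraction = mf)
    })
  }
  feats <- t(vapply(x, function(fm) as.numeric(t(featureValues(fm))),
                    numeric(12 * ncol(featureValues(x[[1]])))))
  kk <- ncol(featureValues(x[[1]]))
  colnames(feats) <- paste(rep(statNames(), each = kk),
                           rep(seq_len(kk) - 1, times = 12), sep = "_")
  out <- list(features = feats)
  if (!is.null(labels)) out$labels <- labels
  out
}

#' Write / read a feature archive TSV
#'
#' One row per replicate or window: a replicate id column, the 12 k
#' feature columns named `stat_subwindowIndex`, and (when available) a
#' label column.
#'
#' @param ft List with `features` (and optionally `labels`), as returned
#'   by [featureTable()].
#' @param path Output (input) path.
#' @return `path`, or the restored feature table list.
#' @export
writeFeatureTable <- function(ft, path) {
  df <- data.frame(replicate = seq_len(nrow(ft$features)))
  if (!is.null(ft$labels)) df$label <- ft$labels
  df <- cbind(df, as.data.frame(ft$features))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  featCols <- setdiff(names(df), c("replicate", "label"))
  out <- list(features = as.matrix(df[, featCols]))
  if (!is.null(df$label)) out$labels <- df$label
  out
}
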