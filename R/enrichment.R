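## Permutation enrichment tests for annotation overlap with sweep windows:
## a gene-set test that shuffles the association between sweep calls and
## window positions, and a GO-term test whose null rotates the per-window
## scores around the concatenated chromosomes, preserving the spatial
## autocorrelation of the scores.

#' Assemble an annotation set
#'
#' @param genes data.frame with columns id, chrom, start, end (0-based
#'   half-open gene intervals).
#' @param goMap Optional data.frame with columns gene_id, term.
#' @param focal Optional character vector of focal gene ids (must be a
#'   subset of `genes$id`), e.g. a curated insecticide-resistance list.
#' @return List of class `AnnotationSet`.
#' @export
annotationSet <- function(genes, goMap = NULL, focal = character(0)) {
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(genes)))
  if (!all(focal %in% genes$id))
    stop("focal genes absent from the gene table: ",
         paste(setdiff(focal, genes$id), collapse = ", "))
  structure(list(genes = genes, goMap = goMap, focal = focal),
            class = "AnnotationSet")
}

## internal: genes x windows overlap incidence for padded gene intervals
.geneWindowIncidence <- function(genes, windows, pad) {
  g <- GenomicRanges::GRanges(genes$chrom,
         IRanges::IRanges(start = pmax(0, genes$start - pad) + 1,
                          end = genes$end + pad))
  w <- .asGRanges(windows)
  hits <- GenomicRanges::findOverlaps(g, w)
  M <- matrix(FALSE, nrow(genes), nrow(windows))
  M[cbind(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))] <- TRUE
  M
}

#' Count genes overlapping sweep windows
#'
#' Number of (focal) genes whose interval, extended by `pad` bp on either
#' side, overlaps at least one sweep window; each gene counts once however
#' many windows it touches.
#'
#' @param sweepWindows data.frame of sweep windows (chrom, start, end).
#' @param annotations An [annotationSet()].
#' @param pad Padding in bp (default 1000).
#' @param restrictToFocal Count only the focal set (default TRUE).
#' @return Integer count.
#' @export
geneOverlapCount <- function(sweepWindows, annotations, pad = 1000,
                             restrictToFocal = TRUE) {
  genes <- annotations$genes
  if (restrictToFocal) genes <- genes[genes$id %in% annotations$focal, ,
                                      drop = FALSE]
  if (nrow(genes) == 0 || nrow(sweepWindows) == 0) return(0L)
  M <- .geneWindowIncidence(genes, sweepWindows, pad)
  sum(rowSums(M) > 0)
}

#' Gene-set enrichment by score permutation
#'
#' Tests whether focal genes overlap sweep windows (score >= threshold)
#' more often than expected when the association between scores and window
#' positions is destroyed. Each permutation reassigns the scores to window
#' positions uniformly at random (equivalently, draws a random window
#' subset of the observed sweep count) and recounts overlapping focal
#' genes. The one-sided p-value is the proportion of permutations with a
#' count at or above the observed one (the observed arrangement is not
#' added to the numerator; set `plusOne = TRUE` for the conservative
#' variant).
#'
#' @param windowScores Per-window combined sweep probabilities.
#' @param windows data.frame of the windows (chrom, start, end), same
#'   length as `windowScores`.
#' @param annotations An [annotationSet()] with a nonempty focal set.
#' @param threshold Sweep-call threshold (default 0.95).
#' @param nPerm Number of permutations (default 10000).
#' @param pad Gene padding in bp (default 1000).
#' @param plusOne Add-one correction to the p-value (default FALSE).
#' @param seed Seed for the permutations.
#' @return List with `observed`, `permMean`, `fold`, `p`, `nPerm`.
#' @export
permutationGeneSetTest <- function(windowScores, windows, annotations,
                                   threshold = 0.95, nPerm = 10000,
                                   pad = 1000, plusOne = FALSE, seed = 1) {
  stopifnot(length(windowScores) == nrow(windows))
  sweepIdx <- which(windowScores >= threshold)
  genes <- annotations$genes[annotations$genes$id %in% annotations$focal, ,
                             drop = FALSE]
  if (length(sweepIdx) == 0 || nrow(genes) == 0) {
    return(list(observed = 0L, permMean = 0, fold = NA_real_, p = 1,
                nPerm = nPerm))
  }
  M <- .geneWindowIncidence(genes, windows, pad)
  countFor <- function(idx) sum(rowSums(M[, idx, drop = FALSE]) > 0)
  observed <- countFor(sweepIdx)
  nW <- nrow(windows)
  permCounts <- .withSeed(seed, vapply(seq_len(nPerm), function(i)
    countFor(sample.int(nW, length(sweepIdx))), numeric(1)))
  hits <- sum(permCounts >= observed)
  p <- if (plusOne) (hits + 1) / (nPerm + 1) else hits / nPerm
  permMean <- mean(permCounts)
  list(observed = observed, permMean = permMean,
       fold = if (permMean > 0) observed / permMean else NA_real_,
       p = p, nPerm = nPerm)
}

#' GO-term enrichment by circular rotation
#'
#' Tests, per GO term, whether the term's genes overlap sweep windows more
#' often than expected under a null that preserves the spatial
#' autocorrelation of the sweep scores: the per-window scores of all
#' chromosomes are concatenated into a ring (windows must be supplied in
#' genome order) and each permutation rotates the score vector by an offset
#' drawn uniformly from \[1, nWindows - 1\], so the multiset of scores and
#' all adjacencies except at the two splice points are preserved.
#'
#' @param windowScores Per-window combined sweep probabilities, in genome
#'   order.
#' @param windows data.frame of the windows (chrom, start, end), ordered by
#'   chromosome then position; at least two windows.
#' @param annotations An [annotationSet()] with a `goMap`.
#' @param threshold Sweep-call threshold (default 0.8).
#' @param nPerm Number of rotations (default 10000).
#' @param pad Gene padding in bp (default 1000).
#' @param plusOne Add-one correction to the p-values (default FALSE).
#' @param seed Seed for the rotation offsets.
#' @return data.frame with one row per term: observed, permMean, fold, p,
#'   and BH-adjusted q.
#' @export
circularRotationTest <- function(windowScores, windows, annotations,
                                 threshold = 0.8, nPerm = 10000, pad = 1000,
                                 plusOne = FALSE, seed = 1) {
  nW <- nrow(windows)
  if (nW < 2) stop("need at least two windows for rotation")
  stopifnot(length(windowScores) == nW)
  goMap <- annotations$goMap
  if (is.null(goMap)) stop("annotation set carries no GO map")
  genes <- annotations$genes
  genes <- genes[genes$id %in% goMap$gene_id, , drop = FALSE]
  terms <- sort(unique(goMap$term))
  M <- .geneWindowIncidence(genes, windows, pad)
  TG <- vapply(terms, function(tm)
    genes$id %in% goMap$gene_id[goMap$term == tm], logical(nrow(genes)))
  sweepFlag <- windowScores >= threshold
  countTerms <- function(flag) {
    geneHit <- rowSums(M[, flag, drop = FALSE]) > 0
    as.numeric(colSums(TG & geneHit))
  }
  observed <- countTerms(sweepFlag)
  offsets <- .withSeed(seed, sample.int(nW - 1, nPerm, replace = TRUE))
  permSum <- numeric(length(terms))
  permGE <- numeric(length(terms))
  for (off in offsets) {
    rotated <- sweepFlag[((seq_len(nW) - 1 + off) %% nW) + 1]
    cnt <- countTerms(rotated)
    permSum <- permSum + cnt
    permGE <- permGE + (cnt >= observed)
  }
  permMean <- permSum / nPerm
  ## literal proportion; may be 0 without the add-one correction
  p <- if (plusOne) (permGE + 1) / (nPerm + 1) else permGE / nPerm
  data.frame(term = terms, observed = observed, permMean = permMean,
             fold = ifelse(permMean > 0, observed / permMean, NA_real_),
             p = p, q = bhFdr(pmax(p, 1e-12)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment mapped back to the input order; input p-values must
#' lie in (0, 1].
#'
#' @param pvalues Numeric vector of p-values.
#' @return Numeric vector of BH q-values.
#' @export
bhFdr <- function(pvalues) {
  if (any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
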