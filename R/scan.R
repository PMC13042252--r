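## Genome scan: sliding feature windows stepped by one subwindow, the two
## data-quality filters (zero recombination, excessive masking), calling at
## combined-probability thresholds, and cross-population intersection.

#' Enumerate sliding scan windows
#'
#' Feature windows of length `windowLen` at starts 0, step, 2*step, ...
#' with start + windowLen <= chromosome length, each paired with its
#' central subwindow (the classified interval). Chromosomes shorter than
#' `windowLen` contribute no windows.
#'
#' @param chromLengths Named numeric vector of chromosome lengths.
#' @param windowLen Feature-window length (divisible by `k`).
#' @param step Step between window starts (typically windowLen / k).
#' @param k Number of subwindows.
#' @return data.frame with chrom, start, end (feature window) and cstart,
#'   cend (central subwindow), ordered by chromosome then start.
#' @export
enumerateWindows <- function(chromLengths, windowLen, step, k = 11) {
  if (windowLen %% k != 0) stop("windowLen must be divisible by k")
  sub <- windowLen / k
  central <- (k - 1) / 2
  out <- lapply(names(chromLengths), function(ch) {
    len <- chromLengths[[ch]]
    if (len < windowLen) return(NULL)
    starts <- seq(0, len - windowLen, by = step)
    data.frame(chrom = ch, start = starts, end = starts + windowLen,
               cstart = starts + central * sub,
               cend = starts + (central + 1) * sub,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), cstart = numeric(0),
                      cend = numeric(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Length-weighted mean recombination rate over an interval
#'
#' Sum of rate_i * overlap_i over the map intervals, divided by the
#' interval length; map-uncovered stretches contribute rate 0.
#'
#' @param map A [RecombinationMap-class].
#' @param chrom,start,end The query interval (0-based half-open).
#' @return Weighted mean rate (>= 0).
#' @export
weightedRecombRate <- function(map, chrom, start, end) {
  m <- mapTable(map)
  m <- m[m$chrom == chrom & m$end > start & m$start < end, , drop = FALSE]
  if (nrow(m) == 0) return(0)
  ov <- pmin(m$end, end) - pmax(m$start, start)
  sum(m$rate * ov) / (end - start)
}

#' Apply the scan's data-quality filters
#'
#' Drops windows whose recombination rate is zero (the spatial sweep
#' signature is undefined without recombination) and windows whose masked
#' fraction exceeds `maxMaskedFraction` (strict inequality: a fraction
#' exactly at the cutoff is retained). By default the recombination filter
#' is evaluated over the central (classified) subwindow and the mask filter
#' over the full feature window (the featurization footprint); both
#' footprints are configurable.
#'
#' @param windows data.frame from [enumerateWindows()].
#' @param map A [RecombinationMap-class].
#' @param maskBed data.frame of masked intervals (chrom, start, end), or
#'   NULL to skip the mask filter.
#' @param maxMaskedFraction Mask cutoff (default 0.85).
#' @param recombFootprint,maskFootprint `"central"` or `"window"`.
#' @return The retained windows, with columns `recombRate` and
#'   `maskedFraction` added and an attribute `filterCounts` recording how
#'   many windows each filter removed.
#' @export
filterWindows <- function(windows, map, maskBed = NULL,
                          maxMaskedFraction = 0.85,
                          recombFootprint = c("central", "window"),
                          maskFootprint = c("window", "central")) {
  recombFootprint <- match.arg(recombFootprint)
  maskFootprint <- match.arg(maskFootprint)
  foot <- function(which, i) {
    if (which == "central") c(windows$cstart[i], windows$cend[i])
    else c(windows$start[i], windows$end[i])
  }
  n <- nrow(windows)
  rr <- vapply(seq_len(n), function(i) {
    f <- foot(recombFootprint, i)
    weightedRecombRate(map, windows$chrom[i], f[1], f[2])
  }, numeric(1))
  mf <- rep(0, n)
  if (!is.null(maskBed)) {
    mf <- vapply(seq_len(n), function(i) {
      f <- foot(maskFootprint, i)
      sub <- maskBed[maskBed$chrom == windows$chrom[i] &
                     maskBed$end > f[1] & maskBed$start < f[2], ,
                     drop = FALSE]
      if (nrow(sub) == 0) return(0)
      sum(pmin(sub$end, f[2]) - pmax(sub$start, f[1])) / (f[2] - f[1])
    }, numeric(1))
  }
  windows$recombRate <- rr
  windows$maskedFraction <- mf
  keepRecomb <- rr > 0
  keepMask <- mf <= maxMaskedFraction
  out <- windows[keepRecomb & keepMask, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filterCounts") <- c(total = n,
                                 zeroRecomb = sum(!keepRecomb),
                                 overMasked = sum(keepRecomb & !keepMask),
                                 retained = nrow(out))
  out
}

#' Call sweeps at a combined-probability threshold
#'
#' If the argmax class is hard or soft, the window is called a sweep (typed
#' by the larger of p_hard and p_soft, ties toward soft) when
#' p_hard + p_soft >= threshold, and `uncertain` otherwise; windows whose
#' argmax is a linked or neutral class keep that class. `threshold = NULL`
#' is pure argmax classification.
#'
#' @param posteriors n x 5 matrix of class posteriors.
#' @param threshold Combined sweep-probability threshold, or NULL.
#' @return Character vector of decisions: one of `sweep-hard`,
#'   `sweep-soft`, `uncertain`, `hard-linked`, `soft-linked`, `neutral`.
#' @export
callSweeps <- function(posteriors, threshold = NULL) {
  classes <- sweepClasses()
  amax <- classes[max.col(posteriors, ties.method = "first")]
  combined <- posteriors[, "hard"] + posteriors[, "soft"]
  sweepType <- ifelse(posteriors[, "hard"] > posteriors[, "soft"],
                      "sweep-hard", "sweep-soft")
  out <- amax
  isSweep <- amax %in% c("hard", "soft")
  pass <- if (is.null(threshold)) rep(TRUE, nrow(posteriors))
          else combined >= threshold
  out[isSweep & pass] <- sweepType[isSweep & pass]
  out[isSweep & !pass] <- "uncertain"
  out
}

#' Classify the windows of a genome
#'
#' Featurizes every (filtered) window of the per-chromosome genotype
#' matrices, predicts posteriors and assembles the scan call table.
#' Variants inside masked intervals are removed before featurization, and
#' each window's masked fraction is recorded.
#'
#' @param genotypesByChrom Named list of [GenotypeMatrix-class], one per
#'   chromosome.
#' @param model A [SweepClassifier-class].
#' @param windows data.frame of (filtered) windows, as returned by
#'   [filterWindows()].
#' @param maskBed Optional data.frame of masked intervals to remove from
#'   the genotypes.
#' @param threshold Combined sweep-probability threshold for the `decision`
#'   column (default 0.95).
#' @param k Number of subwindows.
#' @return data.frame of sweep calls: central-subwindow coordinates, the
#'   five posterior columns, combined sweep probability and decision.
#' @export
classifyGenome <- function(genotypesByChrom, model, windows, maskBed = NULL,
                           threshold = 0.95, k = 11) {
  if (!is.null(maskBed)) {
    genotypesByChrom <- lapply(genotypesByChrom, function(gm) {
      sub <- maskBed[maskBed$chrom == gm@chrom & maskBed$end > gm@start &
                       maskBed$start < gm@end, , drop = FALSE]
      if (nrow(sub) == 0) return(gm)
      prof <- MaskProfile(gm@chrom, gm@start, gm@end,
                          .mergeIntervals(pmax(sub$start, gm@start),
                                          pmin(sub$end, gm@end)))
      .applyMask(gm, prof)
    })
  }
  fms <- lapply(seq_len(nrow(windows)), function(i) {
    gm <- genotypesByChrom[[windows$chrom[i]]]
    sub <- sliceGenotypes(gm, windows$start[i], windows$end[i])
    mf <- if (!is.null(windows$maskedFraction)) windows$maskedFraction[i]
          else 0
    featurizeWindow(sub, k = k, maskedFraction = mf)
  })
  ft <- featureTable(fms, k = k)
  post <- predictPosterior(model, ft$features)
  combined <- post[, "hard"] + post[, "soft"]
  data.frame(chrom = windows$chrom, start = windows$cstart,
             end = windows$cend, fstart = windows$start,
             fend = windows$end,
             predicted_class = sweepClasses()[max.col(post, "first")],
             prob_neutral = post[, "neutral"],
             prob_hard_linked = post[, "hard-linked"],
             prob_soft_linked = post[, "soft-linked"],
             prob_hard = post[, "hard"], prob_soft = post[, "soft"],
             combined_sweep_prob = combined,
             decision = callSweeps(post, threshold),
             stringsAsFactors = FALSE)
}

#' Intersect sweep calls across population samples
#'
#' Keys windows by coordinates and reports, for every window called a sweep
#' in at least one population at the threshold, the set of populations
#' calling it: the full intersection-cardinality table (upset-style), the
#' shared set (called in more than one population) and the
#' population-specific set.
#'
#' @param callsByPopulation Named list of scan-call data.frames sharing the
#'   same window grid (coordinates must match across populations).
#' @param threshold Combined sweep-probability threshold (default 0.95).
#' @return List with `membership` (windows x populations logical
#'   data.frame), `intersectionCounts` (named vector keyed by
#'   population combination), `shared` and `specific` window data.frames.
#' @export
intersectPopulations <- function(callsByPopulation, threshold = 0.95) {
  pops <- names(callsByPopulation)
  key <- function(df) paste(df$chrom, df$start, df$end, sep = ":")
  keys <- lapply(callsByPopulation, key)
  if (length(unique(vapply(keys, paste, character(1), collapse = ";"))) != 1)
    stop("populations must share the same window grid")
  base <- callsByPopulation[[1]][, c("chrom", "start", "end")]
  isSweep <- vapply(callsByPopulation, function(df)
    df$predicted_class %in% c("hard", "soft") &
      df$combined_sweep_prob >= threshold,
    logical(nrow(base)))
  colnames(isSweep) <- pops
  any <- rowSums(isSweep) > 0
  memb <- data.frame(base[any, , drop = FALSE], isSweep[any, , drop = FALSE])
  combo <- apply(isSweep[any, , drop = FALSE], 1, function(b)
    paste(pops[b], collapse = "+"))
  counts <- table(combo)
  nPop <- rowSums(isSweep[any, , drop = FALSE])
  list(membership = memb,
       intersectionCounts = setNames(as.integer(counts), names(counts)),
       shared = base[any, , drop = FALSE][nPop > 1, , drop = FALSE],
       specific = base[any, , drop = FALSE][nPop == 1, , drop = FALSE])
}
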