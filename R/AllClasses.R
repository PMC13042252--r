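## Central S4 data containers.  Coordinates are 0-based half-open throughout;
## conversion to/from the 1-based inclusive reporting convention happens only
## at I/O boundaries (see io-tables.R).

#' GenotypeMatrix: unphased diploid dosages in a genomic interval
#'
#' Holds the alternate-allele dosage (0, 1, 2, or `NA` for a masked genotype)
#' of every individual at every segregating site inside a genomic interval.
#' Positions are 0-based and strictly increasing; every retained site has at
#' least one non-missing genotype.
#'
#' @slot chrom Chromosome name.
#' @slot start,end Interval bounds, 0-based half-open.
#' @slot positions Numeric vector of 0-based site positions.
#' @slot dosages Integer matrix, individuals x sites, values in
#'   \{0, 1, 2, NA\}.
#' @export
setClass("GenotypeMatrix",
  representation(chrom = "character", start = "numeric", end = "numeric",
                 positions = "numeric", dosages = "matrix"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@chrom) != 1L || !nzchar(object@chrom))
      msg <- c(msg, "'chrom' must be a nonempty string")
    if (!(object@start >= 0 && object@start < object@end))
      msg <- c(msg, "need 0 <= start < end")
    p <- object@positions
    if (ncol(object@dosages) != length(p))
      msg <- c(msg, "ncol(dosages) must equal length(positions)")
    if (length(p) > 0) {
      if (any(diff(p) <= 0))
        msg <- c(msg, "positions must be strictly increasing")
      if (p[1] < object@start || p[length(p)] >= object@end)
        msg <- c(msg, "positions must lie inside [start, end)")
      d <- object@dosages
      if (!all(d[!is.na(d)] %in% 0:2))
        msg <- c(msg, "dosages must be 0, 1, 2 or NA")
      if (any(colSums(!is.na(d)) == 0))
        msg <- c(msg, "every site must have at least one non-missing genotype")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a GenotypeMatrix
#'
#' @param chrom Chromosome name.
#' @param start,end Interval bounds (0-based half-open).
#' @param positions 0-based site positions, strictly increasing.
#' @param dosages Individuals x sites matrix of dosages in \{0,1,2,NA\}.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix("chr1", 0, 100, c(10, 50),
#'                      matrix(c(0L, 2L, 1L, 1L), nrow = 2))
#' @export
GenotypeMatrix <- function(chrom, start, end, positions, dosages) {
  storage.mode(dosages) <- "integer"
  new("GenotypeMatrix", chrom = chrom, start = as.numeric(start),
      end = as.numeric(end), positions = as.numeric(positions),
      dosages = dosages)
}

#' RecombinationMap: per-interval crossover rates
#'
#' Non-overlapping genomic intervals with a per-bp per-generation crossover
#' probability each, sorted by chromosome and start.
#'
#' @slot map data.frame with columns chrom, start, end (0-based half-open)
#'   and rate (>= 0).
#' @export
setClass("RecombinationMap", representation(map = "data.frame"),
  validity = function(object) {
    m <- object@map
    if (!all(c("chrom", "start", "end", "rate") %in% names(m)))
      return("map needs columns chrom, start, end, rate")
    if (any(m$rate < 0)) return("rates must be >= 0")
    if (any(m$end <= m$start)) return("need start < end")
    for (ch in unique(m$chrom)) {
      sub <- m[m$chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
        return(paste0("overlapping intervals on ", ch))
    }
    TRUE
  })

#' Construct a RecombinationMap
#'
#' @param chrom,start,end,rate Vectors describing the map intervals
#'   (0-based half-open coordinates, rate in crossovers/bp/generation).
#' @return A [RecombinationMap-class] object sorted by chromosome and start.
#' @export
RecombinationMap <- function(chrom, start, end, rate) {
  m <- .windowFrame(chrom, start, end)
  m$rate <- as.numeric(rate)
  m <- m[order(m$chrom, m$start), , drop = FALSE]
  rownames(m) <- NULL
  new("RecombinationMap", map = m)
}

#' MaskProfile: per-window inaccessible intervals
#'
#' Records which sub-intervals of a window are masked (inaccessible or
#' low-quality) and the resulting masked fraction of the window length.
#'
#' @slot chrom,start,end The window (0-based half-open).
#' @slot masked Two-column matrix (start, end) of non-overlapping masked
#'   intervals inside the window.
#' @slot maskedFraction Total masked length / window length.
#' @export
setClass("MaskProfile",
  representation(chrom = "character", start = "numeric", end = "numeric",
                 masked = "matrix", maskedFraction = "numeric"),
  validity = function(object) {
    m <- object@masked
    if (ncol(m) != 2) return("masked must have two columns (start, end)")
    if (nrow(m) > 0) {
      if (any(m[, 1] < object@start) || any(m[, 2] > object@end))
        return("masked intervals must lie inside the window")
      if (any(m[, 2] <= m[, 1])) return("masked intervals need start < end")
      o <- order(m[, 1])
      if (nrow(m) > 1 && any(m[o, 1][-1] < m[o, 2][-nrow(m)]))
        return("masked intervals must not overlap")
    }
    f <- sum(m[, 2] - m[, 1]) / (object@end - object@start)
    if (abs(object@maskedFraction - f) > 1e-9)
      return("maskedFraction inconsistent with masked intervals")
    TRUE
  })

#' Construct a MaskProfile
#'
#' @param chrom,start,end The window (0-based half-open).
#' @param masked Two-column matrix of masked (start, end) intervals; may have
#'   zero rows.
#' @return A [MaskProfile-class]; the masked fraction is computed.
#' @export
MaskProfile <- function(chrom, start, end, masked = matrix(0, 0, 2)) {
  masked <- matrix(as.numeric(masked), ncol = 2)
  if (nrow(masked) > 0) masked <- masked[order(masked[, 1]), , drop = FALSE]
  f <- if (nrow(masked)) sum(masked[, 2] - masked[, 1]) / (end - start) else 0
  new("MaskProfile", chrom = chrom, start = as.numeric(start),
      end = as.numeric(end), masked = masked, maskedFraction = f)
}

#' DemographicModel: piecewise-constant effective population size
#'
#' Epochs are given as times in generations before present (the first must
#' be 0, i.e. the present-day epoch) with a diploid effective size each.
#'
#' @slot times Numeric vector of epoch start times (generations before
#'   present), strictly increasing, first element 0.
#' @slot sizes Diploid effective sizes (> 0), one per epoch.
#' @slot generationTime Generation time in years (default 0.067).
#' @export
setClass("DemographicModel",
  representation(times = "numeric", sizes = "numeric",
                 generationTime = "numeric"),
  validity = function(object) {
    if (length(object@times) != length(object@sizes))
      return("times and sizes must have equal length")
    if (length(object@times) == 0) return("need at least one epoch")
    if (object@times[1] != 0) return("first epoch must start at time 0")
    if (any(diff(object@times) <= 0))
      return("epoch times must be strictly increasing")
    if (any(object@sizes <= 0)) return("Ne must be > 0")
    TRUE
  })

#' Construct a DemographicModel
#'
#' @param times Epoch start times in generations before present (first = 0).
#' @param sizes Diploid effective population sizes per epoch.
#' @param generationTime Generation time in years.
#' @return A [DemographicModel-class] object.
#' @examples
#' DemographicModel(0, 2.5e5)                  # constant size
#' DemographicModel(c(0, 1e4), c(1e5, 1e6))    # recent bottleneck
#' @export
DemographicModel <- function(times, sizes, generationTime = 0.067) {
  new("DemographicModel", times = as.numeric(times), sizes = as.numeric(sizes),
      generationTime = generationTime)
}

#' SimPriors: prior distributions for simulated training replicates
#'
#' Bounds and shapes of the per-replicate parameter draws: mutation rate
#' uniform on \[muLow, muHigh\]; recombination rate exponential with mean
#' rMean truncated at rCapFactor * rMean; selection coefficient log-uniform
#' on \[sLow, sHigh\]; fixation time uniform on \[0, tauHigh\] (units of 4N
#' generations); initial selected-allele frequency for soft sweeps uniform on
#' \[0, f0High\].
#'
#' @slot muLow,muHigh Mutation-rate bounds (per bp per generation).
#' @slot rMean Mean of the exponential recombination-rate prior.
#' @slot rCapFactor Truncation multiplier for the recombination prior.
#' @slot sLow,sHigh Selection-coefficient bounds.
#' @slot tauHigh Upper bound of the fixation-time prior (coalescent units of
#'   4N generations).
#' @slot f0High Upper bound of the initial-frequency prior for soft sweeps.
#' @slot regionLength Simulated region length in bp.
#' @slot sampleSize Number of diploid individuals sampled.
#' @slot nSubwindows Number of adjacent subwindows (odd).
#' @export
setClass("SimPriors",
  representation(muLow = "numeric", muHigh = "numeric", rMean = "numeric",
                 rCapFactor = "numeric", sLow = "numeric", sHigh = "numeric",
                 tauHigh = "numeric", f0High = "numeric",
                 regionLength = "numeric", sampleSize = "numeric",
                 nSubwindows = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!(0 < object@muLow && object@muLow < object@muHigh))
      msg <- c(msg, "need 0 < muLow < muHigh")
    if (object@rMean <= 0) msg <- c(msg, "rMean must be > 0")
    if (object@rCapFactor <= 0) msg <- c(msg, "rCapFactor must be > 0")
    if (!(0 < object@sLow && object@sLow < object@sHigh))
      msg <- c(msg, "need 0 < sLow < sHigh")
    if (object@tauHigh <= 0) msg <- c(msg, "tauHigh must be > 0")
    if (!(0 < object@f0High && object@f0High <= 1))
      msg <- c(msg, "need 0 < f0High <= 1")
    if (object@regionLength <= 0) msg <- c(msg, "regionLength must be > 0")
    if (object@sampleSize < 2) msg <- c(msg, "sampleSize must be >= 2")
    if (object@nSubwindows %% 2 != 1)
      msg <- c(msg, "nSubwindows must be odd")
    if (length(msg)) msg else TRUE
  })

#' Construct a SimPriors object
#'
#' Defaults are the wide priors used for training at the full 2.75 Mb window
#' scale: mutation rate uniform on \[8.82e-10, 8.82e-9\] (mean 4.85e-9),
#' recombination rate exponential with mean 4.85e-9 truncated at three times
#' the mean, selection coefficient log-uniform on \[0.005, 0.05\], fixation
#' time uniform on \[0, 0.001\] (units of 4N generations), and soft-sweep
#' initial frequency uniform on \[0, 0.05\]. Use [rescaleForRegion()] to
#' adapt the selection prior to a shorter simulated region while preserving
#' the s/r ratio.
#'
#' @param muLow,muHigh,rMean,rCapFactor,sLow,sHigh,tauHigh,f0High See slots.
#' @param regionLength Region length in bp (default 2.75e6).
#' @param sampleSize Number of diploid individuals (default 20).
#' @param nSubwindows Number of subwindows (default 11).
#' @return A [SimPriors-class] object.
#' @export
SimPriors <- function(muLow = 8.82e-10, muHigh = 8.82e-9, rMean = 4.85e-9,
                      rCapFactor = 3, sLow = 0.005, sHigh = 0.05,
                      tauHigh = 0.001, f0High = 0.05, regionLength = 2.75e6,
                      sampleSize = 20, nSubwindows = 11) {
  new("SimPriors", muLow = muLow, muHigh = muHigh, rMean = rMean,
      rCapFactor = rCapFactor, sLow = sLow, sHigh = sHigh, tauHigh = tauHigh,
      f0High = f0High, regionLength = regionLength, sampleSize = sampleSize,
      nSubwindows = nSubwindows)
}

#' SimParams: drawn parameters of one simulation replicate
#'
#' @slot classLabel One of [sweepClasses()].
#' @slot mu,r Mutation and recombination rates (per bp per generation).
#' @slot s Selection coefficient (0 for neutral replicates).
#' @slot tau Fixation time in units of 4N generations (0 for neutral).
#' @slot f0 Initial selected-allele frequency (0 unless soft/soft-linked).
#' @slot sweepSubwindow 0-based subwindow index containing the selected site,
#'   or NA for neutral replicates.
#' @slot sweepPos Position of the selected site in bp, or NA.
#' @slot regionLength,sampleSize Region length (bp) and number of diploid
#'   individuals, copied from the priors the parameters were drawn under.
#' @slot seed Integer seed that reproduces the replicate.
#' @export
setClass("SimParams",
  representation(classLabel = "character", mu = "numeric", r = "numeric",
                 s = "numeric", tau = "numeric", f0 = "numeric",
                 sweepSubwindow = "numeric", sweepPos = "numeric",
                 regionLength = "numeric", sampleSize = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    cl <- object@classLabel
    if (!(cl %in% sweepClasses())) return("unknown class label")
    selected <- cl %in% .selectedClasses()
    if (selected && object@s <= 0)
      return("selected classes need s > 0")
    if (!selected && object@s != 0)
      return("neutral replicates need s == 0")
    soft <- cl %in% c("soft", "soft-linked")
    if (!soft && object@f0 != 0)
      return("f0 must be 0 unless the class is soft or soft-linked")
    if (selected && (is.na(object@sweepSubwindow) || is.na(object@sweepPos)))
      return("selected classes need sweepSubwindow and sweepPos")
    if (!selected && !(is.na(object@sweepSubwindow) && is.na(object@sweepPos)))
      return("neutral replicates must not carry a sweep location")
    TRUE
  })

#' LabeledReplicate: one simulated replicate with its label and mask
#'
#' @slot params The [SimParams-class] drawn for the replicate.
#' @slot genotypes The simulated [GenotypeMatrix-class] (after masking, when
#'   a mask was applied).
#' @slot mask The applied [MaskProfile-class], or NULL.
#' @export
setClass("LabeledReplicate",
  representation(params = "SimParams", genotypes = "GenotypeMatrix",
                 mask = "ANY"))

#' FeatureMatrix: the classifier input for one window
#'
#' Twelve row-normalized summary statistics by k subwindows. Every row is
#' nonnegative and sums to one (degenerate rows are the uniform row 1/k).
#'
#' @slot values 12 x k numeric matrix, rows named by statistic.
#' @slot chrom,start,end The featurized window (0-based half-open).
#' @slot maskedFraction Fraction of the window that was masked.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", chrom = "character", start = "numeric",
                 end = "numeric", maskedFraction = "numeric"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != 12) return("expected 12 statistic rows")
    if (any(!is.finite(v))) return("feature values must be finite")
    if (any(v < -1e-12)) return("feature rows must be nonnegative")
    rs <- rowSums(v)
    if (any(abs(rs - 1) > 1e-9)) return("feature rows must sum to 1")
    TRUE
  })

## ---- accessors -----------------------------------------------------------

#' @rdname GenotypeMatrix-class
#' @param object,x A GenotypeMatrix.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("positions", "GenotypeMatrix", function(x) x@positions)

#' Number of segregating sites / individuals
#' @param x A GenotypeMatrix.
#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSites", "GenotypeMatrix", function(x) length(x@positions))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nIndividuals", "GenotypeMatrix", function(x) nrow(x@dosages))

#' Masked fraction accessor
#' @param x A MaskProfile or FeatureMatrix.
#' @export
setGeneric("maskedFraction", function(x) standardGeneric("maskedFraction"))

#' @rdname maskedFraction
#' @export
setMethod("maskedFraction", "MaskProfile", function(x) x@maskedFraction)

#' @rdname maskedFraction
#' @export
setMethod("maskedFraction", "FeatureMatrix", function(x) x@maskedFraction)

#' Feature values accessor
#' @param x A FeatureMatrix.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' Epochs of a demographic model
#' @param x A DemographicModel.
#' @return data.frame with columns time (generations before present) and Ne.
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' @rdname epochs
#' @export
setMethod("epochs", "DemographicModel",
          function(x) data.frame(time = x@times, Ne = x@sizes))

#' Recombination map table accessor
#' @param x A RecombinationMap.
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))

#' @rdname mapTable
#' @export
setMethod("mapTable", "RecombinationMap", function(x) x@map)

#' Replicate parameter accessor
#' @param x A SimParams or LabeledReplicate.
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname classLabel
#' @export
setMethod("classLabel", "SimParams", function(x) x@classLabel)

#' @rdname classLabel
#' @export
setMethod("classLabel", "LabeledReplicate", function(x) x@params@classLabel)

#' @rdname LabeledReplicate-class
#' @param x A LabeledReplicate.
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))

#' @rdname LabeledReplicate-class
#' @export
setMethod("simParams", "LabeledReplicate", function(x) x@params)

#' @rdname LabeledReplicate-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname LabeledReplicate-class
#' @export
setMethod("genotypes", "LabeledReplicate", function(x) x@genotypes)

## ---- show methods --------------------------------------------------------

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix on ", object@chrom, ":", format(object@start + 1,
      big.mark = ","), "-", format(object@end, big.mark = ","), "\n",
      "  ", nrow(object@dosages), " individuals x ", length(object@positions),
      " segregating sites (", sum(is.na(object@dosages)),
      " missing genotypes)\n", sep = "")
})

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel with", length(object@times), "epoch(s):\n")
  print(epochs(object))
})

setMethod("show", "SimPriors", function(object) {
  cat("SimPriors: L=", object@regionLength, " bp, n=", object@sampleSize,
      " diploids, ", object@nSubwindows, " subwindows\n",
      "  mu ~ U(", object@muLow, ", ", object@muHigh, ")\n",
      "  r ~ Exp(mean=", object@rMean, ") truncated at ",
      object@rCapFactor, "x\n",
      "  s ~ log-U(", object@sLow, ", ", object@sHigh, ")",
      ", tau ~ U(0, ", object@tauHigh, "), f0 ~ U(0, ", object@f0High,
      ")\n", sep = "")
})

setMethod("show", "SimParams", function(object) {
  cat("SimParams [", object@classLabel, "] mu=", signif(object@mu, 4),
      " r=", signif(object@r, 4), " s=", signif(object@s, 4),
      " tau=", signif(object@tau, 4), " f0=", signif(object@f0, 4),
      " sweepPos=", object@sweepPos, " seed=", object@seed, "\n", sep = "")
})

setMethod("show", "LabeledReplicate", function(object) {
  cat("LabeledReplicate [", object@params@classLabel, "]: ",
      nSites(object@genotypes), " sites",
      if (!is.null(object@mask))
        paste0(", masked fraction ",
               signif(object@mask@maskedFraction, 3)) else "", "\n", sep = "")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix (12 x ", ncol(object@values), ") on ", object@chrom,
      ":", object@start + 1, "-", object@end, ", masked fraction ",
      signif(object@maskedFraction, 3), "\n", sep = "")
})

setMethod("show", "RecombinationMap", function(object) {
  cat("RecombinationMap with", nrow(object@map), "interval(s) on",
      length(unique(object@map$chrom)), "chromosome(s)\n")
})

setMethod("show", "MaskProfile", function(object) {
  cat("MaskProfile ", object@chrom, ":", object@start + 1, "-", object@end,
      " with ", nrow(object@masked), " masked interval(s), fraction ",
      signif(object@maskedFraction, 3), "\n", sep = "")
})
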