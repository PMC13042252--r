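#' @import methods
#' @importFrom stats cor runif rnorm sd setNames quantile
#' @importFrom utils read.table write.table head tail
NULL

#' Class labels used throughout the package
#'
#' Returns the canonical ordering of the five window classes: fully neutral,
#' linked to a hard sweep, linked to a soft sweep, hard sweep, soft sweep.
#' Posterior vectors and confusion matrices use this ordering.
#'
#' @return Character vector of length 5.
#' @export
sweepClasses <- function() {
  c("neutral", "hard-linked", "soft-linked", "hard", "soft")
}

## internal: which classes are sweeps / selected at all
.sweepClassIdx <- function() c(4L, 5L)
.selectedClasses <- function() c("hard", "hard-linked", "soft", "soft-linked")

#' Coordinate conversions
#'
#' Internally all intervals are 0-based, half-open. VCF positions are
#' 1-based; BED intervals are already 0-based half-open; reported tables use
#' 1-based inclusive coordinates. These helpers convert between the internal
#' convention and the 1-based inclusive reporting convention and are exact
#' inverses of each other.
#'
#' @param start,end Interval bounds (numeric vectors of equal length).
#' @return A two-column matrix with converted `start` and `end`.
#' @export
toOneBased <- function(start, end) {
  cbind(start = start + 1, end = end)
}

#' @rdname toOneBased
#' @export
fromOneBased <- function(start, end) {
  cbind(start = start - 1, end = end)
}

## internal: validate a chrom/start/end window triple (0-based half-open)
.checkInterval <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("'chrom' must be a nonempty string")
  if (!(start >= 0 && start < end))
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  invisible(TRUE)
}

## internal: windows data.frame constructor/validator
.windowFrame <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), stringsAsFactors = FALSE)
}

## internal: convert 0-based half-open window frame to GRanges (1-based closed)
.asGRanges <- function(windows) {
  GenomicRanges::GRanges(
    seqnames = windows$chrom,
    ranges = IRanges::IRanges(start = windows$start + 1, end = windows$end))
}

## internal: merge overlapping/adjacent intervals (single chromosome),
## returning a sorted non-overlapping (start, end) matrix
.mergeIntervals <- function(start, end) {
  if (length(start) == 0) return(matrix(0, 0, 2))
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1, end = end))
  cbind(IRanges::start(ir) - 1, IRanges::end(ir))
}

## internal: derive a vector of child seeds from one master seed.  Uses R's
## RNG stream so that any replicate is reproducible in isolation from its
## stored seed; all seeds are < 2^31 as required by the python backend.
.deriveSeeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

## internal: run a block under a local RNG seed without disturbing the
## caller's RNG state
.withSeed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  expr
}
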