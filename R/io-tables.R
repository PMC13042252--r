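## Plain-text readers and writers for the tabular formats around the scan:
## recombination maps and demographic histories (TSV), accessibility masks
## and gene annotations (BED, via rtracklayer), gene-to-GO maps, and the
## scan output table.  Internal coordinates are 0-based half-open; BED is
## natively so; scan tables are written 1-based inclusive.

#' Read a recombination map TSV
#'
#' Expects a header line `chrom start end rate` with 0-based half-open
#' intervals and per-bp per-generation crossover rates. Intervals are sorted
#' on read; overlapping intervals or negative rates are rejected.
#'
#' @param path Path to the TSV.
#' @return A [RecombinationMap-class].
#' @export
readRecombMap <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "rate")
  if (!all(need %in% names(tab)))
    stop("recombination map needs columns: ", paste(need, collapse = ", "))
  RecombinationMap(tab$chrom, tab$start, tab$end, tab$rate)
}

#' Write a recombination map TSV
#' @param map A [RecombinationMap-class].
#' @param path Output path.
#' @export
writeRecombMap <- function(map, path) {
  write.table(mapTable(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a piecewise-constant demographic history TSV
#'
#' Expects a header line `time_generations Ne`: epoch start times in
#' generations before present (first row must be 0) and diploid effective
#' sizes. Nonmonotone times or nonpositive sizes are rejected.
#'
#' @param path Path to the TSV.
#' @param generationTime Generation time in years (default 0.067).
#' @return A [DemographicModel-class].
#' @export
readDemography <- function(path, generationTime = 0.067) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("time_generations", "Ne")
  if (!all(need %in% names(tab)))
    stop("demography needs columns: ", paste(need, collapse = ", "))
  DemographicModel(tab$time_generations, tab$Ne, generationTime)
}

#' Write a demographic history TSV
#' @param model A [DemographicModel-class].
#' @param path Output path.
#' @export
writeDemography <- function(model, path) {
  write.table(data.frame(time_generations = model@times, Ne = model@sizes),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Returns the intervals in the internal 0-based half-open convention
#' (BED's native convention). A fourth column, when present, is returned as
#' `name`.
#'
#' @param path Path to the BED file.
#' @return data.frame with columns chrom, start, end (and name).
#' @export
readBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- .windowFrame(as.character(GenomicRanges::seqnames(gr)),
                      GenomicRanges::start(gr) - 1,
                      GenomicRanges::end(gr))
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write intervals to a BED file
#' @param windows data.frame with chrom, start, end (0-based half-open) and
#'   optionally name.
#' @param path Output path.
#' @export
writeBed <- function(windows, path) {
  gr <- .asGRanges(windows)
  if (!is.null(windows$name)) gr$name <- windows$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a gene-to-GO-term map
#'
#' Expects a header line `gene_id term`; one row per (gene, term)
#' assignment.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns gene_id and term.
#' @export
readGoMap <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term") %in% names(tab)))
    stop("GO map needs columns gene_id and term")
  tab
}

#' Read a gene list (one id per line)
#' @param path Path to the text file.
#' @return Character vector of gene ids.
#' @export
readGeneList <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}

## columns of a scan table, in output order
.scanTableCols <- function() {
  c("chrom", "start", "end", "predicted_class", "prob_neutral",
    "prob_hard_linked", "prob_soft_linked", "prob_hard", "prob_soft",
    "combined_sweep_prob", "q_value")
}

#' Write a scan table
#'
#' Writes one row per classified window with its five-class posterior,
#' decision and q-value. Coordinates are converted to the 1-based inclusive
#' reporting convention; probabilities are printed with full precision.
#'
#' @param calls data.frame of sweep calls (internal 0-based half-open
#'   coordinates) with the columns listed in the details.
#' @param path Output path.
#' @export
writeScanTable <- function(calls, path) {
  if (!is.data.frame(calls) || nrow(calls) == 0)
    stop("'calls' must be a nonempty data.frame")
  need <- setdiff(.scanTableCols(), "q_value")
  if (!all(need %in% names(calls)))
    stop("missing scan table columns: ",
         paste(setdiff(need, names(calls)), collapse = ", "))
  out <- calls[, intersect(.scanTableCols(), names(calls)), drop = FALSE]
  conv <- toOneBased(out$start, out$end)
  out$start <- conv[, "start"]
  out$end <- conv[, "end"]
  if (is.null(out$q_value)) out$q_value <- NA_real_
  for (cl in names(out))
    if (is.numeric(out[[cl]]))
      out[[cl]] <- format(out[[cl]], digits = 15, scientific = FALSE,
                          trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scan table written by [writeScanTable()]
#'
#' @param path Path to the TSV.
#' @return data.frame of calls in internal 0-based half-open coordinates.
#' @export
readScanTable <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  conv <- fromOneBased(tab$start, tab$end)
  tab$start <- conv[, "start"]
  tab$end <- conv[, "end"]
  tab
}
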