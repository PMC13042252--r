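## Bridge to the coalescent simulation backend (msprime, via the bundled
## python script inst/python/sweep_sim.py).  Replicates are simulated in
## batches through a manifest file; each replicate is fully determined by
## its stored seed, so any single one can be reproduced in isolation.

.pythonBin <- function() Sys.getenv("SWEEPSCAN_PYTHON", "python")

.simBackendScript <- function() {
  p <- system.file("python", "sweep_sim.py", package = "sweepscan")
  if (!nzchar(p)) stop("simulation backend script not found")
  p
}

## internal: manifest row for one SimParams
.manifestRow <- function(id, p) {
  data.frame(id = id, seed = format(p@seed, scientific = FALSE),
             class = p@classLabel, mu = p@mu, r = p@r, s = p@s, tau = p@tau,
             f0 = p@f0,
             sweep_pos = ifelse(is.na(p@sweepPos), 0, p@sweepPos),
             L = p@regionLength, n = p@sampleSize,
             stringsAsFactors = FALSE)
}

## internal: parse the backend's block output into GenotypeMatrix objects,
## in manifest order.  Errors carry the failing replicate's parameters.
.parseSimOutput <- function(path, paramsList) {
  lines <- readLines(path)
  out <- vector("list", length(paramsList))
  names(out) <- names(paramsList)
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[i]
    if (startsWith(line, "!")) {
      id <- sub("^!(\\S+).*$", "\\1", line)
      stop("simulation failed for replicate ", id, " (",
           sub("^!\\S+\\s*", "", line), "); params: ",
           paste(utils::capture.output(show(paramsList[[id]])),
                 collapse = " "))
    }
    if (!startsWith(line, ">")) stop("malformed backend output at line ", i)
    hdr <- strsplit(sub("^>", "", line), " ", fixed = TRUE)[[1]]
    id <- hdr[1]
    S <- as.integer(hdr[2])
    p <- paramsList[[id]]
    n <- p@sampleSize
    pos <- if (S > 0)
      as.numeric(strsplit(lines[i + 1L], " ", fixed = TRUE)[[1]])
    else numeric(0)
    dos <- matrix(0L, nrow = n, ncol = S)
    if (S > 0) {
      for (j in seq_len(n))
        dos[j, ] <- utf8ToInt(lines[i + 1L + j]) - 48L
    }
    out[[id]] <- GenotypeMatrix("sim", 0, p@regionLength, pos, dos)
    i <- i + 2L + n
  }
  if (any(vapply(out, is.null, logical(1))))
    stop("backend output missing replicates: ",
         paste(names(out)[vapply(out, is.null, logical(1))], collapse = ", "))
  out
}

## internal: simulate a batch of replicates sharing one demography
.simulateBatch <- function(paramsList, demography) {
  if (length(paramsList) == 0) return(list())
  if (is.null(names(paramsList)))
    names(paramsList) <- paste0("r", seq_along(paramsList))
  td <- tempfile("sweepsim")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  manifest <- do.call(rbind, Map(.manifestRow, names(paramsList), paramsList))
  mpath <- file.path(td, "manifest.tsv")
  dpath <- file.path(td, "demography.tsv")
  opath <- file.path(td, "out.txt")
  write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  writeDemography(demography, dpath)
  status <- system2(.pythonBin(),
                    c(.simBackendScript(), "--manifest", mpath,
                      "--demography", dpath, "--out", opath),
                    stdout = FALSE, stderr = "")
  if (!file.exists(opath))
    stop("simulation backend produced no output (exit status ", status, ")")
  .parseSimOutput(opath, paramsList)
}

#' Simulate one labeled replicate
#'
#' Runs the coalescent engine for one set of drawn parameters under a
#' piecewise-constant demography. Neutral replicates use the neutral
#' coalescent with recombination; hard sweeps condition on a beneficial
#' mutation at `sweepPos` with coefficient `s` fixing `tau` (units of 4*N0
#' generations) before sampling; soft sweeps start the selected phase from
#' standing frequency `f0`. Haplotypes are paired into unphased diploid
#' dosages. Fixed seeds give identical matrices on repeated calls.
#'
#' @param params A [SimParams-class].
#' @param demography A [DemographicModel-class].
#' @return A [GenotypeMatrix-class] over \[0, regionLength).
#' @export
simulateReplicate <- function(params, demography) {
  .simulateBatch(list(r1 = params), demography)[["r1"]]
}
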