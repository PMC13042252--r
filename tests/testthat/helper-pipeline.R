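## Heavy shared state for the pipeline-level tests: the reference
## classifier experiment and the fixture-genome scan are each run once per
## test session and reused across test blocks.

.pipelineCache <- new.env(parent = emptyenv())

referenceRun <- function() {
  if (is.null(.pipelineCache$run))
    .pipelineCache$run <- runReferenceExperiment(seed = 1)
  .pipelineCache$run
}

## full fixture-genome scan with the reference classifier: generate the
## synthetic genome, apply both data-quality filters, classify every
## retained window at the 0.80 threshold and attach q-values from the
## simulation null.
fixtureScanRun <- function() {
  if (!is.null(.pipelineCache$scan)) return(.pipelineCache$scan)
  ref <- referenceRun()
  design <- deskScaleDesign()
  cfg <- fixtureGenomeConfig(priors = design$priors,
                             demography = design$demography)
  fx <- makeFixtureGenome(cfg, seed = 2, outDir = tempfile("fxgenome"))
  W <- design$priors@regionLength
  k <- design$priors@nSubwindows
  gms <- lapply(names(cfg$chromLengths), function(ch)
    readVcfWindow(fx$paths[["vcf"]], ch, 0, cfg$chromLengths[[ch]]))
  names(gms) <- names(cfg$chromLengths)
  map <- readRecombMap(fx$paths[["recomb"]])
  maskBed <- readBed(fx$paths[["mask"]])
  wins <- enumerateWindows(cfg$chromLengths, W, W / k, k)
  kept <- filterWindows(wins, map, maskBed)
  calls <- classifyGenome(gms, ref$models, kept, maskBed = maskBed,
                          threshold = 0.80, k = k)
  isSweep <- calls$decision %in% c("sweep-hard", "sweep-soft")
  calls$q_value <- NA_real_
  if (any(isSweep))
    calls$q_value[isSweep] <- sweepQvalues(
      calls$combined_sweep_prob[isSweep], calls$combined_sweep_prob,
      ref$nullProbs, nrow(calls))
  .pipelineCache$scan <- list(fixture = fx, windows = wins, kept = kept,
                              calls = calls,
                              filterCounts = attr(kept, "filterCounts"))
  .pipelineCache$scan
}
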