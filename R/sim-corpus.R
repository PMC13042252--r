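## Corpus construction: the labeled simulation set the classifier learns
## from.  For each sweep type, nPerSubwindow replicates are simulated with
## the selected site placed uniformly within each of the k subwindows;
## replicates whose sweep sits in the central subwindow are labeled
## hard/soft, all others hard-linked/soft-linked, and sweep-free replicates
## neutral.

#' Build a labeled simulation corpus
#'
#' Simulates, per sweep type (hard, soft), `nPerSubwindow` replicates for
#' each of the `nSubwindows` subwindow placements, plus `nNeutral` neutral
#' replicates. Class labels follow from the sweep placement alone. When a
#' mask library is supplied, every replicate inherits the masked intervals
#' of one randomly chosen profile.
#'
#' @param priors A [SimPriors-class].
#' @param demography A [DemographicModel-class].
#' @param nPerSubwindow Replicates per (sweep type, subwindow) cell.
#' @param maskLibrary Optional list of [MaskProfile-class] objects.
#' @param seed Master seed; per-replicate engine seeds are derived from it
#'   so the corpus is fully reproducible.
#' @param nNeutral Number of neutral replicates (default `nPerSubwindow`,
#'   which at reduced scale keeps the neutral pool the size of the
#'   hard/soft pools).
#' @param nPerFlankSubwindow Replicates per non-central subwindow cell
#'   (default `nPerSubwindow`). Because the linked-class pools are
#'   (k-1)-fold larger than the hard/soft pools and are subsampled to the
#'   per-class target anyway, reduced-scale corpora may simulate fewer
#'   replicates per flank cell; placement remains uniform over the flank
#'   subwindows, so the linked-class distribution is unchanged.
#' @return List of [LabeledReplicate-class] objects. Class pool sizes:
#'   nPerSubwindow each for hard and soft, (k-1)*nPerFlankSubwindow each
#'   for the linked classes, nNeutral for neutral.
#' @export
buildCorpus <- function(priors, demography, nPerSubwindow, maskLibrary = NULL,
                        seed = 1, nNeutral = nPerSubwindow,
                        nPerFlankSubwindow = nPerSubwindow) {
  k <- priors@nSubwindows
  central <- (k - 1) / 2
  .withSeed(seed, {
    spec <- list()
    for (type in c("hard", "soft")) {
      for (sw in seq_len(k) - 1) {
        lbl <- if (sw == central) type else paste0(type, "-linked")
        nCell <- if (sw == central) nPerSubwindow else nPerFlankSubwindow
        spec <- c(spec, rep(list(list(label = lbl, sw = sw)), nCell))
      }
    }
    spec <- c(spec, rep(list(list(label = "neutral", sw = NA)), nNeutral))
    seeds <- sample.int(.Machine$integer.max - 1L, length(spec))
    paramsList <- lapply(seq_along(spec), function(i)
      drawSimParams(spec[[i]]$label, spec[[i]]$sw, priors, seed = seeds[i]))
    names(paramsList) <- sprintf("rep%05d", seq_along(paramsList))
    gms <- .simulateBatch(paramsList, demography)
    lapply(names(paramsList), function(id) {
      rep <- new("LabeledReplicate", params = paramsList[[id]],
                 genotypes = gms[[id]], mask = NULL)
      if (!is.null(maskLibrary))
        rep <- applyMaskTransfer(rep, maskLibrary)
      rep
    })
  })
}

#' Split a corpus into balanced, disjoint train and test sets
#'
#' Samples, per class and without replacement, `nTrainPerClass` training
#' and `nTestPerClass` test replicates (the linked-class pools, which are
#' roughly (k-1) times larger than the hard/soft pools, are subsampled like
#' the others). Train and test are disjoint by construction.
#'
#' @param corpus List of [LabeledReplicate-class] objects (or any list whose
#'   elements respond to [classLabel()]).
#' @param nTrainPerClass,nTestPerClass Per-class sizes.
#' @param seed Seed for the subsampling.
#' @return List with elements `train` and `test` (sub-lists of `corpus`)
#'   and `trainIdx`/`testIdx` (indices into `corpus`).
#' @export
assembleTrainTest <- function(corpus, nTrainPerClass, nTestPerClass,
                              seed = 1) {
  labels <- vapply(corpus, classLabel, character(1))
  need <- nTrainPerClass + nTestPerClass
  .withSeed(seed, {
    trainIdx <- integer(0)
    testIdx <- integer(0)
    for (cl in sweepClasses()) {
      pool <- which(labels == cl)
      if (length(pool) < need)
        stop("class '", cl, "' has only ", length(pool),
             " replicates; need ", need)
      pick <- sample(pool, need)
      trainIdx <- c(trainIdx, pick[seq_len(nTrainPerClass)])
      testIdx <- c(testIdx, pick[nTrainPerClass + seq_len(nTestPerClass)])
    }
    list(train = corpus[trainIdx], test = corpus[testIdx],
         trainIdx = trainIdx, testIdx = testIdx)
  })
}

#' Corpus manifest table
#'
#' One row per replicate with its label and all drawn parameters, e.g. for
#' serialization alongside a feature archive.
#'
#' @param corpus List of [LabeledReplicate-class] objects.
#' @return data.frame.
#' @export
corpusManifest <- function(corpus) {
  do.call(rbind, lapply(seq_along(corpus), function(i) {
    p <- simParams(corpus[[i]])
    data.frame(replicate = i, class = p@classLabel, mu = p@mu, r = p@r,
               s = p@s, tau = p@tau, f0 = p@f0,
               sweep_subwindow = p@sweepSubwindow, sweep_pos = p@sweepPos,
               seed = p@seed,
               masked_fraction = if (is.null(corpus[[i]]@mask)) 0
                                 else corpus[[i]]@mask@maskedFraction)
  }))
}
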