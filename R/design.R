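## The package's scaled-down reference experiment: the fixed study design
## used by the test suite and by scripts/acceptance.R to measure classifier
## performance from scratch.  Kept in one place so every consumer runs the
## same conditions.

#' Scaled-down reference experiment design
#'
#' Returns the fixed design of the package's desk-scale classifier
#' experiment: the full-scale priors rescaled to 110 kb windows (11 x 10 kb
#' subwindows) via [rescaleForRegion()], 20 diploid individuals, a constant
#' effective population size of 5e5 (within the 1e5-1e6 range typical of
#' large mosquito populations; the regime without a strong recent
#' bottleneck), pools of 600 replicates per class (60 per flank subwindow
#' for the linked classes), and a balanced 500/100 per-class train/test
#' split — about a fifth of the full-scale 2,700 training examples per
#' class, with a third of the full-scale test size so the test metrics are
#' measured with usefully small error.
#'
#' @return List with `priors`, `demography`, `nPerSubwindow`,
#'   `nPerFlankSubwindow`, `nTrainPerClass`, `nTestPerClass` and
#'   `nModels` (ensemble size).
#' @export
deskScaleDesign <- function() {
  list(priors = rescaleForRegion(SimPriors(sampleSize = 20), 1.1e5),
       demography = DemographicModel(0, 5e5),
       nPerSubwindow = 600,
       nPerFlankSubwindow = 60,
       nTrainPerClass = 500,
       nTestPerClass = 100,
       nModels = 3)
}

#' Run the reference classifier experiment
#'
#' Simulates the corpus of [deskScaleDesign()], assembles the balanced
#' train/test split, trains the classifier and evaluates it on the held-out
#' test set: binary sweep-vs-unselected ROC/PR summaries and the neutral
#' misclassification rates with no threshold and at the 0.80
#' combined-probability threshold.
#'
#' @param seed Master seed driving simulation, splitting and training.
#' @param design Design list (default [deskScaleDesign()]).
#' @return List with `models` (the classifier ensemble; posteriors are the
#'   member average), `model` (first member), `curves`, `posteriors`,
#'   `labels`, `neutralArgmaxPct`, `neutralAt80Pct`, `nTest`, and the
#'   test-set neutral combined sweep probabilities (`nullProbs`, the
#'   simulation null used for q-values).
#' @export
runReferenceExperiment <- function(seed = 1, design = deskScaleDesign()) {
  nModels <- if (is.null(design$nModels)) 1L else design$nModels
  seeds <- .deriveSeeds(seed, 2 + nModels)
  corpus <- buildCorpus(design$priors, design$demography,
                        design$nPerSubwindow, seed = seeds[1],
                        nPerFlankSubwindow = design$nPerFlankSubwindow)
  split <- assembleTrainTest(corpus, design$nTrainPerClass,
                             design$nTestPerClass, seed = seeds[2])
  rm(corpus)
  ftr <- featureTable(split$train)
  fte <- featureTable(split$test)
  models <- lapply(seq_len(nModels), function(i)
    trainSweepClassifier(ftr$features, ftr$labels, seed = seeds[2 + i]))
  post <- predictPosterior(models, fte$features)
  curves <- binarySweepCurves(post, fte$labels)
  amax <- sweepClasses()[max.col(post, ties.method = "first")]
  combined <- post[, "hard"] + post[, "soft"]
  neu <- fte$labels == "neutral"
  list(models = models, model = models[[1]], curves = curves,
       posteriors = post, labels = fte$labels,
       neutralArgmaxPct = 100 * mean(amax[neu] %in% c("hard", "soft")),
       neutralAt80Pct = 100 * mean(amax[neu] %in% c("hard", "soft") &
                                     combined[neu] >= 0.80),
       nTest = nrow(post),
       nullProbs = combined[neu])
}
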