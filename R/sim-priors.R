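## Parameter draws for the simulated training corpus.  The priors are wide
## by design: training examples should span the mutation/recombination
## heterogeneity of the genome and a broad range of sweep strengths and
## ages, so that the classifier does not overfit a narrow parameter regime.

#' Draw one replicate's simulation parameters from the priors
#'
#' Draws mu uniformly, r from a truncated exponential (rejection until
#' r <= rCapFactor * rMean; the realized mean is therefore somewhat below
#' rMean), and — for selected classes — s log-uniformly, tau uniformly on
#' \[0, tauHigh\] and, for soft classes, f0 uniformly on \[0, f0High\]. The
#' selected site is placed uniformly within the designated subwindow.
#'
#' @param classLabel One of [sweepClasses()].
#' @param sweepSubwindow 0-based subwindow index in \[0, nSubwindows) for
#'   selected classes; NA for neutral. The label must be consistent with the
#'   index: the central subwindow for "hard"/"soft", any other for the
#'   linked classes.
#' @param priors A [SimPriors-class].
#' @param seed Optional integer seed stored on the result so that the
#'   replicate can be re-simulated in isolation; drawn from the current RNG
#'   stream when omitted.
#' @return A [SimParams-class].
#' @export
drawSimParams <- function(classLabel, sweepSubwindow = NA, priors, seed = NULL) {
  classLabel <- match.arg(classLabel, sweepClasses())
  k <- priors@nSubwindows
  central <- (k - 1) / 2
  selected <- classLabel %in% .selectedClasses()
  if (!selected) {
    if (!is.na(sweepSubwindow))
      stop("neutral replicates take no sweep subwindow")
  } else {
    if (is.na(sweepSubwindow) || sweepSubwindow < 0 || sweepSubwindow >= k)
      stop("sweepSubwindow must be in [0, ", k, ") for class ", classLabel)
    isCentral <- sweepSubwindow == central
    wantCentral <- classLabel %in% c("hard", "soft")
    if (isCentral != wantCentral)
      stop("class ", classLabel, " inconsistent with subwindow ",
           sweepSubwindow, " (central index ", central, ")")
  }
  mu <- runif(1, priors@muLow, priors@muHigh)
  repeat {
    r <- stats::rexp(1, rate = 1 / priors@rMean)
    if (r <= priors@rCapFactor * priors@rMean) break
  }
  if (selected) {
    s <- exp(runif(1, log(priors@sLow), log(priors@sHigh)))
    tau <- runif(1, 0, priors@tauHigh)
    f0 <- if (classLabel %in% c("soft", "soft-linked"))
      runif(1, 0, priors@f0High) else 0
    w <- priors@regionLength / k
    sweepPos <- runif(1, sweepSubwindow * w, (sweepSubwindow + 1) * w)
  } else {
    s <- 0; tau <- 0; f0 <- 0; sweepPos <- NA_real_
    sweepSubwindow <- NA_real_
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  new("SimParams", classLabel = classLabel, mu = mu, r = r, s = s, tau = tau,
      f0 = f0, sweepSubwindow = as.numeric(sweepSubwindow),
      sweepPos = sweepPos, regionLength = priors@regionLength,
      sampleSize = priors@sampleSize, seed = as.numeric(seed))
}

#' Rescale the selection prior for a different region length
#'
#' Multiplies the selection-coefficient bounds by `newL / regionLength` and
#' replaces the region length, leaving every other prior unchanged. Sweeps
#' simulated under the rescaled priors have the same s/r ratio — hence the
#' same sweep footprint relative to the window — as full-length simulations,
#' which makes shorter (cheaper) regions usable for training. The rescaled
#' prior remains log-uniform.
#'
#' @param priors A [SimPriors-class].
#' @param newL New region length in bp.
#' @return A [SimPriors-class] with rescaled selection bounds.
#' @examples
#' p <- SimPriors()                       # L = 2.75 Mb, s in [0.005, 0.05]
#' rescaleForRegion(p, 5.5e5)             # s in [0.001, 0.01]
#' @export
rescaleForRegion <- function(priors, newL) {
  if (newL <= 0) stop("newL must be > 0")
  f <- newL / priors@regionLength
  SimPriors(muLow = priors@muLow, muHigh = priors@muHigh,
            rMean = priors@rMean, rCapFactor = priors@rCapFactor,
            sLow = priors@sLow * f, sHigh = priors@sHigh * f,
            tauHigh = priors@tauHigh, f0High = priors@f0High,
            regionLength = newL, sampleSize = priors@sampleSize,
            nSubwindows = priors@nSubwindows)
}
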