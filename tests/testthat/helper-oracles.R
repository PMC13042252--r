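## Independent brute-force oracles used to validate the package's
## statistics.  These deliberately re-derive each quantity from first
## principles (explicit enumeration over allele pairs, site pairs or score
## ranks) and share no code with the implementation.

## random genotype matrix, optionally with missing genotypes
randomGenotypeMatrix <- function(nInd, nSites, missFrac = 0, len = 1000) {
  repeat {
    d <- matrix(sample(0:2, nInd * nSites, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)),
                nInd, nSites)
    if (missFrac > 0)
      d[runif(length(d)) < missFrac] <- NA
    keep <- colSums(!is.na(d)) > 0
    d <- d[, keep, drop = FALSE]
    if (ncol(d) > 0 || nSites == 0) break
  }
  pos <- sort(sample(0:(len - 1), ncol(d)))
  storage.mode(d) <- "integer"
  GenotypeMatrix("chrT", 0, len, pos, d)
}

## pi by explicit enumeration over all pairs of (haploid) alleles per site
oraclePi <- function(gm) {
  d <- dosages(gm)
  total <- 0
  for (j in seq_len(ncol(d))) {
    g <- d[, j]
    g <- g[!is.na(g)]
    alleles <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
    m <- length(alleles)
    if (m < 2) next
    diffs <- 0
    for (a in seq_len(m - 1))
      for (b in seq(a + 1, m))
        diffs <- diffs + (alleles[a] != alleles[b])
    total <- total + diffs / choose(m, 2)
  }
  total
}

## Tajima's D re-derived independently (constants spelled out, pi from the
## brute-force oracle above)
oracleTajimaD <- function(gm) {
  d <- dosages(gm)
  mcounts <- 2 * colSums(!is.na(d))
  if (ncol(d) == 0) return(0)
  n <- as.numeric(names(sort(table(mcounts), decreasing = TRUE))[1])
  alt <- colSums(d, na.rm = TRUE)
  S <- sum(alt > 0 & alt < mcounts)
  if (S == 0 || n < 3) return(0)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(0)
  (oraclePi(gm) - S / a1) / sqrt(v)
}

## pairwise-complete squared correlation, by hand
oracleR2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(0)
  vx <- mean(x^2) - mean(x)^2
  vy <- mean(y^2) - mean(y)^2
  if (vx == 0 || vy == 0) return(0)
  ((mean(x * y) - mean(x) * mean(y))^2) / (vx * vy)
}

## Zns by explicit double loop over site pairs
oracleZns <- function(gm) {
  d <- dosages(gm)
  S <- ncol(d)
  if (S < 2) return(0)
  tot <- 0
  for (i in seq_len(S - 1))
    for (j in seq(i + 1, S))
      tot <- tot + oracleR2(d[, i], d[, j])
  tot / choose(S, 2)
}

## omega by direct evaluation of the definition at every split
oracleOmegaMax <- function(gm, minSplit = 3) {
  d <- dosages(gm)
  S <- ncol(d)
  if (S < 2 * minSplit) return(0)
  best <- 0
  found <- FALSE
  for (l in minSplit:(S - minSplit)) {
    wl <- 0; wr <- 0; ac <- 0
    for (i in seq_len(S - 1)) {
      for (j in seq(i + 1, S)) {
        r2 <- oracleR2(d[, i], d[, j])
        if (j <= l) wl <- wl + r2
        else if (i > l) wr <- wr + r2
        else ac <- ac + r2
      }
    }
    if (ac == 0) next
    om <- ((wl + wr) / (choose(l, 2) + choose(S - l, 2))) /
      (ac / (l * (S - l)))
    if (!found || om > best) { best <- om; found <- TRUE }
  }
  if (found) best else 0
}

## AUC as the Mann-Whitney U statistic over all (positive, negative) pairs
oracleAucMannWhitney <- function(score, positive) {
  sp <- score[positive]; sn <- score[!positive]
  tot <- 0
  for (a in sp)
    for (b in sn)
      tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

## small labeled corpus without simulation (for bookkeeping tests): all
## replicates share one tiny genotype matrix
placeholderCorpus <- function(poolSizes) {
  gm <- GenotypeMatrix("chrT", 0, 100, c(10, 20),
                       matrix(c(0L, 1L, 2L, 1L), nrow = 2))
  protos <- list(
    neutral = drawSimParams("neutral", NA, SimPriors(), seed = 1),
    "hard" = drawSimParams("hard", 5, SimPriors(), seed = 2),
    "hard-linked" = drawSimParams("hard-linked", 0, SimPriors(), seed = 3),
    "soft" = drawSimParams("soft", 5, SimPriors(), seed = 4),
    "soft-linked" = drawSimParams("soft-linked", 0, SimPriors(), seed = 5))
  out <- list()
  for (cl in names(poolSizes)) {
    rep <- new("LabeledReplicate", params = protos[[cl]], genotypes = gm,
               mask = NULL)
    out <- c(out, rep(list(rep), poolSizes[[cl]]))
  }
  out
}

## quickly trained classifier on well-separated synthetic features (for
## scan tests that just need a deterministic model)
syntheticModel <- function(seed = 1, nPer = 40) {
  set.seed(seed)
  classes <- sweepClasses()
  X <- NULL; y <- character(0)
  for (ci in seq_along(classes)) {
    base <- matrix(1 / 11, nPer, 132)
    shift <- matrix(0, nPer, 132)
    shift[, ((ci - 1) * 22 + 1):(ci * 22)] <- 0.05
    X <- rbind(X, base + shift + matrix(rnorm(nPer * 132, sd = 0.005),
                                        nPer, 132))
    y <- c(y, rep(classes[ci], nPer))
  }
  trainSweepClassifier(X, y, epochs = 40, seed = seed)
}
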