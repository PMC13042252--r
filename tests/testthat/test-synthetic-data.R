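test_that("prior draws respect bounds and the stated moments", {
  pri <- SimPriors()
  set.seed(31)
  mus <- replicate(10000, drawSimParams("neutral", NA, pri, seed = 1)@mu)
  ## mean of the uniform mutation-rate prior, within 3 standard errors
  se <- sd(mus) / sqrt(length(mus))
  expect_lt(abs(mean(mus) - (pri@muLow + pri@muHigh) / 2), 3 * se)
  expect_lt(abs(mean(mus) - 4.85e-9), 3 * se + 1e-12)
  expect_true(all(mus >= pri@muLow & mus <= pri@muHigh))

  rs <- replicate(10000, drawSimParams("neutral", NA, pri, seed = 1)@r)
  expect_true(all(rs <= 3 * pri@rMean))          # truncation at 3x the mean
  expect_true(all(rs >= 0))
  ## truncation pulls the realized mean below the exponential mean
  expect_lt(mean(rs), pri@rMean)

  draws <- replicate(2000, {
    p <- drawSimParams("soft", 5, pri, seed = 1)
    c(p@s, p@tau, p@f0, p@sweepPos)
  })
  expect_true(all(draws[1, ] >= pri@sLow & draws[1, ] <= pri@sHigh))
  expect_true(all(draws[2, ] >= 0 & draws[2, ] <= pri@tauHigh))
  expect_true(all(draws[3, ] >= 0 & draws[3, ] <= pri@f0High))
  ## sweep position confined to the designated (central) subwindow
  w <- pri@regionLength / pri@nSubwindows
  expect_true(all(draws[4, ] >= 5 * w & draws[4, ] < 6 * w))
})

test_that("neutral draws carry no selection parameters", {
  p <- drawSimParams("neutral", NA, SimPriors(), seed = 5)
  expect_equal(p@s, 0)
  expect_equal(p@f0, 0)
  expect_true(is.na(p@sweepPos))
  expect_true(is.na(p@sweepSubwindow))
})

test_that("invalid class/subwindow combinations are rejected", {
  pri <- SimPriors()
  expect_error(drawSimParams("hard", 0, pri), "inconsistent")
  expect_error(drawSimParams("hard-linked", 5, pri), "inconsistent")
  expect_error(drawSimParams("soft", 11, pri), "sweepSubwindow")
  expect_error(drawSimParams("neutral", 3, pri), "no sweep subwindow")
})

test_that("selection-prior rescaling preserves s/r and inverts exactly", {
  pri <- SimPriors()                       # L = 2.75 Mb, s in [0.005, 0.05]
  down <- rescaleForRegion(pri, 5.5e5)
  expect_equal(down@sLow, 0.001)
  expect_equal(down@sHigh, 0.01)
  expect_equal(down@regionLength, 5.5e5)
  expect_equal(down@muLow, pri@muLow)      # everything else unchanged
  expect_equal(down@rMean, pri@rMean)
  ## identity and invertibility
  expect_equal(rescaleForRegion(pri, pri@regionLength)@sLow, pri@sLow)
  back <- rescaleForRegion(down, 2.75e6)
  expect_equal(back@sLow, pri@sLow, tolerance = 1e-12)
  expect_equal(back@sHigh, pri@sHigh, tolerance = 1e-12)
})

test_that("neutral simulations match Watterson's expected site count", {
  ## n = 10 diploids (20 alleles), Ne = 1e4, mu = 1e-8, L = 1e5:
  ## E[S] = a_19 * 4 Ne mu L ~ 142
  pri <- SimPriors(muLow = 1e-8 - 1e-15, muHigh = 1e-8 + 1e-15,
                   regionLength = 1e5, sampleSize = 10)
  dem <- DemographicModel(0, 1e4)
  ps <- lapply(seq_len(200), function(i) {
    p <- drawSimParams("neutral", NA, pri, seed = 40000 + i)
    p@r <- 1e-8
    p
  })
  names(ps) <- paste0("r", seq_along(ps))
  gms <- sweepscan:::.simulateBatch(ps, dem)
  meanS <- mean(vapply(gms, nSites, numeric(1)))
  expected <- sum(1 / (1:19)) * 4 * 1e4 * 1e-8 * 1e5
  expect_lt(abs(meanS - expected) / expected, 0.10)
})

test_that("simulation is deterministic given the stored seed", {
  pri <- rescaleForRegion(SimPriors(sampleSize = 6), 2.2e4)
  dem <- DemographicModel(0, 5e4)
  p <- drawSimParams("hard", 5, pri, seed = 77)
  a <- simulateReplicate(p, dem)
  b <- simulateReplicate(p, dem)
  expect_identical(positions(a), positions(b))
  expect_identical(dosages(a), dosages(b))
})

test_that("mask transfer removes variants and records the profile", {
  d <- matrix(rep(c(0L, 1L, 2L), 10), nrow = 3)
  gm <- GenotypeMatrix("sim", 0, 1000, seq(50, 950, by = 100), d)
  p <- drawSimParams("neutral", NA, SimPriors(regionLength = 1000,
                                              sampleSize = 3), seed = 1)
  rep0 <- new("LabeledReplicate", params = p, genotypes = gm, mask = NULL)

  ## profile masking the left half removes all variants below L/2
  half <- MaskProfile("w", 0, 1000, matrix(c(0, 500), 1))
  set.seed(1)
  out <- applyMaskTransfer(rep0, list(half))
  expect_true(all(positions(genotypes(out)) >= 500))
  expect_equal(maskedFraction(out@mask), 0.5)

  ## an empty profile leaves the replicate unchanged
  none <- MaskProfile("w", 0, 1000)
  out2 <- applyMaskTransfer(rep0, list(none))
  expect_identical(dosages(genotypes(out2)), dosages(gm))

  ## a full mask leaves a 0-site matrix
  full <- MaskProfile("w", 0, 1000, matrix(c(0, 1000), 1))
  out3 <- applyMaskTransfer(rep0, list(full))
  expect_equal(nSites(genotypes(out3)), 0)
  expect_equal(maskedFraction(out3@mask), 1)

  ## mask coordinates rescale proportionally across window lengths
  half2 <- MaskProfile("w", 0, 100, matrix(c(0, 50), 1))
  out4 <- applyMaskTransfer(rep0, list(half2))
  expect_true(all(positions(genotypes(out4)) >= 500))

  expect_error(applyMaskTransfer(rep0, list()), "empty")
})

test_that("corpus labeling and pool sizes follow the sweep placement", {
  pri <- rescaleForRegion(SimPriors(sampleSize = 4), 1.1e4)
  dem <- DemographicModel(0, 2e4)
  corpus <- buildCorpus(pri, dem, nPerSubwindow = 2, seed = 55)
  labels <- vapply(corpus, classLabel, character(1))
  tab <- table(labels)
  expect_equal(unname(tab[["hard"]]), 2)
  expect_equal(unname(tab[["soft"]]), 2)
  expect_equal(unname(tab[["hard-linked"]]), 20)
  expect_equal(unname(tab[["soft-linked"]]), 20)
  expect_equal(unname(tab[["neutral"]]), 2)
  ## label is a pure function of sweep placement
  for (rep in corpus) {
    p <- simParams(rep)
    if (p@classLabel == "neutral") {
      expect_true(is.na(p@sweepSubwindow))
    } else if (p@classLabel %in% c("hard", "soft")) {
      expect_equal(p@sweepSubwindow, 5)
    } else {
      expect_true(p@sweepSubwindow != 5)
    }
  }
  ## reproducible end to end under the same master seed
  corpus2 <- buildCorpus(pri, dem, nPerSubwindow = 2, seed = 55)
  expect_identical(lapply(corpus, function(x) dosages(genotypes(x))),
                   lapply(corpus2, function(x) dosages(genotypes(x))))
})

test_that("train/test assembly is balanced, disjoint and validated", {
  corpus <- placeholderCorpus(c(neutral = 10, "hard" = 10,
                                "hard-linked" = 10, "soft" = 10,
                                "soft-linked" = 10))
  split <- assembleTrainTest(corpus, 8, 2, seed = 9)
  expect_length(split$train, 40)
  expect_length(split$test, 10)
  expect_length(intersect(split$trainIdx, split$testIdx), 0)
  trLab <- vapply(split$train, classLabel, character(1))
  expect_true(all(table(trLab) == 8))
  teLab <- vapply(split$test, classLabel, character(1))
  expect_true(all(table(teLab) == 2))
  expect_error(assembleTrainTest(corpus, 9, 2, seed = 9), "neutral")
})

test_that("the fixture genome is reproducible and lists its implants", {
  pri <- rescaleForRegion(SimPriors(sampleSize = 4), 1.1e4)
  cfg <- fixtureGenomeConfig(priors = pri,
                             demography = DemographicModel(0, 2e4))
  cfg$chromLengths <- c(chr1 = 6 * 1.1e4, chr2 = 6 * 1.1e4)
  cfg$sweeps <- data.frame(chrom = c("chr1", "chr2"), tile = c(2, 3),
                           type = c("soft", "soft"))
  cfg$zeroRateTile <- list(chrom = "chr1", tile = 4)
  cfg$highMaskTile <- list(chrom = "chr2", tile = 5, fraction = 0.9)
  cfg$nGenes <- 20; cfg$nFocal <- 5; cfg$nTerms <- 4

  out1 <- makeFixtureGenome(cfg, seed = 3, outDir = withr::local_tempdir())
  expect_equal(nrow(out1$truth), 2)
  expect_true(all(out1$truth$type == "soft"))
  expect_true(all(file.exists(out1$paths)))

  out2 <- makeFixtureGenome(cfg, seed = 3, outDir = withr::local_tempdir())
  for (f in names(out1$paths))
    expect_identical(readLines(out1$paths[[f]]),
                     readLines(out2$paths[[f]]),
                     label = paste("file", f))

  ## the VCF round-trips through the standard reader
  gm <- readVcfWindow(out1$paths[["vcf"]], "chr1", 0, 6 * 1.1e4)
  expect_gt(nSites(gm), 20)     # ~11 expected sites per 11 kb tile
  expect_equal(nIndividuals(gm), 4)

  ## the zero-rate interval knocks out at least one scan window
  map <- readRecombMap(out1$paths[["recomb"]])
  wins <- enumerateWindows(cfg$chromLengths, 1.1e4, 1e3)
  kept <- filterWindows(wins, map, readBed(out1$paths[["mask"]]))
  counts <- attr(kept, "filterCounts")
  expect_gt(counts[["zeroRecomb"]], 0)
  expect_gt(counts[["overMasked"]], 0)
})
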