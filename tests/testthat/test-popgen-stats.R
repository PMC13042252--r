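test_that("nucleotide diversity matches the brute-force allele-pair oracle", {
  gm <- GenotypeMatrix("c", 0, 100, 10, matrix(c(0L, 2L), nrow = 2))
  expect_equal(nucleotideDiversity(gm), 4 / 6)       # alleles {0,0,1,1}
  expect_equal(nucleotideDiversity(gm), oraclePi(gm))

  ## monomorphic matrix
  gmMono <- GenotypeMatrix("c", 0, 100, c(1, 2),
                           matrix(c(2L, 2L, 2L, 2L), nrow = 2))
  expect_equal(nucleotideDiversity(gmMono), 0)

  ## a site with all-but-one genotype missing is skipped
  d <- matrix(c(1L, NA, NA, 0L, 2L, 1L), nrow = 3)
  gmMiss <- GenotypeMatrix("c", 0, 100, c(5, 6), d)
  expect_equal(nucleotideDiversity(gmMiss), oraclePi(gmMiss))

  set.seed(11)
  for (i in 1:20) {
    gm <- randomGenotypeMatrix(sample(3:8, 1), sample(1:10, 1),
                               missFrac = sample(c(0, 0.2), 1))
    expect_equal(nucleotideDiversity(gm), oraclePi(gm), tolerance = 1e-12)
  }
})

test_that("Watterson's theta follows the harmonic-sum definition", {
  ## S = 3 segregating sites, 4 alleles (2 diploids)
  d <- matrix(c(0L, 1L, 1L, 2L, 0L, 1L), nrow = 2)
  gm <- GenotypeMatrix("c", 0, 100, c(1, 2, 3), d)
  expect_equal(wattersonTheta(gm), 3 / (1 + 1 / 2 + 1 / 3),
               tolerance = 1e-9)
  ## no segregating sites
  expect_equal(wattersonTheta(GenotypeMatrix("c", 0, 100, numeric(0),
                                             matrix(0L, 2, 0))), 0)
  ## linearity in S at fixed allele count
  d6 <- cbind(d, d)
  gm6 <- GenotypeMatrix("c", 0, 100, 1:6, d6)
  expect_equal(wattersonTheta(gm6), 2 * wattersonTheta(gm))
})

test_that("Tajima's D sign, convention and oracle equivalence", {
  expect_equal(tajimasD(GenotypeMatrix("c", 0, 10, numeric(0),
                                       matrix(0L, 4, 0))), 0)
  ## excess rare variants drives D negative: many singleton sites
  set.seed(2)
  d <- matrix(0L, 10, 12)
  for (j in 1:12) d[sample(10, 1), j] <- 1L
  gmRare <- GenotypeMatrix("c", 0, 100, 1:12, d)
  expect_lt(tajimasD(gmRare), 0)
  set.seed(3)
  for (i in 1:20) {
    gm <- randomGenotypeMatrix(sample(3:8, 1), sample(2:10, 1),
                               missFrac = sample(c(0, 0.2), 1))
    expect_equal(tajimasD(gm), oracleTajimaD(gm), tolerance = 1e-9)
  }
})

test_that("MLG spectrum reproduces the homozygosity formulas", {
  ## frequencies (0.5, 0.3, 0.2)
  d <- rbind(matrix(rep(c(0L, 0L), 5), ncol = 2, byrow = TRUE),
             matrix(rep(c(1L, 2L), 3), ncol = 2, byrow = TRUE),
             matrix(rep(c(2L, 0L), 2), ncol = 2, byrow = TRUE))
  m <- mlgSpectrum(GenotypeMatrix("c", 0, 100, c(5, 50), d))
  expect_equal(m[["h1"]], 0.38)
  expect_equal(m[["h12"]], 0.68)
  expect_equal(m[["h2h1"]], (0.38 - 0.25) / 0.38)
  expect_equal(m[["nDistinct"]], 3)

  ## all individuals identical
  dAll <- matrix(1L, 6, 3)
  mAll <- mlgSpectrum(GenotypeMatrix("c", 0, 10, 1:3, dAll))
  expect_equal(unname(mAll), c(1, 1, 1, 0))

  ## all individuals distinct
  dDist <- diag(2L, 5)
  storage.mode(dDist) <- "integer"
  mD <- mlgSpectrum(GenotypeMatrix("c", 0, 10, 1:5, dDist))
  expect_equal(mD[["nDistinct"]], 5)
  expect_equal(mD[["h1"]], 1 / 5)

  ## empty input convention
  expect_equal(unname(mlgSpectrum(GenotypeMatrix("c", 0, 10, numeric(0),
                                                 matrix(0L, 3, 0)))),
               c(0, 0, 0, 0))

  ## missing data is a distinct symbol: (0) vs (NA) differ
  dNA <- matrix(c(0L, NA), nrow = 2)
  expect_equal(mlgSpectrum(GenotypeMatrix("c", 0, 10, 1, dNA))[["nDistinct"]],
               2)
})

test_that("Rogers-Huff r2 conventions and values", {
  expect_equal(rogersHuffR2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(rogersHuffR2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  expect_equal(rogersHuffR2(c(0, 1, 2), c(2, 1, 0)), 1)   # r = -1, squared
  expect_equal(rogersHuffR2(c(1, 1, 1), c(0, 1, 2)), 0)   # zero variance
  expect_equal(rogersHuffR2(c(0, NA, NA), c(NA, 1, 2)), 0) # < 2 pairs
  expect_error(rogersHuffR2(c(0, 1), c(0, 1, 2)), "equal length")
})

test_that("Zns equals the brute-force pair average", {
  d2 <- matrix(c(0L, 0L, 2L, 2L, 0L, 0L, 2L, 2L), ncol = 2)
  expect_equal(kellyZns(GenotypeMatrix("c", 0, 10, 1:2, d2)), 1)
  expect_equal(kellyZns(GenotypeMatrix("c", 0, 10, 1,
                                       matrix(c(0L, 1L), 2))), 0)
  set.seed(4)
  for (i in 1:10) {
    gm <- randomGenotypeMatrix(sample(4:8, 1), sample(2:8, 1),
                               missFrac = sample(c(0, 0.2), 1))
    expect_equal(kellyZns(gm), oracleZns(gm), tolerance = 1e-12)
  }
})

test_that("omega matches its definition and conventions", {
  ## identical columns: all pairwise r2 = 1, omega(l) = 1 everywhere
  d <- matrix(rep(c(0L, 1L, 2L, 1L, 0L, 2L), 8), ncol = 8)
  gm <- GenotypeMatrix("c", 0, 100, 1:8, d)
  expect_equal(omegaMax(gm), 1)

  ## S = 4 < 2*minSplit
  expect_equal(omegaMax(GenotypeMatrix("c", 0, 10, 1:4,
                                       d[, 1:4, drop = FALSE])), 0)

  ## two internally coherent, nearly uncorrelated blocks: omega is large
  ## at the block boundary and equals the brute-force evaluation
  set.seed(5)
  x <- c(0L, 0L, 2L, 2L, 1L, 0L)
  y <- c(0L, 2L, 0L, 2L, 1L, 2L)
  dB <- cbind(x, x, x, y, y, y)
  gmB <- GenotypeMatrix("c", 0, 100, 1:6, dB)
  expect_gt(omegaMax(gmB), 5)
  expect_equal(omegaMax(gmB), oracleOmegaMax(gmB), tolerance = 1e-9)

  set.seed(6)
  for (i in 1:10) {
    gm <- randomGenotypeMatrix(sample(4:8, 1), sample(6:10, 1),
                               missFrac = sample(c(0, 0.15), 1))
    expect_equal(omegaMax(gm), oracleOmegaMax(gm), tolerance = 1e-9)
  }
})

test_that("pairwise-difference moments are population moments", {
  dAll <- matrix(1L, 4, 3)
  expect_equal(unname(pairwiseDiffMoments(
    GenotypeMatrix("c", 0, 10, 1:3, dAll))), c(0, 0, 0))

  ## distances {0, 6, 6}: variance 8, skewness -1/sqrt(2), kurtosis 1.5
  d3 <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(2L, 2L, 2L))
  pm <- pairwiseDiffMoments(GenotypeMatrix("c", 0, 10, 1:3, d3))
  expect_equal(pm[["variance"]], 8)
  expect_equal(pm[["skewness"]], -sqrt(0.5))
  expect_equal(pm[["kurtosis"]], 1.5)

  ## direct check of the moment conventions on the multiset {0, 0, 6}
  dd <- c(0, 0, 6)
  mu <- mean(dd); v <- mean((dd - mu)^2)
  expect_equal(v, 8)
  expect_equal(mean((dd - mu)^3) / v^1.5, sqrt(0.5), tolerance = 1e-9)

  ## invariant under site reordering
  set.seed(7)
  gm <- randomGenotypeMatrix(5, 8)
  d <- dosages(gm)
  perm <- sample(ncol(d))
  gmP <- GenotypeMatrix("c", 0, 1000, sort(positions(gm)),
                        d[, perm, drop = FALSE])
  expect_equal(pairwiseDiffMoments(gm)[["variance"]],
               pairwiseDiffMoments(gmP)[["variance"]])
  expect_error(pairwiseDiffMoments(
    GenotypeMatrix("c", 0, 10, 1:2, matrix(c(0L, 1L), 1))), "2 individuals")
})

test_that("statistic invariants hold on fuzzed matrices", {
  set.seed(8)
  for (i in 1:300) {
    gm <- randomGenotypeMatrix(sample(2:8, 1), sample(0:12, 1),
                               missFrac = sample(c(0, 0.1, 0.3), 1))
    sv <- statVector(gm)
    expect_true(all(is.finite(sv)))
    expect_gte(sv[["pi"]], 0)
    expect_gte(sv[["theta_w"]], 0)
    expect_gte(sv[["h12"]], sv[["h1"]] - 1e-12)
    expect_true(sv[["h1"]] >= 0 && sv[["h1"]] <= 1)
    expect_true(sv[["h12"]] >= 0 && sv[["h12"]] <= 1)
    expect_true(sv[["zns"]] >= 0 && sv[["zns"]] <= 1 + 1e-12)
    expect_gte(sv[["omega_max"]], 0)
  }
})

test_that("LD statistics are invariant to individual reordering", {
  set.seed(9)
  gm <- randomGenotypeMatrix(8, 10)
  d <- dosages(gm)
  perm <- sample(nrow(d))
  gmP <- GenotypeMatrix("c", 0, 1000, positions(gm), d[perm, , drop = FALSE])
  expect_equal(kellyZns(gm), kellyZns(gmP))
  expect_equal(omegaMax(gm), omegaMax(gmP))
})

test_that("pi on fully homozygous data equals the classic haploid pi", {
  ## dosages restricted to {0, 2}: each diploid is two identical haploids
  set.seed(10)
  d <- matrix(sample(c(0L, 2L), 6 * 8, replace = TRUE), 6, 8)
  gm <- GenotypeMatrix("c", 0, 100, 1:8, d)
  ## haploid pi on the n distinct sequences, sample size n (each individual
  ## contributes a duplicated haplotype, oracle enumerates all 2n alleles)
  expect_equal(nucleotideDiversity(gm), oraclePi(gm))
})
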