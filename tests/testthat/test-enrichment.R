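## shared fixture: a grid of windows on two chromosomes plus random genes
enrichFixture <- function(seed = 1, nWin = 40, nGenes = 60, nFocal = 15,
                          winLen = 1e4) {
  set.seed(seed)
  wins <- rbind(
    data.frame(chrom = "chr1", start = (0:(nWin / 2 - 1)) * winLen),
    data.frame(chrom = "chr2", start = (0:(nWin / 2 - 1)) * winLen))
  wins$end <- wins$start + winLen
  chromLen <- nWin / 2 * winLen
  geneChrom <- sample(c("chr1", "chr2"), nGenes, replace = TRUE)
  geneStart <- round(runif(nGenes, 0, chromLen - 2000))
  genes <- data.frame(id = sprintf("g%03d", 1:nGenes), chrom = geneChrom,
                      start = geneStart, end = geneStart + 2000,
                      stringsAsFactors = FALSE)
  list(windows = wins, genes = genes,
       focal = sample(genes$id, nFocal))
}

test_that("gene overlap counting honors padding and deduplication", {
  wins <- data.frame(chrom = "chr1", start = 10000, end = 20000)
  genes <- data.frame(id = c("a", "b", "c"),
                      chrom = "chr1",
                      start = c(9000, 8000, 15000),
                      end = c(9500, 8500, 16000))
  ann <- annotationSet(genes, focal = c("a", "b", "c"))
  ## gene a ends 500 bp before the window: counted with 1 kb padding;
  ## gene b ends 1500 bp before: not counted even when padded
  expect_equal(geneOverlapCount(wins, ann, pad = 1000), 2L)
  ## without padding only the contained gene counts
  expect_equal(geneOverlapCount(wins, ann, pad = 0), 1L)
  ## a gene spanning two windows counts once
  wins2 <- rbind(wins, data.frame(chrom = "chr1", start = 14000,
                                  end = 15500))
  expect_equal(geneOverlapCount(wins2,
                                annotationSet(genes, focal = "c"),
                                pad = 0), 1L)
})

test_that("the gene-set permutation test detects a constructed signal", {
  fx <- enrichFixture(seed = 81)
  ## positive control: every sweep window hosts a focal gene
  sweepIdx <- c(2, 7, 12, 25, 33)
  scores <- rep(0.1, nrow(fx$windows)); scores[sweepIdx] <- 0.99
  genes <- fx$genes
  focal <- sprintf("f%02d", seq_along(sweepIdx))
  implanted <- data.frame(id = focal,
                          chrom = fx$windows$chrom[sweepIdx],
                          start = fx$windows$start[sweepIdx] + 4000,
                          end = fx$windows$start[sweepIdx] + 6000)
  ann <- annotationSet(rbind(genes, implanted), focal = focal)
  res <- permutationGeneSetTest(scores, fx$windows, ann, threshold = 0.95,
                                nPerm = 200, seed = 82)
  expect_equal(res$observed, 5L)
  expect_lte(res$p, 0.05)
  expect_gt(res$fold, 1)

  ## all scores below the threshold: observed 0, p = 1
  res0 <- permutationGeneSetTest(rep(0.1, nrow(fx$windows)), fx$windows,
                                 ann, nPerm = 50, seed = 83)
  expect_equal(res0$observed, 0L)
  expect_equal(res0$p, 1)

  ## observed count never exceeds the focal-set size
  expect_lte(res$observed, length(focal))
})

test_that("gene-set test p-values are calibrated under the null", {
  fx <- enrichFixture(seed = 84, nWin = 60, nGenes = 120, nFocal = 40)
  ann <- annotationSet(fx$genes, focal = fx$focal)
  nRuns <- 200
  ps <- vapply(seq_len(nRuns), function(i) {
    set.seed(8400 + i)
    scores <- rep(0.1, nrow(fx$windows))
    scores[sample(nrow(fx$windows), 12)] <- 0.99
    permutationGeneSetTest(scores, fx$windows, ann, threshold = 0.95,
                           nPerm = 200, seed = 8400 + i)$p
  }, numeric(1))
  ## approximately uniform: KS statistic below the 1% critical value
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(nRuns))
  ## type-I error at alpha = 0.05 within binomial error of 0.05
  expect_lt(abs(mean(ps <= 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / nRuns) + 0.01)
})

test_that("permutation tests are invariant to gene id relabeling", {
  fx <- enrichFixture(seed = 85)
  scores <- rep(0.1, nrow(fx$windows)); scores[c(3, 9)] <- 0.99
  ann1 <- annotationSet(fx$genes, focal = fx$focal)
  relabeled <- fx$genes
  relabeled$id <- paste0("x_", relabeled$id)
  ann2 <- annotationSet(relabeled, focal = paste0("x_", fx$focal))
  r1 <- permutationGeneSetTest(scores, fx$windows, ann1, nPerm = 100,
                               seed = 86)
  r2 <- permutationGeneSetTest(scores, fx$windows, ann2, nPerm = 100,
                               seed = 86)
  expect_equal(r1$observed, r2$observed)
  expect_equal(r1$p, r2$p)
})

test_that("circular rotation flags a term tiling the sweep windows", {
  fx <- enrichFixture(seed = 87, nGenes = 80)
  sweepIdx <- c(4, 5, 6, 24, 25)
  scores <- rep(0.1, nrow(fx$windows)); scores[sweepIdx] <- 0.9
  ## one term whose genes sit exactly in the sweep windows; decoy terms
  ## distributed at random
  hitGenes <- data.frame(id = sprintf("hit%02d", seq_along(sweepIdx)),
                         chrom = fx$windows$chrom[sweepIdx],
                         start = fx$windows$start[sweepIdx] + 4000,
                         end = fx$windows$start[sweepIdx] + 6000)
  genes <- rbind(fx$genes, hitGenes)
  goMap <- rbind(
    data.frame(gene_id = hitGenes$id, term = "GO:HIT"),
    data.frame(gene_id = fx$genes$id,
               term = sample(sprintf("GO:D%02d", 1:8), nrow(fx$genes),
                             replace = TRUE)))
  ann <- annotationSet(genes, goMap = goMap)
  res <- circularRotationTest(scores, fx$windows, ann, threshold = 0.8,
                              nPerm = 200, seed = 88)
  expect_lte(res$p[res$term == "GO:HIT"], 0.05)
  expect_gt(median(res$p[res$term != "GO:HIT"]), 0.2)
  ## observed counts never exceed the term size
  sizes <- table(goMap$term)
  expect_true(all(res$observed <= as.integer(sizes[res$term])))
  expect_error(circularRotationTest(0.5, fx$windows[1, ], ann), "two windows")
})

test_that("BH adjustment matches the hand calculation", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.2), 0.2)
  set.seed(89)
  p <- runif(30)
  q <- bhFdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in sorted order
  expect_true(all(q >= p - 1e-12))
  expect_error(bhFdr(c(0.5, 0)), "0, 1")
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})
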