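# sweepscan

Simulation-trained detection and classification of **hard and soft
selective sweeps** from unphased diploid genotype data.

## The problem

Recent positive selection perturbs diversity, the site-frequency spectrum
and linkage disequilibrium around the selected site. Classic scans look
for the deep diversity valley of a *hard* sweep (fixation of a single de
novo mutation) and are weak against *soft* sweeps (fixation from standing
variation at initial frequency f0, or from recurrent mutation), whose
signature is spread over several haplotype backgrounds. They are also
easily fooled by the "soft shoulder" of a nearby sweep and by
nonequilibrium demography. In large, diverse populations — e.g. insect
disease vectors with Ne of 1e5–1e6 adapting to insecticides — soft sweeps
are expected to be the dominant mode of adaptation, so a scan that cannot
see them misses most of the signal.

`sweepscan` takes the supervised approach: simulate labeled training data
under the user's own demographic history, summarize each genomic window
by the spatial pattern of twelve population-genetic statistics in eleven
adjacent subwindows (π, Watterson's θ, Tajima's D; the multilocus-genotype
analogues of the haplotype statistics — number of distinct MLGs, H1, H12,
H2/H1; Rogers–Huff r²-based Zns and max ω; and the variance, skewness and
kurtosis of the pairwise-difference distribution — each statistic's row
normalized to sum to 1), and train a small convolutional softmax network
to assign each window a posterior over five classes:

    neutral | hard-linked | soft-linked | hard | soft

Downstream of classification it implements the matching inference layer:
sliding-window genome scans with data-quality filters (zero-recombination
windows, masked fraction > 0.85), sweep calls at combined
hard+soft-probability thresholds, simulation-null FDR / q-values per
candidate, a conservative confusion-matrix-corrected estimate of the
fraction of sweeps that are soft, cross-population intersection of
calls, and two permutation enrichment tests (gene-set label shuffling,
and GO-term testing against a circular-rotation null that preserves the
spatial autocorrelation of sweep scores).

Everything runs on unphased dosages (0/1/2 with missing genotypes), read
from standard formats: VCF for genotypes, BED for masks and genes, TSV
for recombination maps, demographic histories and gene–GO maps.
Coalescent simulation (neutral, hard-sweep and soft-sweep histories under
piecewise-constant Ne) is delegated to msprime through a bundled Python
helper; everything else is R.

## Worked example

Simulate a small labeled corpus under a constant-size history, train the
classifier, and classify a held-out replicate:

```r
library(sweepscan)

## priors at the full 2.75 Mb scale, rescaled to cheap 110 kb windows
## (selection bounds scale with window length, preserving s/r)
priors <- rescaleForRegion(SimPriors(sampleSize = 20), 1.1e5)
dem    <- DemographicModel(0, 5e5)      # constant Ne = 500,000

corpus <- buildCorpus(priors, dem, nPerSubwindow = 40,
                      nPerFlankSubwindow = 8, seed = 7)
split  <- assembleTrainTest(corpus, nTrainPerClass = 30,
                            nTestPerClass = 10, seed = 8)
train  <- featureTable(split$train)
test   <- featureTable(split$test)

model <- trainSweepClassifier(train$features, train$labels, seed = 9)
post  <- predictPosterior(model, test$features)
head(round(post, 3), 3)
#>      neutral hard-linked soft-linked  hard  soft
#> [1,]   0.892       0.036       0.055 0.006 0.011
#> [2,]   0.732       0.032       0.186 0.020 0.030
#> [3,]   0.542       0.074       0.307 0.022 0.055

curves <- binarySweepCurves(post, test$labels)
round(c(auc = curves$auc, ap = curves$averagePrecision), 3)
#>   auc    ap
#> 0.812 0.696
```

The first test windows are truly neutral and the classifier puts most of
their mass on `neutral`/`soft-linked`; with only 150 training replicates
the binary sweep-vs-unselected AUC is 0.81. (This toy run is for
illustration; the package's reference experiment below trains on a 16x
larger corpus and an ensemble of three networks, reaching AUC around
0.89.) Rows
are windows, columns the five class posteriors; `binarySweepCurves`
scores each window by p(hard) + p(soft) for the binary
sweep-vs-unselected task. A genome scan on files looks like:

```r
gm    <- readVcfWindow("genotypes.vcf", "chr2", 0, 1.32e6, minGq = 20)
map   <- readRecombMap("recomb_map.tsv")
mask  <- readBed("mask.bed")
wins  <- enumerateWindows(c(chr2 = 1.32e6), windowLen = 1.1e5, step = 1e4)
kept  <- filterWindows(wins, map, mask)           # drops r = 0, mask > 0.85
calls <- classifyGenome(list(chr2 = gm), model, kept, maskBed = mask,
                        threshold = 0.80)
isSweep <- calls$decision %in% c("sweep-hard", "sweep-soft")
calls$q_value <- NA
calls$q_value[isSweep] <- sweepQvalues(calls$combined_sweep_prob[isSweep],
                                       calls$combined_sweep_prob,
                                       nullProbs = neutralTestProbs,
                                       nWindows = nrow(calls))
writeScanTable(calls[isSweep, ], "sweeps.tsv")
```

`makeFixtureGenome()` generates a complete synthetic dataset (VCF + mask
BED + recombination map + gene/GO annotations + truth table of implanted
sweeps) for exercising this pipeline end to end without any download.

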