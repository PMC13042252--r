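---
title: "Detecting and classifying selective sweeps from unphased genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying selective sweeps from unphased genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sweepscan)
```

## The problem

Recent positive selection leaves localized footprints in patterns of
genetic variation. A *hard* sweep — fixation of a single de novo
beneficial mutation — erases diversity around the selected site and
produces a characteristic excess of linkage disequilibrium on its flanks.
A *soft* sweep — fixation of an allele that was already segregating (at
frequency $f_0$) when selection began, or that arose recurrently — leaves
several haplotype backgrounds carrying the beneficial allele, a subtler
and qualitatively different signature. Single-statistic scans are biased
toward hard sweeps and are easily confounded by nonequilibrium demography;
large, genetically diverse insect populations (effective sizes of
$10^5$–$10^6$) are exactly the setting where soft sweeps are expected to
dominate and where that bias matters.

`sweepscan` implements a supervised, simulation-trained approach to this
problem for **unphased diploid genotype data**. Each genomic window is
summarized by the *spatial pattern* of twelve population-genetic
statistics across eleven adjacent subwindows, and a small convolutional
softmax network assigns the window a posterior over five classes:

* `neutral` — no sweep in or near the window;
* `hard` / `soft` — a sweep of that type in the central subwindow;
* `hard-linked` / `soft-linked` — a sweep in a flanking subwindow (the
  "soft shoulder" of a sweep, which single-statistic methods routinely
  miscall as an independent signal).

Training data come from coalescent simulations under the user's own
demographic history, so the classifier learns what neutrality looks like
*under that history* rather than under equilibrium assumptions.

## The feature representation

For a feature window of length $L$ split into $k = 11$ subwindows, the
twelve statistics (`statNames()`) are computed per subwindow on the
dosage matrix (0/1/2, `NA` for masked genotypes):

* frequency-spectrum summaries: nucleotide diversity $\pi$, Watterson's
  $\hat\theta_w$, Tajima's $D$;
* multilocus-genotype (MLG) spectrum summaries: number of distinct MLGs,
  $H_1 = \sum_i p_i^2$, $H_{12} = (p_1 + p_2)^2 + \sum_{i \ge 3} p_i^2$,
  $H_2/H_1$ — the unphased analogues of the haplotype-homozygosity
  statistics ($H_{12}$ is sensitive to both sweep types, $H_2/H_1$
  measures softness);
* linkage disequilibrium summaries built on the Rogers–Huff genotype
  $r^2$: Kelly's $Z_{nS}$ (mean pairwise $r^2$) and the maximum of the
  $\omega$ statistic over split points (within-flank vs between-flank LD
  contrast);
* the variance, skewness and kurtosis of the distribution of pairwise
  dosage differences between individuals.

Each statistic's row of $k$ values is then normalized to sum to one: if
the smallest value is negative (possible for Tajima's $D$ and skewness),
its absolute value is first added to every entry, then the row is divided
by its sum; an all-zero row becomes the uniform row $1/k$. The shift is
applied *before* division because dividing by a possibly nonpositive row
sum is ill-defined; the normalization is per window, not per dataset.
Row-normalization discards absolute levels — which drift with genome-wide
demography — and keeps the spatial profile, which is what distinguishes a
sweep centered on the window from one on its shoulder.

Degenerate inputs are given explicit conventions so every feature is
finite on every window: empty subwindows yield zeros (and the uniform row
after normalization), monomorphic or fully missing site pairs contribute
$r^2 = 0$, $\omega$ split points with zero across-flank LD are skipped,
and per-site sample sizes are adjusted for missing genotypes ($\pi$,
$\hat\theta_w$ use per-site allele counts; the MLG spectrum treats a
missing genotype as a distinct fifth symbol; LD uses pairwise-complete
individuals).

## Training-data design

`SimPriors()` holds the wide priors the corpus is drawn from. At the full
scale of the motivating design these are: mutation rate
$\mu \sim U(8.82\times10^{-10},\, 8.82\times10^{-9})$ per bp per
generation (mean $4.85\times10^{-9}$); recombination rate $r$ exponential
with mean $4.85\times10^{-9}$, truncated at three times the mean (the
realized mean is therefore slightly below the nominal one); selection
coefficient $s$ log-uniform on $[0.005, 0.05]$; fixation time
$\tau \sim U(0, 0.001)$ in units of $4N$ generations (the most recent
epoch's $N$; so all sweeps completed very recently); and, for soft
sweeps, the standing frequency $f_0 \sim U(0, 0.05)$. Hard sweeps start
from a single copy.

`buildCorpus()` places the selected site uniformly within each subwindow
in turn — replicates whose sweep lands in the central subwindow are
labeled `hard`/`soft`, all others `hard-linked`/`soft-linked` — and adds
sweep-free `neutral` replicates. `assembleTrainTest()` subsamples the
pools into balanced, disjoint train and test sets. Since the linked-class
pools are $(k-1)$-fold larger than needed for a balanced design,
`nPerFlankSubwindow` lets reduced-scale corpora simulate fewer replicates
per flank cell; placement remains uniform across flank subwindows, so the
linked-class distribution is unchanged.

`rescaleForRegion()` adapts the selection prior to a shorter simulated
region by multiplying the $s$ bounds by the length ratio, preserving
$s/r$ and hence the sweep's footprint *relative to the window*. The
rescaled prior is kept log-uniform (the distribution family is not
changed by rescaling). The same trade-off motivates the choice in the
original full-scale design of simulating 550 kb windows with
$s \in [0.001, 0.01]$ in place of 2.75 Mb windows with
$s \in [0.005, 0.05]$.

Simulation is delegated to `msprime` (through a bundled Python helper):
neutral replicates use the standard coalescent with recombination under a
piecewise-constant `DemographicModel`; sweep replicates use the
structured-coalescent sweep model, run to fixation $\tau \cdot 4N_0$
generations before sampling, starting from frequency $1/2N_0$ (hard) or
$f_0$ (soft). Haplotypes are paired into unphased diploid dosages.
Every replicate carries its own seed, so any single one is reproducible
in isolation.

To emulate heterogeneous data quality, `applyMaskTransfer()` copies the
masked intervals of a randomly chosen empirical window profile onto a
simulated replicate (rescaling coordinates proportionally if the lengths
differ) and removes the variants inside them — training data are then
degraded the same way the real scan windows are.

## The classifier

The network is deliberately small: one $3\times3$ convolution (16
filters, ReLU) over the $12 \times 11$ feature grid — so each unit sees
how neighbouring statistics co-vary across adjacent subwindows — followed
by a 64-unit dense ReLU layer and a 5-way softmax. It is trained with
mini-batch Adam (batch 32, learning rate $10^{-3}$), decoupled weight
decay $10^{-2}$ (chosen by validation loss; small networks on a few
thousand noisy rows overfit within a handful of epochs without it), and
features standardized by training-set mean and standard deviation.
Because the simulation process is mirror-symmetric in
subwindow order (sweep placement is uniform, and each flank placement has
an equally likely mirror image in the same class), the training split is
augmented with subwindow-reversed copies; the validation split is not.

Early stopping follows the usual best-weights rule: 10% of the training
examples (stratified by class) are held out as a validation set, and when
five consecutive epochs fail to improve the best validation
cross-entropy by at least 0.001, training stops and the weights from the
best epoch are restored. "Improvement" is measured against the best loss
seen so far, not the previous epoch.

The softmax outputs are treated as class posteriors but are not
recalibrated; downstream inference therefore never interprets them as
frequentist probabilities — it compares them against simulation-based
null distributions instead.

## Genome scan and filters

`enumerateWindows()` slides the feature window along each chromosome in
steps of one subwindow; the *central subwindow* is the classified
interval. Two data-quality filters mirror common practice
(`filterWindows()`):

* windows whose weighted mean recombination rate is zero are dropped —
  the spatial sweep signature is undefined without recombination; the
  rate is evaluated over the central subwindow by default (footprint
  configurable), with map-uncovered sequence counting as rate zero;
* windows whose masked fraction exceeds 0.85 are dropped (strict
  inequality: exactly 0.85 is retained); the fraction is evaluated over
  the full feature window, the footprint that the features are computed
  on.

`callSweeps()` applies the decision rule at a combined-probability
threshold $t$: a window whose argmax class is hard or soft is called a
sweep (typed by the larger of the two sweep posteriors, ties toward soft)
only if $p_\text{hard} + p_\text{soft} \ge t$; otherwise it is
`uncertain`. Windows whose argmax is a linked or neutral class keep that
class. Decisions are monotone in $t$. `intersectPopulations()` keys
windows by coordinates across population samples and reports the
shared / population-specific partition plus all intersection
cardinalities.

Coordinates are 0-based half-open internally, matching BED; VCF input is
1-based; scan tables are written 1-based inclusive. Whether the
original reports' window bounds are half-open is not stated there; the
output convention here is an interpretation, applied consistently.

## Post-classification inference

**FDR and q-values** (`fdrAtThreshold()`, `sweepQvalues()`). The null
distribution is the set of combined sweep probabilities of *neutral test
replicates*. At threshold $t$,
$\mathrm{FDR}(t) = \min\!\big(1,\; W\,\hat F_0(t) / \max(1, R(t))\big)$,
where $\hat F_0(t)$ is the null exceedance rate, $W$ the number of
analyzed genomic windows and $R(t)$ the number of real windows at or
above $t$. Scaling by the full window count assumes every window could be
neutral ($\pi_0 = 1$), which is conservative; the cap at 1 removes
meaningless values. Each candidate's q-value is the minimum FDR over all
candidate thresholds at or below its own probability (a cumulative
minimum over candidates ordered by probability), so q-values are
monotone in the sweep probability.

**Confusion-corrected soft fraction** (`correctedSoftFraction()`). Two
deliberately conservative corrections reduce the soft-sweep count before
the fraction is formed: all expected false discoveries
($q \times$ calls) are assumed to be soft calls, and the confusion
matrix at the matching threshold supplies the rate at which *true hard*
sweeps are called soft — the implied hard-as-soft count uses the raw hard
calls inflated by the hard recall ($\hat H = \text{hard}/a$, a step this
package makes explicit). Soft sweeps misclassified as hard are ignored,
so the estimate is a lower bound on the soft fraction. It reduces to the
raw fraction under perfect classification.

**Enrichment** (`permutationGeneSetTest()`, `circularRotationTest()`).
The gene-set test counts focal genes (padded by 1 kb) overlapping sweep
windows and compares against permutations that reassign the scores to
window positions uniformly; the GO test instead concatenates the
chromosomes into a ring and rotates the score vector by a random nonzero
offset, preserving the scores' spatial autocorrelation — the appropriate
null when genes cluster. One-sided p-values are the literal proportion of
permutations with a count at or above the observed one (a `plusOne`
option gives the standard conservative variant; the literal proportion
can be zero). GO-term p-values are BH-adjusted (`bhFdr()`).

## The scaled-down reference experiment

Full-scale corpora (66,000 simulations of 2.75 Mb windows) are not
desk-scale objects, so the package pins a reduced design,
`deskScaleDesign()`, used by the test suite and by
`scripts/acceptance.R`:

* 110 kb windows (11 × 10 kb subwindows), priors rescaled via
  `rescaleForRegion()` so $s \in [2\times10^{-4}, 2\times10^{-3}]$;
* 20 diploid individuals, constant $N_e = 5\times10^5$ — inside the
  $10^5$–$10^6$ range estimated for the motivating populations and
  chosen so the population-scaled sweep strengths $2N_e s$ (200–2,000)
  overlap the regime the full-scale design trains on; weaker choices of
  $N_e L$ starve the features of signal rather than merely adding noise;
* pools of 600 per class (60 per flank cell via `nPerFlankSubwindow`),
  split 500 train / 100 test per class — about a fifth of the full-scale
  training size, with a larger-than-proportional test set so the
  evaluation metrics are measured with usefully small error;
* an ensemble of three networks trained from different seeds, predictions
  averaged — single small networks vary noticeably from seed to seed at
  this data size and averaging removes most of that variance; one master
  seed drives simulation, splitting and all trainings.

Scaling down changes what is achievable, not just how long it takes. All
of the classifier's information comes through the per-subwindow summary
statistics, whose Monte-Carlo noise shrinks with the number of
segregating sites, and under the `rescaleForRegion()` rule the
population-scaled sweep strengths scale with $N_e L$. A full-scale
design (2.75 Mb windows at $N_e$ around $5\times10^5$) carries roughly
25 times more $N_e L$ — both far stronger sweeps (up to
$2N_e s \approx 5\times10^4$) and an order of magnitude more sites per
subwindow — than any corpus that can be simulated and featurized in
minutes on one CPU. The desk-scale experiment is therefore a faithful
miniature of the procedure — every pipeline stage, rule and estimator is
identical — but its accuracy numbers (run `runReferenceExperiment()` or
`scripts/acceptance.R` to compute them) necessarily sit below what the
same pipeline attains on full-scale corpora, for signal-to-noise
reasons, not implementation ones. Equivalently: at a fixed compute
budget the desk-scale family of designs is nearly scale-invariant
(halving $L$ while doubling $N_e$ changes little), so the budget itself
sets the accuracy ceiling.

`runReferenceExperiment()` runs the whole chain and reports the binary
sweep-vs-unselected ROC AUC and average precision on the held-out test
set, plus the neutral misclassification rates with no threshold and at
the 0.80 combined-probability threshold. The synthetic fixture genome
(`makeFixtureGenome()`) exercises the scan end-to-end: tiled simulations
with implanted strong sweeps at recorded positions, a mask file with one
over-threshold window, a recombination map with one zero-rate interval,
and gene/GO annotations, all written in standard formats.

```{r reference, eval = FALSE}
res <- runReferenceExperiment(seed = 1)
res$curves$auc
res$curves$averagePrecision
res$neutralArgmaxPct
res$neutralAt80Pct
```

## What the synthetic data do and do not show

The generator reproduces the *mechanisms* the classifier exploits —
coalescent genealogies under piecewise-constant demography, hard and
soft sweep trajectories, recombination- and mutation-rate heterogeneity,
masking — and therefore supports meaningful tests of the entire
pipeline. It does not reproduce several features of real resequencing
data: linkage is broken at fixture tile boundaries, there is no
population structure or migration, no sequencing-error model beyond
masking, no indels or multiallelic sites, and the demographic histories
used here are simple one- or two-epoch models rather than full inferred
trajectories. Passing tests demonstrate the method's correctness and its
power under the stated conditions, not its accuracy on any particular
empirical dataset; on real data, performance is bounded by how well the
supplied demographic model fits (a strong recent bottleneck, as in the
excluded population samples of the motivating study, degrades it).

## Numerical choices and limitations

* The $\omega$ statistic uses split bounds $[3, S-3]$ (configurable);
  pairwise-difference moments are population (not sample) moments with
  non-excess kurtosis.
* Watterson's $\hat\theta_w$ and Tajima's $D$ use the modal per-site
  allele count under missingness; with heavy, uneven masking the
  constants are approximate.
* The FDR null is scaled by the full analyzed-window count
  ($\pi_0 = 1$); with many true sweeps this over-corrects, never
  under-corrects.
* Sweep-type ties ($p_\text{hard} = p_\text{soft}$) break toward soft;
  the event has probability ~0 with continuous posteriors.
* The discrete-time sweep trajectories use a fixed small integration
  step; extremely weak selection ($2Ns \lesssim 10$) is slow to simulate
  and outside the intended regime.
* Training runs on a single CPU in a few seconds at desk scale; the
  simulation corpus dominates runtime (minutes). Problem sizes used by
  the tests and the acceptance script are stated in
  `deskScaleDesign()`.
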