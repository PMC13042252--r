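## Synthetic fixture genome: a small multi-chromosome dataset assembled
## from tiled coalescent simulations with implanted sweeps at recorded
## positions, plus the accessory files a real scan needs (accessibility
## mask, recombination map, gene and GO annotations) and a truth table.
## Adjacent tiles are simulated independently, so linkage is broken at tile
## boundaries; the fixture emulates the file formats and the local sweep
## signatures, not chromosome-scale LD.

#' Default fixture-genome configuration
#'
#' @param priors A [SimPriors-class] (defaults to the full-scale priors
#'   rescaled to 110 kb windows).
#' @param demography A [DemographicModel-class].
#' @return Configuration list for [makeFixtureGenome()].
#' @export
fixtureGenomeConfig <- function(priors = rescaleForRegion(SimPriors(), 1.1e5),
                                demography = DemographicModel(0, 2e5)) {
  W <- priors@regionLength
  list(
    chromLengths = c(chr1 = 12 * W, chr2 = 12 * W),
    priors = priors,
    demography = demography,
    ## implanted sweeps: tile index (0-based) per chromosome and type
    sweeps = data.frame(chrom = c("chr1", "chr1", "chr2", "chr2", "chr2"),
                        tile = c(2, 5, 2, 5, 8),
                        type = c("hard", "soft", "hard", "soft", "hard"),
                        stringsAsFactors = FALSE),
    ## strong-implant parameters: selection at the prior maximum, sweep
    ## just completed, few founding haplotypes for soft implants
    implantF0 = 0.005,
    ## the span of this tile gets recombination rate zero
    zeroRateTile = list(chrom = "chr1", tile = 9),
    ## this tile is masked beyond the 0.85 scan cutoff
    highMaskTile = list(chrom = "chr2", tile = 11, fraction = 0.9),
    lightMaskMaxFraction = 0.1,
    nGenes = 150, geneLength = 2000, nTerms = 15, nFocal = 30)
}

#' Generate a synthetic fixture genome
#'
#' Simulates every tile of the configured chromosomes (neutral, except the
#' configured implants, which carry strong, just-completed sweeps —
#' selection coefficient at the prior maximum, few founding haplotypes for
#' soft implants — at the center of the tile's central subwindow) and
#' writes a complete synthetic
#' dataset: a diploid VCF, a mask BED with one window masked beyond the
#' scan cutoff, a recombination map with one zero-rate interval, gene BED,
#' gene-to-GO map, a focal gene list, and the truth table of implanted
#' sweeps. The same seed reproduces byte-identical files.
#'
#' @param config Configuration list (see [fixtureGenomeConfig()]).
#' @param seed Master seed.
#' @param outDir Output directory (created if needed).
#' @return List with `paths` (named file paths), `truth` (data.frame of
#'   implanted sweeps) and `config`.
#' @export
makeFixtureGenome <- function(config = fixtureGenomeConfig(), seed = 1,
                              outDir = tempfile("fixture")) {
  priors <- config$priors
  dem <- config$demography
  W <- priors@regionLength
  k <- priors@nSubwindows
  w <- W / k
  central <- (k - 1) / 2
  n <- priors@sampleSize
  if (any(config$chromLengths %% W != 0))
    stop("chromosome lengths must be multiples of the tile length")
  if (nrow(config$sweeps) > 0) {
    nt <- config$chromLengths[config$sweeps$chrom] / W
    if (any(config$sweeps$tile < 0 | config$sweeps$tile >= nt))
      stop("sweep tile index outside chromosome")
    if (!all(config$sweeps$type %in% c("hard", "soft")))
      stop("sweep types must be 'hard' or 'soft'")
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  .withSeed(seed, {
    ## draw tile parameters.  All tiles share the mean mutation and
    ## recombination rates: the fixture's recombination map declares a
    ## uniform rate, and a real genome does not jump an order of magnitude
    ## in mu between adjacent 110 kb tiles the way independent draws from
    ## the (deliberately wide) training prior would.  Implants get strong,
    ## just-completed sweeps at the center of the tile's central subwindow.
    muMean <- (priors@muLow + priors@muHigh) / 2
    implantF0 <- if (is.null(config$implantF0)) 0.005 else config$implantF0
    tiles <- list(); meta <- list()
    for (ch in names(config$chromLengths)) {
      for (t in seq_len(config$chromLengths[[ch]] / W) - 1) {
        hit <- which(config$sweeps$chrom == ch & config$sweeps$tile == t)
        if (length(hit)) {
          type <- config$sweeps$type[hit[1]]
          p <- drawSimParams(type, central, priors)
          p@s <- priors@sHigh
          p@tau <- 0
          p@f0 <- if (type == "soft") implantF0 else 0
          p@sweepPos <- W / 2
        } else {
          p <- drawSimParams("neutral", NA, priors)
        }
        p@mu <- muMean
        p@r <- priors@rMean
        validObject(p)
        id <- sprintf("%s_t%02d", ch, t)
        tiles[[id]] <- p
        meta[[id]] <- list(chrom = ch, tile = t)
      }
    }
    gms <- .simulateBatch(tiles, dem)

    ## assemble global site list and dosage matrix
    posAll <- numeric(0); dosAll <- NULL; chromAll <- character(0)
    for (id in names(tiles)) {
      off <- meta[[id]]$tile * W
      gm <- gms[[id]]
      posAll <- c(posAll, gm@positions + off)
      chromAll <- c(chromAll, rep(meta[[id]]$chrom, nSites(gm)))
      dosAll <- cbind(dosAll, dosages(gm))
    }

    ## masks: light random masking per tile + one over-threshold window
    maskRows <- list()
    for (id in names(tiles)) {
      frac <- runif(1, 0, config$lightMaskMaxFraction)
      if (frac > 0.005) {
        len <- frac * W
        s <- meta[[id]]$tile * W + runif(1, 0, W - len)
        maskRows[[id]] <- data.frame(chrom = meta[[id]]$chrom,
                                     start = round(s), end = round(s + len))
      }
    }
    hm <- config$highMaskTile
    hmStart <- hm$tile * W
    maskRows[["high"]] <- data.frame(chrom = hm$chrom,
      start = hmStart, end = round(hmStart + hm$fraction * W))
    maskBed <- do.call(rbind, c(maskRows, list(make.row.names = FALSE)))
    maskBed <- maskBed[order(maskBed$chrom, maskBed$start), ]

    ## recombination map: uniform rate with one zero-rate tile
    zr <- config$zeroRateTile
    r0 <- priors@rMean
    mapRows <- list()
    for (ch in names(config$chromLengths)) {
      len <- config$chromLengths[[ch]]
      if (!is.null(zr) && ch == zr$chrom) {
        zs <- zr$tile * W; ze <- zs + W
        mapRows[[ch]] <- data.frame(chrom = ch,
          start = c(0, zs, ze), end = c(zs, ze, len), rate = c(r0, 0, r0))
      } else {
        mapRows[[ch]] <- data.frame(chrom = ch, start = 0, end = len,
                                    rate = r0)
      }
    }
    mapDf <- do.call(rbind, c(mapRows, list(make.row.names = FALSE)))
    mapDf <- mapDf[mapDf$end > mapDf$start, ]
    recomb <- RecombinationMap(mapDf$chrom, mapDf$start, mapDf$end,
                               mapDf$rate)

    ## genes, GO terms, focal subset
    nG <- config$nGenes
    geneChrom <- sample(names(config$chromLengths), nG, replace = TRUE)
    geneStart <- vapply(geneChrom, function(ch)
      round(runif(1, 0, config$chromLengths[[ch]] - config$geneLength)),
      numeric(1))
    genes <- data.frame(id = sprintf("gene%04d", seq_len(nG)),
                        chrom = geneChrom, start = geneStart,
                        end = geneStart + config$geneLength,
                        stringsAsFactors = FALSE)
    terms <- sprintf("GO:%07d", seq_len(config$nTerms))
    goMap <- do.call(rbind, lapply(seq_len(nG), function(i) {
      tm <- sample(terms, sample(1:2, 1))
      data.frame(gene_id = genes$id[i], term = tm, stringsAsFactors = FALSE)
    }))
    focal <- sort(sample(genes$id, config$nFocal))

    ## truth table of implanted sweeps (central subwindow coordinates)
    truth <- if (nrow(config$sweeps) > 0) {
      data.frame(chrom = config$sweeps$chrom,
                 start = config$sweeps$tile * W + central * w,
                 end = config$sweeps$tile * W + (central + 1) * w,
                 sweep_pos = config$sweeps$tile * W + W / 2,
                 type = config$sweeps$type, stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 sweep_pos = numeric(0), type = character(0))
    }

    ## write everything
    paths <- c(vcf = file.path(outDir, "genotypes.vcf"),
               mask = file.path(outDir, "mask.bed"),
               recomb = file.path(outDir, "recomb_map.tsv"),
               genes = file.path(outDir, "genes.bed"),
               go = file.path(outDir, "go_map.tsv"),
               focal = file.path(outDir, "ir_genes.txt"),
               truth = file.path(outDir, "truth.tsv"))
    .writeFixtureVcf(paths[["vcf"]], config$chromLengths, chromAll, posAll,
                     dosAll)
    writeBed(maskBed, paths[["mask"]])
    writeRecombMap(recomb, paths[["recomb"]])
    writeBed(data.frame(genes[, c("chrom", "start", "end")],
                        name = genes$id), paths[["genes"]])
    write.table(goMap, paths[["go"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(focal, paths[["focal"]])
    write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(paths = paths, truth = truth, config = config)
  })
}

## internal: write a minimal diploid VCF through vcfR (deterministically
## uncompressed so fixture outputs are byte-stable across runs)
.writeFixtureVcf <- function(path, chromLengths, chrom, pos, dos) {
  n <- nrow(dos)
  o <- order(match(chrom, names(chromLengths)), pos)
  chrom <- chrom[o]; pos <- pos[o]; dos <- dos[, o, drop = FALSE]
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##contig=<ID=%s,length=%d>", names(chromLengths),
                    as.integer(chromLengths)),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  fix <- cbind(CHROM = chrom, POS = format(pos + 1, scientific = FALSE,
                                           trim = TRUE),
               ID = ".", REF = "A", ALT = "T", QUAL = ".", FILTER = "PASS",
               INFO = ".")
  gtCodes <- c("0/0", "0/1", "1/1")
  gt <- matrix(gtCodes[t(dos) + 1L], nrow = length(pos), ncol = n)
  colnames(gt) <- sprintf("ind%02d", seq_len(n))
  gt <- cbind(FORMAT = "GT", gt)
  vcf <- suppressMessages(
    methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                 meta = meta, fix = fix, gt = gt))
  tmp <- tempfile(fileext = ".vcf.gz")
  vcfR::write.vcf(vcf, file = tmp)
  writeLines(readLines(tmp), path)
  unlink(tmp)
  invisible(path)
}
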