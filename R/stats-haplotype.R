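## Multilocus-genotype (MLG) frequency-spectrum statistics.  With unphased
## data the "haplotype" homozygosity statistics are computed on the string
## of diploid dosages carried by each individual, missing genotypes acting
## as a distinct fifth symbol.

#' Multilocus-genotype spectrum statistics
#'
#' Collapses each individual's dosages across sites into a multilocus
#' genotype (MLG) string and computes, from the sorted MLG frequencies
#' p1 >= p2 >= ...: the number of distinct MLGs, H1 = sum(p_i^2),
#' H12 = (p1 + p2)^2 + sum_\{i>=3\}(p_i^2), and H2/H1 = (H1 - p1^2)/H1.
#' H12 pools the two most frequent classes and is sensitive to both hard and
#' soft sweeps; H2/H1 measures sweep softness. An empty matrix (no sites)
#' gives (0, 0, 0, 0).
#'
#' @param gm A [GenotypeMatrix-class].
#' @return Named numeric vector (nDistinct, h1, h12, h2h1).
#' @export
mlgSpectrum <- function(gm) {
  d <- dosages(gm)
  if (ncol(d) == 0)
    return(c(nDistinct = 0, h1 = 0, h12 = 0, h2h1 = 0))
  d[is.na(d)] <- 9L
  keys <- apply(d + 48L, 1, intToUtf8)
  counts <- tabulate(match(keys, unique(keys)))
  p <- sort(counts / length(keys), decreasing = TRUE)
  h1 <- sum(p^2)
  p2 <- if (length(p) >= 2) p[2] else 0
  h12 <- (p[1] + p2)^2 + if (length(p) >= 3) sum(p[-(1:2)]^2) else 0
  c(nDistinct = length(p), h1 = h1, h12 = h12, h2h1 = (h1 - p[1]^2) / h1)
}
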