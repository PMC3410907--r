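# Shared fixture builders. Everything is generated in code; no stored data.

# Genetic map from anchor positions and per-interval rates (rate[k] applies
# to the interval pos[k] -> pos[k+1]; the last entry pads the rate column).
mkMap <- function(pos, rate, chrom = "1") {
  rate <- rep_len(rate, length(pos))
  cm <- c(0, cumsum(diff(pos) * rate[-length(pos)] / 1e6))
  GeneticMap(data.frame(chrom = chrom, pos = pos, rate = rate, cm = cm))
}

mkPanel <- function(alleles, pos = NULL, chrom = "1", ids = NULL) {
  m <- ncol(alleles)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- paste0("s", seq_len(m))
  HaplotypePanel(data.frame(id = ids, chrom = chrom, pos = pos), alleles)
}

# Independent brute-force r2 from haplotype contingency counts (the oracle:
# works from the 2x2 haplotype table, not column correlations).
bruteR2 <- function(x, y) {
  n <- length(x)
  nAB <- sum(x == 1 & y == 1)
  pA <- sum(x) / n
  pB <- sum(y) / n
  D <- nAB / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Collapse a phased panel into unphased diploid genotypes (haplotypes
# 2k-1, 2k -> sample k).
collapseGeno <- function(panel) {
  a <- alleleMatrix(panel)
  odd <- seq(1, nrow(a) - 1, 2)
  GenotypeMatrix(a[odd, , drop = FALSE] + a[odd + 1, , drop = FALSE],
                 as.data.frame(variantTable(panel)))
}

# A moderately sized LD panel reused across files.
ldFixture <- function(seed = 3, nHap = 1000, len = 2e5, nFound = 20) {
  simulatePanel(PanelSimConfig(nHaplotypes = nHap, regionLength = len,
                               nFounders = nFound, seed = seed))
}

regionStart <- GenomicRanges::start
regionEnd <- GenomicRanges::end
regionMcols <- S4Vectors::mcols
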