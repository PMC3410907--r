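#' @name qcstats
#' @title Enriched-array-aware statistical analysis
#'
#' @description
#' An array whose SNPs were chosen *because* they associate with the study
#' traits breaks the assumptions behind standard genomic control, PCA and
#' kinship estimation. This module provides the machinery that repairs
#' them: null-SNP-set selection (replication SNPs for unrelated traits,
#' minus known-locus neighbourhoods, LD-pruned), the Cochran-Armitage
#' trend test and genomic-control lambda, structure-SNP selection,
#' method-of-moments IBD estimation, a Balding-Nichols-standardized
#' genetic relationship matrix, and a permutation test for SNP-set overlap
#' between traits.
NULL

#' Select null SNPs for genomic control on a trait-enriched array
#'
#' Starts from replication-tagged SNPs whose tag traits exclude the target
#' trait, removes any within `exclusionBp` of a known trait-associated
#' locus, and LD-prunes the remainder at `r2Max`. The provenance attribute
#' of the result records all three steps.
#'
#' @param design An [ArrayDesign-class].
#' @param targetTrait Trait under analysis.
#' @param knownAssoc `data.frame(chrom, pos)` of loci previously associated
#'   with the target trait (may be empty/NULL).
#' @param substrate A [HaplotypePanel-class] or [GenotypeMatrix-class] used
#'   for LD pruning; design SNPs absent from it are dropped with a message.
#' @param exclusionBp Exclusion distance (default 250 kb).
#' @param r2Max Pruning threshold (default 0.3).
#' @param windowBp Pruning window (default 1 Mb).
#' @return Character vector of null-SNP ids with a `provenance` attribute;
#'   an empty result is an error advising threshold relaxation.
#' @export
selectNullSnps <- function(design, targetTrait, knownAssoc = NULL, substrate,
                           exclusionBp = 250000, r2Max = 0.3, windowBp = 1e6) {
  stopifnot(is(design, "ArrayDesign"))
  e <- design@entries
  isRepl <- vapply(e$tags, function(t) any(startsWith(t, "replication:")), TRUE)
  tagTraits <- lapply(e$tags, function(t) unique(sub("^[^:]*:", "", t)))
  offTarget <- !vapply(tagTraits, function(t) targetTrait %in% t, TRUE)
  ids <- e$id[isRepl & offTarget]
  n0 <- length(ids)
  if (!is.null(knownAssoc) && nrow(knownAssoc)) {
    pos <- e$pos[match(ids, e$id)]
    chrom <- e$chrom[match(ids, e$id)]
    nearKnown <- vapply(seq_along(ids), function(k)
      any(knownAssoc$chrom == chrom[k] &
          abs(knownAssoc$pos - pos[k]) <= exclusionBp), TRUE)
    ids <- ids[!nearKnown]
  }
  n1 <- length(ids)
  missing <- setdiff(ids, variantIds(substrate))
  if (length(missing)) {
    message(length(missing), " null-candidate SNP(s) absent from LD substrate; dropped")
    ids <- setdiff(ids, missing)
  }
  kept <- if (length(ids)) ldPrune(substrate, ids, r2Max = r2Max,
                                   windowBp = windowBp) else character()
  if (!length(kept))
    stop("no null SNPs remain for trait '", targetTrait,
         "'; consider relaxing exclusionBp or r2Max")
  attr(kept, "provenance") <- sprintf(
    paste0("replication SNPs off-target for '%s': %d; after %d bp ",
           "known-locus exclusion: %d; after LD pruning (r2<=%.2f): %d"),
    targetTrait, n0, exclusionBp, n1, r2Max, length(kept))
  kept
}

## Vectorized Cochran-Armitage trend chi-squares for all variants; NA where
## the statistic is undefined (monomorphic column or single phenotype
## class among called samples). Scores (0,1,2) are the dosages themselves,
## so the moment sums come straight from the dosage matrix.
.trendStatAll <- function(dos, phenotype) {
  y <- as.numeric(phenotype)
  M <- !is.na(dos)
  D <- dos
  D[!M] <- 0L
  D <- D * 1.0
  N <- colSums(M)
  R <- as.numeric(crossprod(M, y))
  sxn <- colSums(D)
  sx2n <- colSums(D * D)
  sxr <- as.numeric(crossprod(D, y))
  num <- N * sxr - R * sxn
  den <- R * (N - R) * (N * sx2n - sxn^2)
  stat <- ifelse(den > 0, N * num^2 / den, NA_real_)
  stat[R == 0 | R == N] <- NA_real_
  stat
}

#' Cochran-Armitage trend test for one variant
#'
#' One-degree-of-freedom chi-square for trend on the 2x3 case/control by
#' genotype table with scores (0, 1, 2); missing dosages are excluded.
#'
#' @param geno A [GenotypeMatrix-class].
#' @param phenotype Binary vector (1 = case), length = samples.
#' @param variant Variant id or column index.
#' @return Chi-square statistic (1 df).
#' @export
trendTest <- function(geno, phenotype, variant) {
  stopifnot(is(geno, "GenotypeMatrix"),
            length(phenotype) == length(geno@samples))
  if (is.character(variant)) variant <- .idIndex(geno, variant)
  if (length(unique(phenotype[!is.na(phenotype)])) < 2)
    stop("both phenotype classes must be present")
  s <- unname(.trendStatAll(geno@dosages[, variant, drop = FALSE], phenotype))
  if (is.na(s))
    stop("trend statistic undefined for variant ", variant,
         " (monomorphic among called samples)")
  s
}

#' @rdname trendTest
#' @return `trendScan` returns the named vector of statistics for all
#'   variants (NA where undefined).
#' @export
trendScan <- function(geno, phenotype) {
  stopifnot(is(geno, "GenotypeMatrix"),
            length(phenotype) == length(geno@samples))
  stats::setNames(unname(.trendStatAll(geno@dosages, phenotype)),
                  variantIds(geno))
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi-squares) / 0.4549`, the median of the 1-df
#' chi-square distribution used by the genomic-control construction.
#'
#' @param stats Numeric vector of 1-df chi-square statistics (NAs dropped).
#' @param snpSetLabel Provenance label for the SNP set used.
#' @return A [LambdaGC-class].
#' @export
lambdaGc <- function(stats, snpSetLabel = "unspecified") {
  stats <- stats[!is.na(stats)]
  if (!length(stats)) stop("no statistics supplied")
  new("LambdaGC", lambda = stats::median(stats) / 0.4549,
      nSnps = length(stats), snpSetLabel = snpSetLabel)
}

#' Select SNPs for structure analysis (PCA/MDS/kinship)
#'
#' MAF filter (`maf > mafMin`) followed by greedy LD pruning; the returned
#' set feeds any standard eigen-decomposition, MDS or kinship routine.
#'
#' @param substrate A [HaplotypePanel-class] or [GenotypeMatrix-class].
#' @param mafMin Minimum MAF, exclusive (default 0.05).
#' @param r2Max Pruning threshold (default 0.3).
#' @param windowBp Pruning window (default 1 Mb).
#' @return Character vector of retained ids; empty result is an error.
#' @export
selectStructureSnps <- function(substrate, mafMin = 0.05, r2Max = 0.3,
                                windowBp = 1e6) {
  m <- mafs(substrate)
  ids <- names(m)[!is.na(m) & m > mafMin]
  if (!length(ids))
    stop("no SNPs pass the MAF filter (maf > ", mafMin, ")")
  kept <- ldPrune(substrate, ids, r2Max = r2Max, windowBp = windowBp)
  if (!length(kept)) stop("no SNPs survive LD pruning")
  kept
}

#' Method-of-moments IBD estimation for a sample pair
#'
#' Decomposes observed identity-by-state (IBS) counts into expected
#' contributions from the IBD states given the supplied allele
#' frequencies, solving for (k0, k1, k2) moment-wise and repairing the
#' estimate onto the simplex by truncation and renormalization.
#'
#' @param geno A [GenotypeMatrix-class].
#' @param i,j Sample ids or row indices (i = j estimates a self/duplicate
#'   pair and returns k2 = 1).
#' @param freqs Optional per-variant ALT-allele frequencies; estimated
#'   from the genotype matrix when NULL.
#' @param minSnps Minimum number of complete, polymorphic SNPs (default 200).
#' @return A [KinshipResult-class].
#' @export
ibdMom <- function(geno, i, j, freqs = NULL, minSnps = 200L) {
  stopifnot(is(geno, "GenotypeMatrix"))
  if (is.character(i)) i <- match(i, geno@samples)
  if (is.character(j)) j <- match(j, geno@samples)
  if (is.na(i) || is.na(j)) stop("unknown sample id")
  gi <- geno@dosages[i, ]
  gj <- geno@dosages[j, ]
  if (is.null(freqs)) freqs <- colMeans(geno@dosages, na.rm = TRUE) / 2
  ok <- !is.na(gi) & !is.na(gj) & freqs > 0 & freqs < 1
  if (sum(ok) < minSnps)
    stop("only ", sum(ok), " usable SNPs; need at least ", minSnps)
  gi <- gi[ok]; gj <- gj[ok]
  p <- freqs[ok]; q <- 1 - p
  d <- abs(gi - gj)
  N0 <- sum(d == 2L)
  N1 <- sum(d == 1L)
  e0.ibs0 <- sum(2 * p^2 * q^2)
  e0.ibs1 <- sum(4 * p^3 * q + 4 * p * q^3)
  e1.ibs1 <- sum(2 * p * q)
  k0 <- N0 / e0.ibs0
  k1 <- (N1 - k0 * e0.ibs1) / e1.ibs1
  k2 <- 1 - k0 - k1
  k <- pmax(c(k0, k1, k2), 0)
  k <- k / sum(k)
  new("KinshipResult", pair = c(geno@samples[i], geno@samples[j]),
      k0 = k[1], k1 = k[2], k2 = k[3], pihat = k[3] + k[2] / 2,
      nSnpsUsed = as.integer(sum(ok)))
}

#' Genetic relationship matrix from standardized genotypes
#'
#' Entry (i, j) is the mean over usable SNPs of
#' `(g_i - 2p)(g_j - 2p) / (2p(1-p))`; the diagonal approximates `1 + F`.
#' Missing dosages are excluded pairwise.
#'
#' @param geno A [GenotypeMatrix-class].
#' @param freqs Optional per-variant ALT-allele frequencies (estimated
#'   when NULL); SNPs with frequency outside (0, 1) are dropped.
#' @return Symmetric samples x samples matrix.
#' @export
grm <- function(geno, freqs = NULL) {
  stopifnot(is(geno, "GenotypeMatrix"))
  if (is.null(freqs)) freqs <- colMeans(geno@dosages, na.rm = TRUE) / 2
  use <- which(freqs > 0 & freqs < 1)
  if (!length(use)) stop("no polymorphic SNPs with frequencies in (0,1)")
  d <- geno@dosages[, use, drop = FALSE]
  p <- freqs[use]
  Z <- sweep(d, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = nrow(d))
  M <- !is.na(Z)
  Z[!M] <- 0
  K <- tcrossprod(Z) / tcrossprod(M * 1)
  dimnames(K) <- list(geno@samples, geno@samples)
  (K + t(K)) / 2
}

#' Permutation test for SNP-set overlap between two traits
#'
#' Null replicates draw `|A|` and `|B|` ids independently and uniformly
#' without replacement from the supplied universe and record the overlap;
#' the one-sided enrichment p-value is `(1 + #\{overlap >= observed\}) /
#' (nSim + 1)`. The universe is a required, explicit argument because the
#' sampling frame changes the p-value.
#'
#' @param setA,setB Variant id sets (subsets of `universe`).
#' @param universe The candidate pool both sets were drawn from.
#' @param nSim Number of null replicates (>= 1).
#' @param seed RNG seed.
#' @return An [OverlapTestResult-class].
#' @export
overlapTest <- function(setA, setB, universe, nSim = 9999L, seed = 1L) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("setA and setB must be subsets of the universe")
  stopifnot(nSim >= 1)
  obs <- length(intersect(setA, setB))
  nA <- length(setA); nB <- length(setB); U <- length(universe)
  .withSeed(seed, {
    nullOv <- integer(nSim)
    for (s in seq_len(nSim)) {
      a <- sample.int(U, nA)
      b <- sample.int(U, nB)
      nullOv[s] <- sum(match(a, b, nomatch = 0L) > 0L)
    }
    new("OverlapTestResult",
        nOverlap = obs, propMax = obs / min(nA, nB),
        expected = mean(nullOv),
        pEnrichment = (1 + sum(nullOv >= obs)) / (nSim + 1),
        nSim = as.integer(nSim),
        setSizes = c(A = nA, B = nB, universe = U))
  })
}
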