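#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' HaplotypePanel: phased reference haplotypes over ordered variants
#'
#' The LD substrate of the toolkit. Holds a 0/1 allele matrix with one row
#' per haplotype (two per diploid sample) and one column per variant, plus a
#' variant table (id, chrom, pos, ref, alt, maf, designable). Variants are
#' ordered by (chrom, pos) and the per-variant minor allele frequency is
#' always recomputed from the matrix, so `maf` can never drift out of sync
#' with the alleles.
#'
#' @slot variants A [S4Vectors::DataFrame] with columns `id`, `chrom`,
#'   `pos` (1-based bp), `ref`, `alt`, `maf` (in \[0, 0.5\]), `designable`.
#' @slot alleles Integer matrix in \{0, 1\}, haplotypes x variants.
#' @aliases HaplotypePanel
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  slots = c(variants = "DataFrame", alleles = "matrix"))

setValidity("HaplotypePanel", function(object) {
  v <- object@variants
  a <- object@alleles
  msg <- character()
  need <- c("id", "chrom", "pos", "ref", "alt", "maf", "designable")
  if (!all(need %in% colnames(v)))
    msg <- c(msg, paste("variants must have columns:", paste(need, collapse = ", ")))
  else {
    if (ncol(a) != nrow(v))
      msg <- c(msg, "allele matrix column count must equal variant count")
    if (length(a) && !all(a %in% c(0L, 1L)))
      msg <- c(msg, "allele matrix entries must be 0 or 1")
    if (anyDuplicated(v$id))
      msg <- c(msg, "variant ids must be unique within a panel")
    if (any(v$pos < 1))
      msg <- c(msg, "positions must be >= 1")
    if (any(v$maf < 0 | v$maf > 0.5))
      msg <- c(msg, "maf must lie in [0, 0.5]")
    o <- order(as.character(v$chrom), v$pos)
    if (!identical(o, seq_len(nrow(v))))
      msg <- c(msg, "variants must be sorted by (chrom, pos)")
    if (nrow(a) > 0 && ncol(a) > 0) {
      cm <- colMeans(a)
      if (max(abs(pmin(cm, 1 - cm) - v$maf)) > 1e-9)
        msg <- c(msg, "stored maf must equal min(mean, 1-mean) of each allele column")
    }
  }
  if (length(msg)) msg else TRUE
})

#' GenotypeMatrix: unphased diploid dosages
#'
#' Dosages are coded 0/1/2 copies of the alt allele with `NA` as the missing
#' sentinel; every estimator in the package excludes missing entries
#' pairwise.
#'
#' @slot samples Character vector of sample ids (rows).
#' @slot variants Variant table as in [HaplotypePanel-class].
#' @slot dosages Integer matrix over \{0, 1, 2, NA\}, samples x variants.
#' @aliases GenotypeMatrix
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  slots = c(samples = "character", variants = "DataFrame", dosages = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  msg <- character()
  if (nrow(d) != length(object@samples))
    msg <- c(msg, "dosage row count must equal sample count")
  if (ncol(d) != nrow(object@variants))
    msg <- c(msg, "dosage column count must equal variant count")
  if (length(d) && !all(d %in% c(0L, 1L, 2L) | is.na(d)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' GeneticMap: bp-to-cM anchors per chromosome
#'
#' Anchors carry (chrom, pos, rate in cM/Mb, cumulative cM). Genetic
#' position is piecewise-linear between anchors and constant beyond the
#' outermost anchors; local recombination rates between consecutive anchors
#' drive hotspot detection.
#'
#' @slot anchors A [S4Vectors::DataFrame] with columns `chrom`, `pos`,
#'   `rate`, `cm`, sorted by (chrom, pos).
#' @aliases GeneticMap
#' @exportClass GeneticMap
setClass("GeneticMap", slots = c(anchors = "DataFrame"))

setValidity("GeneticMap", function(object) {
  a <- object@anchors
  need <- c("chrom", "pos", "rate", "cm")
  if (!all(need %in% colnames(a)))
    return(paste("anchors must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  for (ch in unique(as.character(a$chrom))) {
    sub <- a[as.character(a$chrom) == ch, ]
    if (is.unsorted(sub$pos, strictly = TRUE))
      msg <- c(msg, sprintf("positions must be strictly increasing on chromosome %s", ch))
    if (is.unsorted(sub$cm))
      msg <- c(msg, sprintf("cumulative cM must be nondecreasing on chromosome %s", ch))
  }
  if (any(a$rate < 0)) msg <- c(msg, "rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SummaryStats: per-trait GWAS association summary results
#'
#' @slot trait Trait label.
#' @slot records A [S4Vectors::DataFrame] with columns `id`, `chrom`, `pos`,
#'   `pvalue` in (0, 1\], `eaf` (effect-allele frequency), sorted by
#'   (chrom, pos).
#' @aliases SummaryStats
#' @exportClass SummaryStats
setClass("SummaryStats", slots = c(trait = "character", records = "DataFrame"))

setValidity("SummaryStats", function(object) {
  r <- object@records
  need <- c("id", "chrom", "pos", "pvalue", "eaf")
  if (!all(need %in% colnames(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (any(r$pvalue <= 0 | r$pvalue > 1))
    msg <- c(msg, "p-values must lie in (0, 1]")
  o <- order(as.character(r$chrom), r$pos)
  if (!identical(o, seq_len(nrow(r))))
    msg <- c(msg, "records must be sorted by (chrom, pos)")
  if (length(msg)) msg else TRUE
})

## Closed category vocabulary for array entries.
.DESIGN_CATEGORIES <- c("replication", "fine_mapping", "prior_association",
                        "cnp_tag", "mhc", "mitochondrial", "sex_check",
                        "fingerprint", "wildcard")

#' ArrayDesign: the selected SNP set with per-SNP design tags
#'
#' One entry per unique variant id; each entry carries one or more
#' (category, trait) tags encoded as `"category:trait"` strings, plus an
#' alias list recording ids that resolved to the same physical site
#' (unintended duplicates collapsed at assembly).
#'
#' @slot entries A [S4Vectors::DataFrame] with columns `id`, `chrom`, `pos`,
#'   `ref`, `alt`, `tags` (CharacterList of `"category:trait"`), `aliases`
#'   (CharacterList).
#' @aliases ArrayDesign
#' @exportClass ArrayDesign
setClass("ArrayDesign", slots = c(entries = "DataFrame"))

setValidity("ArrayDesign", function(object) {
  e <- object@entries
  need <- c("id", "chrom", "pos", "ref", "alt", "tags", "aliases")
  if (!all(need %in% colnames(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(e$id)) msg <- c(msg, "one entry per unique variant id")
  tl <- lengths(e$tags)
  if (any(tl < 1)) msg <- c(msg, "every entry needs at least one tag")
  cats <- sub(":.*$", "", unlist(e$tags, use.names = FALSE))
  bad <- setdiff(unique(cats), .DESIGN_CATEGORIES)
  if (length(bad))
    msg <- c(msg, paste("unknown categories:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' KinshipResult: pairwise IBD-state estimates
#'
#' @slot pair Character vector of the two sample ids.
#' @slot k0,k1,k2 Estimated probabilities of sharing 0/1/2 alleles
#'   identical by descent; constrained to the simplex.
#' @slot pihat Relatedness `k2 + k1/2`.
#' @slot nSnpsUsed Number of SNPs with complete calls for both samples.
#' @aliases KinshipResult
#' @exportClass KinshipResult
setClass("KinshipResult",
  slots = c(pair = "character", k0 = "numeric", k1 = "numeric",
            k2 = "numeric", pihat = "numeric", nSnpsUsed = "integer"))

setValidity("KinshipResult", function(object) {
  k <- c(object@k0, object@k1, object@k2)
  msg <- character()
  if (length(object@pair) != 2) msg <- c(msg, "pair must hold two sample ids")
  if (any(k < -1e-9 | k > 1 + 1e-9)) msg <- c(msg, "each k must lie in [0, 1]")
  if (abs(sum(k) - 1) > 1e-9) msg <- c(msg, "k0+k1+k2 must equal 1")
  if (object@pihat < -1e-9 || object@pihat > 1 + 1e-9)
    msg <- c(msg, "pihat must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' OverlapTestResult: permutation test for SNP-set overlap between traits
#'
#' @slot nOverlap Observed number of shared SNPs.
#' @slot propMax `nOverlap / min(|A|, |B|)`, the proportion of the maximum
#'   possible overlap.
#' @slot expected Mean overlap across null replicates.
#' @slot pEnrichment One-sided permutation p-value, `(1 + exceed)/(nSim + 1)`.
#' @slot nSim Number of null replicates.
#' @slot setSizes Sizes of the two sets and the universe.
#' @aliases OverlapTestResult
#' @exportClass OverlapTestResult
setClass("OverlapTestResult",
  slots = c(nOverlap = "integer", propMax = "numeric", expected = "numeric",
            pEnrichment = "numeric", nSim = "integer", setSizes = "integer"))

setValidity("OverlapTestResult", function(object) {
  msg <- character()
  if (object@propMax < 0 || object@propMax > 1)
    msg <- c(msg, "propMax must lie in [0, 1]")
  if (object@pEnrichment <= 0 || object@pEnrichment > 1)
    msg <- c(msg, "p must lie in (0, 1]")
  if (object@pEnrichment < 1 / (object@nSim + 1) - 1e-12)
    msg <- c(msg, "p cannot be smaller than 1/(nSim+1)")
  if (length(msg)) msg else TRUE
})

#' LambdaGC: genomic-control inflation factor
#'
#' @slot lambda Median chi-square divided by 0.4549, the 1-df null median.
#' @slot nSnps Number of statistics used.
#' @slot snpSetLabel Provenance of the SNP set the statistics came from.
#' @aliases LambdaGC
#' @exportClass LambdaGC
setClass("LambdaGC",
  slots = c(lambda = "numeric", nSnps = "integer", snpSetLabel = "character"))

setValidity("LambdaGC", function(object) {
  if (object@lambda <= 0) "lambda must be positive" else TRUE
})
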