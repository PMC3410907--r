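#' Construct a HaplotypePanel
#'
#' `maf` is recomputed from the allele matrix; a `maf` column in `variants`
#' is ignored. Variants are reordered by (chrom, pos) together with the
#' matrix columns.
#'
#' @param variants A data.frame or DataFrame with columns `id`, `chrom`,
#'   `pos` and optionally `ref`, `alt`, `designable` (defaults "A"/"G"/TRUE).
#' @param alleles Matrix of 0/1 alleles, haplotypes x variants.
#' @return A [HaplotypePanel-class].
#' @examples
#' p <- HaplotypePanel(
#'   data.frame(id = c("s1", "s2"), chrom = "1", pos = c(100L, 200L)),
#'   matrix(c(0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L), nrow = 4))
#' mafs(p)
#' @export
HaplotypePanel <- function(variants, alleles) {
  v <- DataFrame(as.data.frame(variants))
  if (is.null(v$ref)) v$ref <- "A"
  if (is.null(v$alt)) v$alt <- "G"
  if (is.null(v$designable)) v$designable <- TRUE
  v$chrom <- as.character(v$chrom)
  v$pos <- as.integer(v$pos)
  alleles <- matrix(as.integer(alleles), nrow = nrow(alleles),
                    dimnames = dimnames(alleles))
  o <- order(v$chrom, v$pos)
  v <- v[o, , drop = FALSE]
  alleles <- alleles[, o, drop = FALSE]
  cm <- if (nrow(alleles)) colMeans(alleles) else rep(0, ncol(alleles))
  v$maf <- pmin(cm, 1 - cm)
  v <- v[, c("id", "chrom", "pos", "ref", "alt", "maf", "designable")]
  rownames(v) <- NULL
  colnames(alleles) <- v$id
  new("HaplotypePanel", variants = v, alleles = alleles)
}

#' Construct a GenotypeMatrix
#'
#' @param dosages Matrix over \{0, 1, 2, NA\}, samples x variants.
#' @param variants Variant table (`id`, `chrom`, `pos`, ...).
#' @param samples Sample ids; defaults to rownames or "ind1", "ind2", ...
#' @return A [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(dosages, variants, samples = NULL) {
  if (is.null(samples))
    samples <- rownames(dosages) %||% paste0("ind", seq_len(nrow(dosages)))
  v <- DataFrame(as.data.frame(variants))
  v$chrom <- as.character(v$chrom)
  v$pos <- as.integer(v$pos)
  if (is.null(v$ref)) v$ref <- "A"
  if (is.null(v$alt)) v$alt <- "G"
  o <- order(v$chrom, v$pos)
  v <- v[o, , drop = FALSE]
  rownames(v) <- NULL
  d <- matrix(as.integer(dosages), nrow = nrow(dosages))
  d <- d[, o, drop = FALSE]
  dimnames(d) <- list(samples, v$id)
  new("GenotypeMatrix", samples = as.character(samples), variants = v, dosages = d)
}

#' Construct a GeneticMap from anchor rows
#'
#' @param anchors data.frame with columns `chrom`, `pos` (bp), `rate`
#'   (cM/Mb), `cm` (cumulative cM).
#' @return A [GeneticMap-class].
#' @export
GeneticMap <- function(anchors) {
  a <- DataFrame(as.data.frame(anchors))
  a$chrom <- as.character(a$chrom)
  a$pos <- as.integer(a$pos)
  o <- order(a$chrom, a$pos)
  a <- a[o, c("chrom", "pos", "rate", "cm")]
  rownames(a) <- NULL
  new("GeneticMap", anchors = a)
}

#' Construct a SummaryStats object
#'
#' @param trait Trait label.
#' @param records data.frame with columns `id`, `chrom`, `pos`, `pvalue`,
#'   `eaf`; sorted internally by (chrom, pos).
#' @return A [SummaryStats-class].
#' @export
SummaryStats <- function(trait, records) {
  r <- DataFrame(as.data.frame(records))
  r$chrom <- as.character(r$chrom)
  r$pos <- as.integer(r$pos)
  o <- order(r$chrom, r$pos)
  r <- r[o, c("id", "chrom", "pos", "pvalue", "eaf")]
  rownames(r) <- NULL
  new("SummaryStats", trait = as.character(trait), records = r)
}

## ---- accessors -------------------------------------------------------------

#' @rdname HaplotypePanel-class
#' @export
setMethod("variantTable", "HaplotypePanel", function(x) x@variants)
#' @rdname GenotypeMatrix-class
#' @export
setMethod("variantTable", "GenotypeMatrix", function(x) x@variants)
#' @rdname ArrayDesign-class
#' @export
setMethod("variantTable", "ArrayDesign", function(x)
  x@entries[, c("id", "chrom", "pos", "ref", "alt")])

#' @rdname HaplotypePanel-class
#' @export
setMethod("variantIds", "HaplotypePanel", function(x) as.character(x@variants$id))
#' @rdname GenotypeMatrix-class
#' @export
setMethod("variantIds", "GenotypeMatrix", function(x) as.character(x@variants$id))
#' @rdname ArrayDesign-class
#' @export
setMethod("variantIds", "ArrayDesign", function(x) as.character(x@entries$id))

#' @rdname HaplotypePanel-class
#' @export
setMethod("alleleMatrix", "HaplotypePanel", function(x) x@alleles)

#' @rdname HaplotypePanel-class
#' @export
setMethod("mafs", "HaplotypePanel", function(x) {
  stats::setNames(x@variants$maf, x@variants$id)
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("mafs", "GenotypeMatrix", function(x) {
  f <- colMeans(x@dosages, na.rm = TRUE) / 2
  stats::setNames(pmin(f, 1 - f), x@variants$id)
})

#' @rdname HaplotypePanel-class
#' @export
setMethod("nVariants", "HaplotypePanel", function(x) nrow(x@variants))
#' @rdname GenotypeMatrix-class
#' @export
setMethod("nVariants", "GenotypeMatrix", function(x) nrow(x@variants))

#' @rdname HaplotypePanel-class
#' @export
setMethod("nHaplotypes", "HaplotypePanel", function(x) nrow(x@alleles))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dosageMatrix", "GenotypeMatrix", function(x) x@dosages)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) x@samples)

#' @rdname GeneticMap-class
#' @export
setMethod("mapAnchors", "GeneticMap", function(x) x@anchors)

#' @rdname SummaryStats-class
#' @export
setMethod("statRecords", "SummaryStats", function(x) x@records)

#' @rdname SummaryStats-class
#' @export
setMethod("traitName", "SummaryStats", function(x) x@trait)

#' @rdname ArrayDesign-class
#' @export
setMethod("designEntries", "ArrayDesign", function(x) x@entries)

## ---- show methods ----------------------------------------------------------

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d haplotypes x %d variants on %d chromosome(s)\n",
              nrow(object@alleles), nrow(object@variants),
              length(unique(object@variants$chrom))))
  if (nrow(object@variants))
    cat(sprintf("  MAF: mean %.3f, %d monomorphic\n",
                mean(object@variants$maf), sum(object@variants$maf == 0)))
})

setMethod("show", "GenotypeMatrix", function(object) {
  miss <- if (length(object@dosages)) mean(is.na(object@dosages)) else 0
  cat(sprintf("GenotypeMatrix: %d samples x %d variants (%.2f%% missing)\n",
              length(object@samples), nrow(object@variants), 100 * miss))
})

setMethod("show", "GeneticMap", function(object) {
  a <- object@anchors
  cat(sprintf("GeneticMap: %d anchors on %d chromosome(s), %.3f cM total\n",
              nrow(a), length(unique(a$chrom)),
              sum(tapply(a$cm, a$chrom, function(z) max(z) - min(z)))))
})

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats for trait '%s': %d records, min p = %.3g\n",
              object@trait, nrow(object@records),
              if (nrow(object@records)) min(object@records$pvalue) else NA))
})

setMethod("show", "ArrayDesign", function(object) {
  cats <- sub(":.*$", "", unlist(object@entries$tags, use.names = FALSE))
  cat(sprintf("ArrayDesign: %d unique variants, %d tags\n",
              nrow(object@entries), length(cats)))
  if (length(cats)) {
    tab <- sort(table(cats), decreasing = TRUE)
    cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "KinshipResult", function(object) {
  cat(sprintf("KinshipResult %s-%s: k=(%.3f, %.3f, %.3f), pihat=%.3f [%d SNPs]\n",
              object@pair[1], object@pair[2], object@k0, object@k1,
              object@k2, object@pihat, object@nSnpsUsed))
})

setMethod("show", "OverlapTestResult", function(object) {
  cat(sprintf(paste0("OverlapTestResult: observed %d (%.1f%% of max), ",
                     "expected %.2f, p = %.4g (%d replicates)\n"),
              object@nOverlap, 100 * object@propMax, object@expected,
              object@pEnrichment, object@nSim))
})

setMethod("show", "LambdaGC", function(object) {
  cat(sprintf("LambdaGC: %.4f over %d SNPs [%s]\n",
              object@lambda, object@nSnps, object@snpSetLabel))
})

## pihat / k accessors used downstream
#' @rdname KinshipResult-class
#' @param x A KinshipResult.
#' @export
kHat <- function(x) c(k0 = x@k0, k1 = x@k1, k2 = x@k2)

#' @rdname KinshipResult-class
#' @export
piHat <- function(x) x@pihat

#' @rdname LambdaGC-class
#' @param x A LambdaGC.
#' @export
lambdaValue <- function(x) x@lambda

#' @rdname OverlapTestResult-class
#' @param x An OverlapTestResult.
#' @export
overlapP <- function(x) x@pEnrichment
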