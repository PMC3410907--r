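#' @name ld
#' @title Pairwise linkage disequilibrium and derived operations
#'
#' @description
#' The quantitative core of the package: squared allelic correlation
#' (r-squared) from phased haplotypes or from unphased genotypes via EM,
#' greedy LD pruning, tag coverage and the minor-allele-frequency spectrum.
#'
#' For phased 0/1 haplotype columns, r-squared equals
#' `D^2 / (pA(1-pA) pB(1-pB))` with `D = pAB - pA pB`, which is exactly the
#' squared Pearson correlation of the two allele-indicator columns; the
#' implementation exploits that identity.
NULL

## Default MAF bin edges: covers the design-relevant cut points .02 and .05.
.DEFAULT_MAF_BINS <- c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)

## Default LD horizon: r2 beyond this distance (or across chromosomes) is
## treated as 0 in pruning/coverage searches.
.DEFAULT_LD_HORIZON <- 1e6

## Squared correlation of haplotype column i against columns js (vectorized).
.r2ColVec <- function(a, i, js) {
  x <- a[, i]
  y <- a[, js, drop = FALSE]
  n <- nrow(a)
  sx <- sum(x); sy <- colSums(y)
  num <- (colSums(x * y) - sx * sy / n)
  den <- (sx - sx^2 / n) * (sy - sy^2 / n)
  r2 <- ifelse(den > 0, num^2 / den, NA_real_)
  pmin(pmax(r2, 0), 1)
}

#' Phased r-squared between two variants
#'
#' @param panel A [HaplotypePanel-class].
#' @param i,j Variant ids or column indices.
#' @return r-squared in \[0, 1\].
#' @examples
#' sim <- simulatePanel(PanelSimConfig(nHaplotypes = 40, regionLength = 5e4,
#'                                     seed = 1))
#' r2Phased(sim$panel, 1, 2)
#' @export
r2Phased <- function(panel, i, j) {
  stopifnot(is(panel, "HaplotypePanel"))
  if (is.character(i)) i <- .idIndex(panel, i)
  if (is.character(j)) j <- .idIndex(panel, j)
  a <- panel@alleles
  for (k in c(i, j)) {
    m <- mean(a[, k])
    if (m == 0 || m == 1)
      stop("LD undefined: variant '", variantIds(panel)[k], "' is monomorphic")
  }
  unname(.r2ColVec(a, i, j)[1])
}

#' Unphased r-squared via EM haplotype-frequency estimation
#'
#' Estimates the four two-locus haplotype frequencies from unphased dosages
#' by EM over the double-heterozygote phase ambiguity, initialized at
#' linkage equilibrium, then computes r-squared from the converged
#' frequencies. Samples with a missing dosage at either variant are
#' excluded.
#'
#' @param geno A [GenotypeMatrix-class].
#' @param i,j Variant ids or column indices.
#' @param maxIter Maximum EM iterations.
#' @param tol Convergence tolerance on the haplotype-frequency change.
#' @return r-squared in \[0, 1\]. Warns (and returns the last iterate) on
#'   non-convergence.
#' @export
r2UnphasedEM <- function(geno, i, j, maxIter = 100L, tol = 1e-8) {
  stopifnot(is(geno, "GenotypeMatrix"))
  if (is.character(i)) i <- .idIndex(geno, i)
  if (is.character(j)) j <- .idIndex(geno, j)
  gi <- geno@dosages[, i]
  gj <- geno@dosages[, j]
  keep <- !is.na(gi) & !is.na(gj)
  gi <- gi[keep]; gj <- gj[keep]
  if (!length(gi)) stop("no complete genotype pairs for variants ", i, ", ", j)
  pA <- mean(gi) / 2
  pB <- mean(gj) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("LD undefined: a variant is monomorphic among complete pairs")
  n <- table(factor(gi, 0:2), factor(gj, 0:2))
  ## haplotype copies fixed by unambiguous genotype cells
  fix00 <- 2 * n[1, 1] + n[1, 2] + n[2, 1]
  fix01 <- 2 * n[1, 3] + n[1, 2] + n[2, 3]
  fix10 <- 2 * n[3, 1] + n[2, 1] + n[3, 2]
  fix11 <- 2 * n[3, 3] + n[3, 2] + n[2, 3]
  ndh <- n[2, 2]                       # double heterozygotes: ambiguous phase
  tot <- 2 * length(gi)
  p <- c(`00` = (1 - pA) * (1 - pB), `01` = (1 - pA) * pB,
         `10` = pA * (1 - pB), `11` = pA * pB)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    cis <- p["00"] * p["11"]
    trans <- p["01"] * p["10"]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    pNew <- c(fix00 + ndh * w, fix01 + ndh * (1 - w),
              fix10 + ndh * (1 - w), fix11 + ndh * w) / tot
    names(pNew) <- names(p)
    if (max(abs(pNew - p)) < tol) { p <- pNew; converged <- TRUE; break }
    p <- pNew
  }
  if (!converged)
    warning("EM did not converge in ", maxIter, " iterations; returning last iterate")
  qA <- p["11"] + p["10"]
  qB <- p["11"] + p["01"]
  D <- p["11"] - qA * qB
  r2 <- D^2 / (qA * (1 - qA) * qB * (1 - qB))
  unname(pmin(pmax(r2, 0), 1))
}

## Pairwise r2 dispatch used by pruning/selection: phased panels use the
## closed-form column correlation, genotype matrices the EM estimator.
.r2PairFun <- function(x) {
  if (is(x, "HaplotypePanel")) {
    a <- x@alleles
    function(i, j) {
      m1 <- mean(a[, i]); m2 <- mean(a[, j])
      if (m1 %in% c(0, 1) || m2 %in% c(0, 1)) return(0)
      .r2ColVec(a, i, j)
    }
  } else if (is(x, "GenotypeMatrix")) {
    function(i, j) {
      r2 <- tryCatch(r2UnphasedEM(x, i, j), error = function(e) 0)
      r2
    }
  } else stop("need a HaplotypePanel or GenotypeMatrix")
}

#' @describeIn ldPrune Greedy left-to-right pruning on either substrate.
#'
#' Scans candidates in (chrom, pos) order; a candidate is retained iff its
#' r-squared with every already-retained variant within `windowBp` on the
#' same chromosome is `<= r2Max`. Ties therefore resolve leftmost-wins and
#' the output is deterministic and idempotent.
#' @export
setMethod("ldPrune", "ANY", function(x, ids = variantIds(x), r2Max = 0.3,
                                     windowBp = 1e6L, ...) {
  stopifnot(r2Max >= 0, r2Max <= 1)
  idx <- .idIndex(x, ids)
  v <- variantTable(x)
  ord <- idx[order(v$chrom[idx], v$pos[idx])]
  r2fun <- .r2PairFun(x)
  kept <- integer(0)
  for (i in ord) {
    near <- kept[v$chrom[kept] == v$chrom[i] &
                 abs(v$pos[kept] - v$pos[i]) <= windowBp]
    ok <- TRUE
    for (k in rev(near)) {          # nearest retained first: fails fastest
      if (r2fun(k, i) > r2Max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  as.character(v$id[kept])
})

#' Tagging coverage of a target SNP set by a tag SNP set
#'
#' A target counts as covered iff it is itself a tag, or its maximum
#' r-squared with any tag on the same chromosome within `ldHorizonBp` is at
#' least `r2Threshold`. Coverage is reported overall and per MAF bin.
#'
#' @param panel A [HaplotypePanel-class] containing both sets.
#' @param targets,tags Variant ids (nonempty; subsets of the panel).
#' @param r2Threshold Tagging threshold (0.8 for "strong LD" coverage).
#' @param ldHorizonBp Maximum tag search distance; cross-chromosome r2 is 0.
#' @param bins MAF bin edges partitioning \[0, 0.5\].
#' @return List with `overall` (fraction covered) and `perBin`
#'   (data.frame: bin, nTargets, nCovered, fraction).
#' @export
coverageFraction <- function(panel, targets, tags, r2Threshold = 0.8,
                             ldHorizonBp = .DEFAULT_LD_HORIZON,
                             bins = .DEFAULT_MAF_BINS) {
  stopifnot(is(panel, "HaplotypePanel"))
  if (!length(targets)) stop("targets must be nonempty")
  if (!length(tags)) stop("tags must be nonempty")
  ti <- .idIndex(panel, targets)
  gi <- .idIndex(panel, tags)
  v <- panel@variants
  a <- panel@alleles
  poly <- colMeans(a) > 0 & colMeans(a) < 1
  covered <- logical(length(ti))
  isTag <- ti %in% gi
  covered[isTag] <- TRUE
  for (k in which(!isTag)) {
    i <- ti[k]
    if (!poly[i]) next
    cand <- gi[v$chrom[gi] == v$chrom[i] &
               abs(v$pos[gi] - v$pos[i]) <= ldHorizonBp]
    cand <- cand[poly[cand]]
    if (!length(cand)) next
    covered[k] <- max(.r2ColVec(a, i, cand)) >= r2Threshold
  }
  mafT <- v$maf[ti]
  lab <- .mafBinLabels(bins)
  binOf <- .mafBinAssign(mafT, bins)
  perBin <- data.frame(
    bin = lab,
    nTargets = as.integer(table(factor(binOf, levels = lab))),
    nCovered = as.integer(tapply(covered, factor(binOf, levels = lab), sum,
                                 default = 0L)))
  perBin$fraction <- ifelse(perBin$nTargets > 0,
                            perBin$nCovered / perBin$nTargets, NA_real_)
  list(overall = mean(covered), perBin = perBin)
}

.checkBins <- function(bins) {
  if (length(bins) < 2 || bins[1] != 0 || bins[length(bins)] != 0.5 ||
      is.unsorted(bins, strictly = TRUE))
    stop("bins must be strictly increasing edges from 0 to 0.5")
  bins
}

.mafBinLabels <- function(bins) {
  .checkBins(bins)
  c("monomorphic",
    sprintf("(%g,%g]", bins[-length(bins)], bins[-1]))
}

.mafBinAssign <- function(maf, bins) {
  lab <- .mafBinLabels(bins)
  out <- character(length(maf))
  mono <- maf == 0
  out[mono] <- "monomorphic"
  out[!mono] <- lab[-1][cut(maf[!mono], bins, labels = FALSE)]
  out
}

#' Minor-allele-frequency spectrum
#'
#' Fraction of variants falling in each MAF bin; monomorphic variants
#' (MAF = 0) are reported as their own bin. Fractions sum to 1.
#'
#' @param x A [HaplotypePanel-class], [GenotypeMatrix-class] or numeric
#'   vector of MAFs.
#' @param bins Strictly increasing bin edges from 0 to 0.5; bin k is
#'   `(bins[k], bins[k+1]]`.
#' @return Named numeric vector of fractions ("monomorphic" first).
#' @export
mafSpectrum <- function(x, bins = .DEFAULT_MAF_BINS) {
  maf <- if (is.numeric(x)) x else mafs(x)
  maf <- maf[!is.na(maf)]
  lab <- .mafBinLabels(bins)
  if (!length(maf)) return(stats::setNames(rep(NA_real_, length(lab)), lab))
  tab <- table(factor(.mafBinAssign(maf, bins), levels = lab))
  as.numeric(tab) / length(maf) -> fr
  stats::setNames(fr, lab)
}
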