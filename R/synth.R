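#' @name synth
#' @title Seeded synthetic-data generators
#'
#' @description
#' Generators for every input the toolkit consumes, with known ground
#' truth: haplotype panels with block LD punctuated by recombination
#' hotspots (a founder-mosaic model, not a coalescent — it produces LD
#' texture, not population-genetic realism), pedigree genotypes with
#' realized IBD fractions, stratified case-control studies under the
#' Balding-Nichols construction, and GWAS summary statistics with planted
#' causal signals propagated through LD analytically. Every generator is
#' deterministic given its seed.
NULL

#' Configuration for the haplotype-panel simulator
#'
#' Founder haplotypes are drawn site-wise from a `1/x` minor-allele
#' frequency law truncated to `[1/(2 nHaplotypes), 0.5]`; the remaining
#' haplotypes are founder mosaics with crossovers placed as a Poisson
#' process whose intensity follows the genetic map (`backgroundRate`
#' everywhere except inside hotspots).
#'
#' @param nHaplotypes Total haplotypes in the panel.
#' @param regionLength Region length in bp.
#' @param nFounders Number of founder haplotypes (<= `nHaplotypes`).
#' @param snpDensity SNPs per kb.
#' @param hotspots `data.frame(start, end, rate)` of hotspot intervals
#'   (bp, cM/Mb), or NULL.
#' @param backgroundRate Background recombination rate, cM/Mb.
#' @param mosaicGenerations Effective generation depth of the founder
#'   mosaic: descendant crossover intensity is the map intensity times this
#'   factor, emulating the recombination a real panel accumulates over many
#'   meioses (default 100). LD block scale shrinks as it grows.
#' @param chrom Chromosome label.
#' @param seed RNG seed fixing all randomness.
#' @return A validated config list for [simulatePanel].
#' @export
PanelSimConfig <- function(nHaplotypes, regionLength, nFounders = 10L,
                           snpDensity = 1, hotspots = NULL,
                           backgroundRate = 1, mosaicGenerations = 100,
                           chrom = "1", seed = 1L) {
  stopifnot(nHaplotypes > 0, regionLength > 0, nFounders <= nHaplotypes,
            backgroundRate >= 0, snpDensity > 0, mosaicGenerations > 0)
  if (!is.null(hotspots)) {
    stopifnot(all(c("start", "end", "rate") %in% names(hotspots)),
              all(hotspots$rate >= 0), all(hotspots$start < hotspots$end))
    hotspots <- hotspots[order(hotspots$start), , drop = FALSE]
  }
  structure(list(nHaplotypes = as.integer(nHaplotypes),
                 regionLength = as.integer(regionLength),
                 nFounders = as.integer(nFounders), snpDensity = snpDensity,
                 hotspots = hotspots, backgroundRate = backgroundRate,
                 mosaicGenerations = mosaicGenerations,
                 chrom = as.character(chrom), seed = as.integer(seed)),
            class = "PanelSimConfig")
}

## Build the map implied by a PanelSimConfig: anchors at region ends and
## hotspot edges; each anchor's rate is the rate of the following interval.
.configMap <- function(cfg) {
  pos <- c(1L, cfg$regionLength)
  if (!is.null(cfg$hotspots))
    pos <- sort(unique(c(pos, cfg$hotspots$start, cfg$hotspots$end)))
  rateAt <- function(p) {        # rate of interval starting at p
    r <- cfg$backgroundRate
    if (!is.null(cfg$hotspots)) {
      inHot <- cfg$hotspots$start <= p & p < cfg$hotspots$end
      if (any(inHot)) r <- cfg$hotspots$rate[which(inHot)[1]]
    }
    r
  }
  rates <- vapply(pos, rateAt, numeric(1))
  cm <- c(0, cumsum(diff(pos) * rates[-length(rates)] / 1e6))
  GeneticMap(data.frame(chrom = cfg$chrom, pos = pos, rate = rates, cm = cm))
}

#' Simulate a haplotype panel and its genetic map
#'
#' @param cfg A [PanelSimConfig].
#' @return List with `panel` ([HaplotypePanel-class]) and `map`
#'   ([GeneticMap-class] with anchors at hotspot edges and region ends).
#' @examples
#' sim <- simulatePanel(PanelSimConfig(nHaplotypes = 100, regionLength = 1e5,
#'                                     seed = 7))
#' sim$panel
#' @export
simulatePanel <- function(cfg) {
  stopifnot(inherits(cfg, "PanelSimConfig"))
  map <- .configMap(cfg)
  .withSeed(cfg$seed, {
    L <- cfg$regionLength
    nSnps <- max(2L, as.integer(round(L / 1000 * cfg$snpDensity)))
    pos <- sort(sample.int(L, nSnps))
    lo <- 1 / (2 * cfg$nHaplotypes)
    freq <- lo * (0.5 / lo)^stats::runif(nSnps)       # 1/x law on [lo, 0.5]
    founders <- matrix(stats::rbinom(cfg$nFounders * nSnps, 1L,
                                     rep(freq, each = cfg$nFounders)),
                       nrow = cfg$nFounders)
    nDesc <- cfg$nHaplotypes - cfg$nFounders
    totalCm <- interpolateCm(map, cfg$chrom, L)
    desc <- matrix(0L, nrow = nDesc, ncol = nSnps)
    for (d in seq_len(nDesc)) {
      nx <- stats::rpois(1, totalCm / 100 * cfg$mosaicGenerations)
      cuts <- sort(cmToBp(map, cfg$chrom, stats::runif(nx, 0, totalCm)))
      bounds <- c(0, cuts, L + 1)
      seg <- findInterval(pos, bounds)                # segment index per SNP
      src <- sample.int(cfg$nFounders, length(bounds) - 1L, replace = TRUE)
      desc[d, ] <- founders[cbind(src[seg], seq_len(nSnps))]
    }
    alleles <- rbind(founders, desc)
    panel <- HaplotypePanel(
      data.frame(id = sprintf("snp%05d", seq_len(nSnps)), chrom = cfg$chrom,
                 pos = pos),
      alleles)
    list(panel = panel, map = map)
  })
}

#' Specify a pedigree
#'
#' @param id Individual ids, parents preceding children.
#' @param father,mother Parent ids or NA for founders.
#' @return A validated pedigree data.frame for [dropPedigree].
#' @export
PedigreeSpec <- function(id, father = NA, mother = NA) {
  ped <- data.frame(id = as.character(id), father = as.character(father),
                    mother = as.character(mother), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(ped))) {
    for (p in c(ped$father[k], ped$mother[k])) {
      if (!is.na(p) && !(p %in% ped$id[seq_len(k - 1L)]))
        stop("parent '", p, "' of '", ped$id[k], "' must precede it")
    }
  }
  if (any(xor(is.na(ped$father), is.na(ped$mother))))
    stop("individuals must have either both parents or neither")
  ped
}

## One meiosis: recombine a parent's two gametes (segment lists) into a
## child gamete, with crossovers from the genetic map.
.meiose <- function(g1, g2, map, chrom, L) {
  totalCm <- interpolateCm(map, chrom, L)
  nx <- stats::rpois(1, totalCm / 100)
  cuts <- sort(cmToBp(map, chrom, stats::runif(nx, 0, totalCm)))
  first <- sample.int(2L, 1L)
  bounds <- c(0, cuts, L)
  segs <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    src <- if ((k + first) %% 2L == 0L) g1 else g2
    s <- bounds[k]; e <- bounds[k + 1L]
    if (s >= e) next
    keep <- src$end > s & src$start < e
    sub <- src[keep, , drop = FALSE]
    sub$start <- pmax(sub$start, s)
    sub$end <- pmin(sub$end, e)
    segs[[length(segs) + 1L]] <- sub
  }
  do.call(rbind, segs)
}

## Allele vector of a gamete at the panel's SNP positions.
.gameteAlleles <- function(g, pos, alleles) {
  seg <- findInterval(pos, g$start, rightmost.closed = FALSE)
  seg[seg < 1] <- 1L
  alleles[cbind(g$lab[seg], seq_along(pos))]
}

#' Drop a pedigree through a haplotype panel
#'
#' Founders receive panel haplotypes without replacement; children receive
#' recombinant parental gametes with map-driven crossovers. The truth table
#' records *realized* genome-wide IBD0/1/2 fractions per pair, computed
#' exactly from the founder-haplotype segment labels (so k0+k1+k2 = 1 by
#' construction).
#'
#' @param panel A single-chromosome [HaplotypePanel-class] with at least
#'   `2 x nFounders` haplotypes.
#' @param map A [GeneticMap-class].
#' @param ped A pedigree from [PedigreeSpec].
#' @param seed RNG seed.
#' @return List with `geno` ([GenotypeMatrix-class]) and `truth`
#'   (data.frame: id1, id2, k0, k1, k2, pihat).
#' @export
dropPedigree <- function(panel, map, ped, seed = 1L) {
  stopifnot(is(panel, "HaplotypePanel"))
  v <- panel@variants
  if (length(unique(v$chrom)) != 1L)
    stop("dropPedigree expects a single-chromosome panel")
  chrom <- v$chrom[1]
  L <- max(v$pos)
  founders <- ped$id[is.na(ped$father)]
  if (2L * length(founders) > nrow(panel@alleles))
    stop("panel has too few haplotypes for ", length(founders), " founders")
  .withSeed(seed, {
    hapIdx <- sample.int(nrow(panel@alleles), 2L * length(founders))
    gam <- list()
    for (k in seq_along(ped$id)) {
      ind <- ped$id[k]
      if (is.na(ped$father[k])) {
        w <- which(founders == ind)
        gam[[ind]] <- list(
          data.frame(start = 0, end = L, lab = hapIdx[2L * w - 1L]),
          data.frame(start = 0, end = L, lab = hapIdx[2L * w]))
      } else {
        fg <- gam[[ped$father[k]]]
        mg <- gam[[ped$mother[k]]]
        gam[[ind]] <- list(.meiose(fg[[1]], fg[[2]], map, chrom, L),
                           .meiose(mg[[1]], mg[[2]], map, chrom, L))
      }
    }
    pos <- v$pos
    dos <- t(vapply(ped$id, function(ind)
      .gameteAlleles(gam[[ind]][[1]], pos, panel@alleles) +
      .gameteAlleles(gam[[ind]][[2]], pos, panel@alleles),
      integer(length(pos))))
    geno <- GenotypeMatrix(dos, as.data.frame(v), samples = ped$id)
    pairs <- utils::combn(ped$id, 2L)
    truth <- data.frame(id1 = pairs[1, ], id2 = pairs[2, ],
                        k0 = NA_real_, k1 = NA_real_, k2 = NA_real_)
    for (p in seq_len(ncol(pairs))) {
      kk <- .realizedIbd(gam[[pairs[1, p]]], gam[[pairs[2, p]]], L)
      truth[p, c("k0", "k1", "k2")] <- kk
    }
    truth$pihat <- truth$k2 + truth$k1 / 2
    list(geno = geno, truth = truth)
  })
}

## Exact realized IBD fractions from segment labels of two individuals.
.realizedIbd <- function(ga, gb, L) {
  cuts <- sort(unique(c(0, L, ga[[1]]$start, ga[[1]]$end, ga[[2]]$start,
                        ga[[2]]$end, gb[[1]]$start, gb[[1]]$end,
                        gb[[2]]$start, gb[[2]]$end)))
  cuts <- cuts[cuts >= 0 & cuts <= L]
  mid <- (cuts[-length(cuts)] + cuts[-1]) / 2
  len <- diff(cuts)
  labAt <- function(g, x) g$lab[findInterval(x, g$start)]
  la1 <- labAt(ga[[1]], mid); la2 <- labAt(ga[[2]], mid)
  lb1 <- labAt(gb[[1]], mid); lb2 <- labAt(gb[[2]], mid)
  shared <- integer(length(mid))
  for (k in seq_along(mid)) {
    a <- c(la1[k], la2[k]); b <- c(lb1[k], lb2[k])
    s <- 0L
    for (lab in unique(a)) s <- s + min(sum(a == lab), sum(b == lab))
    shared[k] <- min(s, 2L)
  }
  c(k0 = sum(len[shared == 0L]) / L, k1 = sum(len[shared == 1L]) / L,
    k2 = sum(len[shared == 2L]) / L)
}

#' Simulate a stratified case-control study (Balding-Nichols model)
#'
#' Two subpopulation allele-frequency vectors are drawn around `baseFreqs`
#' from the Balding-Nichols Beta construction (shape parameters
#' `p(1-fst)/fst` and `(1-p)(1-fst)/fst`, so each subpopulation frequency
#' has mean `p` and variance `fst * p(1-p)`); genotypes are Binomial(2,
#' subpopulation frequency) and the phenotype is independent of genotype
#' given population. `fst` may be a scalar or a per-SNP vector, so a single
#' study can mix differentiated (confounded) and undifferentiated (null)
#' SNPs; `fst = 0` makes both subpopulation frequencies equal `baseFreqs`
#' exactly.
#'
#' @param baseFreqs Ancestral allele frequencies, strictly inside (0, 1).
#' @param fst Differentiation parameter(s) in \[0, 1).
#' @param nCases,nControls Sample counts.
#' @param casePop1Fraction,controlPop1Fraction Fraction of cases/controls
#'   drawn from subpopulation 1 (exact counts, rounded).
#' @param seed RNG seed.
#' @param spacingBp Inter-SNP spacing for the synthetic positions
#'   (default 1 Mb, a genome-wide near-independent panel).
#' @param chrom Chromosome label.
#' @return List with `geno` ([GenotypeMatrix-class]), `phenotype` (0/1,
#'   1 = case), `population` (1/2) and the two subpopulation frequency
#'   vectors `popFreqs`.
#' @export
simulateStratifiedCC <- function(baseFreqs, fst, nCases, nControls,
                                 casePop1Fraction = 0.5,
                                 controlPop1Fraction = 0.5, seed = 1L,
                                 spacingBp = 1e6, chrom = "1") {
  if (any(baseFreqs <= 0 | baseFreqs >= 1))
    stop("base frequencies must lie strictly inside (0, 1)")
  m <- length(baseFreqs)
  fst <- rep_len(fst, m)
  stopifnot(all(fst >= 0 & fst < 1),
            casePop1Fraction >= 0, casePop1Fraction <= 1,
            controlPop1Fraction >= 0, controlPop1Fraction <= 1)
  .withSeed(seed, {
    drawPop <- function() {
      p <- baseFreqs
      w <- fst > 0
      if (any(w))
        p[w] <- stats::rbeta(sum(w), baseFreqs[w] * (1 - fst[w]) / fst[w],
                             (1 - baseFreqs[w]) * (1 - fst[w]) / fst[w])
      pmin(pmax(p, 1e-6), 1 - 1e-6)
    }
    popFreqs <- list(drawPop(), drawPop())
    nCase1 <- round(nCases * casePop1Fraction)
    nCtrl1 <- round(nControls * controlPop1Fraction)
    population <- c(rep(1L, nCase1), rep(2L, nCases - nCase1),
                    rep(1L, nCtrl1), rep(2L, nControls - nCtrl1))
    phenotype <- c(rep(1L, nCases), rep(0L, nControls))
    n <- length(population)
    dos <- matrix(0L, nrow = n, ncol = m)
    for (pop in 1:2) {
      rows <- which(population == pop)
      if (!length(rows)) next
      dos[rows, ] <- matrix(stats::rbinom(length(rows) * m, 2L,
                                          rep(popFreqs[[pop]], each = length(rows))),
                            nrow = length(rows))
    }
    perChrom <- 200L                 # synthetic chromosomes of 200 SNPs
    j <- seq_len(m)
    geno <- GenotypeMatrix(
      dos, data.frame(id = sprintf("snp%05d", j),
                      chrom = sprintf("%s_%03d", chrom, (j - 1L) %/% perChrom + 1L),
                      pos = as.integer(((j - 1L) %% perChrom + 1L) * spacingBp)),
      samples = sprintf("ind%05d", seq_len(n)))
    list(geno = geno, phenotype = phenotype, population = population,
         popFreqs = popFreqs)
  })
}

#' Simulate GWAS summary statistics with planted causal signals
#'
#' Per-SNP Wald statistics are generated analytically: the marginal effect
#' at SNP j is the causal effect propagated through LD,
#' `beta_j = sum_c r_jc beta_c` (signed allelic correlation to each causal
#' SNP within the LD horizon), its standard error is
#' `1/sqrt(2 n maf (1-maf))`, and `z = beta/se + N(0,1)`. SNPs unlinked to
#' any causal variant therefore carry uniform p-values under the null.
#' Monomorphic panel SNPs are skipped.
#'
#' @param panel A [HaplotypePanel-class].
#' @param causal `data.frame(id, beta)` of causal variants (ids must exist
#'   in the panel), or NULL for a pure null.
#' @param nStudy Effective study sample size.
#' @param trait Trait label.
#' @param seed RNG seed.
#' @param ldHorizonBp LD propagation horizon (default 1 Mb).
#' @return A [SummaryStats-class].
#' @export
simulateSummaryStats <- function(panel, causal = NULL, nStudy = 10000L,
                                 trait = "trait", seed = 1L,
                                 ldHorizonBp = .DEFAULT_LD_HORIZON) {
  stopifnot(is(panel, "HaplotypePanel"))
  v <- as.data.frame(panel@variants)
  a <- panel@alleles
  keep <- which(v$maf > 0)
  beta <- numeric(nrow(v))
  if (!is.null(causal) && nrow(as.data.frame(causal))) {
    causal <- as.data.frame(causal)
    ci <- .idIndex(panel, causal$id)
    for (k in seq_along(ci)) {
      i <- ci[k]
      if (v$maf[i] == 0) stop("causal SNP '", causal$id[k], "' is monomorphic")
      near <- keep[v$chrom[keep] == v$chrom[i] &
                   abs(v$pos[keep] - v$pos[i]) <= ldHorizonBp]
      r <- suppressWarnings(stats::cor(a[, i], a[, near]))
      r[is.na(r)] <- 0
      beta[near] <- beta[near] + as.numeric(r) * causal$beta[k]
    }
  }
  .withSeed(seed, {
    maf <- v$maf[keep]
    se <- 1 / sqrt(2 * nStudy * maf * (1 - maf))
    z <- beta[keep] / se + stats::rnorm(length(keep))
    p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
    SummaryStats(trait, data.frame(
      id = v$id[keep], chrom = v$chrom[keep], pos = v$pos[keep],
      pvalue = p, eaf = colMeans(a[, keep, drop = FALSE])))
  })
}
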