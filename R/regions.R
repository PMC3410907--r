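#' @name regions
#' @title Fine-mapping region construction
#'
#' @description
#' Regions are represented as [GenomicRanges::GRanges] (1-based inclusive
#' coordinates, matching VCF) with metadata columns `kind` ("SFM" or
#' "LFM"), `indexIds` and `traits` (CharacterList), and `provenance`, a
#' free-text audit of each boundary decision.
#'
#' A signal-fine-mapping (SFM) region starts from the span of all SNPs in
#' LD with the index SNP at `r2Seed` or above, then each boundary is
#' independently pushed outward to the inner edge of the nearest
#' recombination hotspot — provided that edge lies within `hotspotSearchCm`
#' — and otherwise extended by a fixed genetic-distance shoulder
#' (`shoulderCm`, 0.02 cM by default, roughly 20 kb on a 1 cM/Mb
#' background). A locus-fine-mapping (LFM) region additionally absorbs
#' every gene interval it overlaps, to transitive closure.
#' @importFrom GenomicRanges GRanges start end seqnames mcols mcols<- reduce
#'   findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Construct a fine-mapping region object
#'
#' @param chrom Chromosome.
#' @param start,end 1-based inclusive bp boundaries.
#' @param kind "SFM" or "LFM".
#' @param indexIds Character vector of index variant ids.
#' @param traits Character vector of source traits.
#' @param provenance Audit string for the boundary decisions.
#' @return A length-1 `GRanges` with the region metadata columns.
#' @export
fineMapRegion <- function(chrom, start, end, kind = c("SFM", "LFM"),
                          indexIds = character(), traits = character(),
                          provenance = "") {
  kind <- match.arg(kind)
  stopifnot(start <= end, start >= 1)
  gr <- GRanges(seqnames = as.character(chrom),
                ranges = IRanges(as.integer(start), as.integer(end)))
  mcols(gr)$kind <- kind
  mcols(gr)$indexIds <- S4Vectors::SimpleList(as.character(indexIds))
  mcols(gr)$traits <- S4Vectors::SimpleList(as.character(traits))
  mcols(gr)$provenance <- provenance
  gr
}

#' Build a signal-fine-mapping (SFM) region around an index SNP
#'
#' @param panel A [HaplotypePanel-class] providing the LD substrate.
#' @param map A [GeneticMap-class].
#' @param indexId Index variant id (must be polymorphic).
#' @param r2Seed LD threshold defining the seed span (default 0.5).
#' @param shoulderCm Genetic-distance shoulder applied when no hotspot is
#'   near (default 0.02 cM).
#' @param hotspotRate Hotspot detection threshold, cM/Mb (default 10).
#' @param hotspotSearchCm Maximum genetic distance from a seed boundary to
#'   a usable hotspot inner edge (default 0.1 cM); beyond this, "no hotspot
#'   nearby" and the shoulder rule fires.
#' @param ldHorizonBp LD partner search window (default 1 Mb).
#' @param trait Optional trait label recorded on the region.
#' @param shoulderMode `"fallback"` (default): the shoulder fires only when
#'   no hotspot is near. `"always"`: the shoulder is additionally applied
#'   beyond the hotspot edge (the alternative reading of the boundary rule).
#' @return A length-1 `GRanges` region with per-side provenance.
#' @export
buildSfmRegion <- function(panel, map, indexId, r2Seed = 0.5,
                           shoulderCm = 0.02, hotspotRate = 10,
                           hotspotSearchCm = 0.1,
                           ldHorizonBp = .DEFAULT_LD_HORIZON,
                           trait = character(),
                           shoulderMode = c("fallback", "always")) {
  shoulderMode <- match.arg(shoulderMode)
  stopifnot(is(panel, "HaplotypePanel"))
  idx <- .idIndex(panel, indexId)
  v <- panel@variants
  a <- panel@alleles
  m <- mean(a[, idx])
  if (m == 0 || m == 1) stop("index SNP '", indexId, "' is monomorphic")
  ch <- v$chrom[idx]
  cand <- which(v$chrom == ch & abs(v$pos - v$pos[idx]) <= ldHorizonBp)
  cand <- cand[cand != idx]
  poly <- colMeans(a[, cand, drop = FALSE])
  cand <- cand[poly > 0 & poly < 1]
  partners <- if (length(cand))
    cand[.r2ColVec(a, idx, cand) >= r2Seed] else integer(0)
  seedStart <- min(v$pos[c(idx, partners)])
  seedEnd <- max(v$pos[c(idx, partners)])
  hs <- detectHotspots(map, hotspotRate)
  hs <- hs[as.character(seqnames(hs)) == ch]

  resolve <- function(boundary, side) {
    bCm <- interpolateCm(map, ch, boundary)
    if (side == "left") {
      edges <- end(hs)[end(hs) <= boundary]          # inner (proximal) edges
      edge <- if (length(edges)) max(edges) else NA
    } else {
      edges <- start(hs)[start(hs) >= boundary]
      edge <- if (length(edges)) min(edges) else NA
    }
    hit <- !is.na(edge) &&
      abs(bCm - interpolateCm(map, ch, edge)) <= hotspotSearchCm
    if (hit) {
      newPos <- edge
      rule <- sprintf("%s: hotspot inner edge at %d (%.4f cM from seed)",
                      side, as.integer(edge),
                      abs(bCm - interpolateCm(map, ch, edge)))
      if (shoulderMode == "always") {
        eCm <- interpolateCm(map, ch, edge)
        newPos <- cmToBp(map, ch, eCm + if (side == "left") -shoulderCm else shoulderCm)
        rule <- paste0(rule, sprintf("; +%.3f cM shoulder", shoulderCm))
      }
    } else {
      newPos <- cmToBp(map, ch, bCm + if (side == "left") -shoulderCm else shoulderCm)
      rule <- sprintf("%s: no hotspot within %.3f cM; %.3f cM shoulder to %d",
                      side, hotspotSearchCm, shoulderCm, as.integer(round(newPos)))
    }
    list(pos = as.integer(round(newPos)), rule = rule)
  }

  L <- resolve(seedStart, "left")
  R <- resolve(seedEnd, "right")
  prov <- sprintf("seed [%d,%d] (r2>=%.2f, %d partners); %s; %s",
                  seedStart, seedEnd, r2Seed, length(partners), L$rule, R$rule)
  fineMapRegion(ch, max(1L, L$pos), R$pos, kind = "SFM",
                indexIds = indexId, traits = trait, provenance = prov)
}

#' Extend an SFM region to a locus-fine-mapping (LFM) region
#'
#' Boundaries grow to the union of the region and every overlapping gene
#' interval, repeated to transitive closure, so a chain of mutually
#' overlapping genes is absorbed in full. The result always contains the
#' input region.
#'
#' @param sfm A region `GRanges` (as from [buildSfmRegion]).
#' @param genes Gene intervals: a `GRanges` or a data.frame with columns
#'   `chrom`, `start`, `end`, `name`.
#' @return The expanded region with `kind = "LFM"`.
#' @export
buildLfmRegion <- function(sfm, genes) {
  stopifnot(is(sfm, "GRanges"), length(sfm) == 1L)
  if (is.data.frame(genes))
    genes <- GRanges(seqnames = as.character(genes$chrom),
                     ranges = IRanges(genes$start, genes$end),
                     name = if (!is.null(genes$name)) genes$name
                            else paste0("gene", seq_len(nrow(genes))))
  ch <- as.character(seqnames(sfm))
  s <- start(sfm); e <- end(sfm)
  g <- genes[as.character(seqnames(genes)) == ch]
  absorbed <- character()
  repeat {
    ov <- which(start(g) <= e & end(g) >= s)
    ns <- min(s, start(g)[ov]); ne <- max(e, end(g)[ov])
    if (ns == s && ne == e) break
    s <- ns; e <- ne
    nm <- mcols(g)$name
    if (!is.null(nm)) absorbed <- union(absorbed, nm[ov])
  }
  prov <- paste0(mcols(sfm)$provenance, sprintf(
    "; LFM: %d gene(s) absorbed%s", length(absorbed),
    if (length(absorbed)) paste0(" (", paste(absorbed, collapse = ","), ")") else ""))
  fineMapRegion(ch, s, e, kind = "LFM",
                indexIds = unlist(mcols(sfm)$indexIds),
                traits = unlist(mcols(sfm)$traits), provenance = prov)
}

#' Merge overlapping fine-mapping regions
#'
#' Same-chromosome regions sharing at least one bp are merged into their
#' union; abutting-but-not-overlapping regions stay separate. Index ids and
#' traits of the constituents are concatenated (unique, order of first
#' appearance); a merged region's kind is "LFM" if any constituent is LFM.
#'
#' @param regions A region `GRanges` (concatenate with `c()`).
#' @return A disjoint, sorted region `GRanges`.
#' @export
mergeRegions <- function(regions) {
  stopifnot(is(regions, "GRanges"))
  if (length(regions) <= 1L)
    return(sort(GenomeInfoDb::sortSeqlevels(regions)))
  merged <- reduce(regions, min.gapwidth = 0L)
  ov <- findOverlaps(merged, regions)
  kind <- character(length(merged))
  idxL <- vector("list", length(merged))
  trtL <- vector("list", length(merged))
  provL <- character(length(merged))
  for (k in seq_along(merged)) {
    src <- subjectHits(ov)[queryHits(ov) == k]
    kind[k] <- if (any(mcols(regions)$kind[src] == "LFM")) "LFM" else "SFM"
    idxL[[k]] <- unique(unlist(mcols(regions)$indexIds[src]))
    trtL[[k]] <- unique(unlist(mcols(regions)$traits[src]))
    provL[k] <- paste0("merged from ", length(src), " region(s)")
  }
  mcols(merged)$kind <- kind
  mcols(merged)$indexIds <- S4Vectors::SimpleList(idxL)
  mcols(merged)$traits <- S4Vectors::SimpleList(trtL)
  mcols(merged)$provenance <- provL
  sort(GenomeInfoDb::sortSeqlevels(merged))
}

#' Enumerate catalog SNPs inside a fine-mapping region
#'
#' @param catalog A variant table (data.frame/DataFrame with `id`, `chrom`,
#'   `pos`, optionally `designable`) or an object with a [variantTable]
#'   method.
#' @param region A length-1 region `GRanges`.
#' @param requireDesignable Drop variants flagged `designable = FALSE`.
#' @return Character vector of variant ids in position order.
#' @export
enumerateFinemappingSnps <- function(catalog, region, requireDesignable = FALSE) {
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  v <- if (is.data.frame(catalog) || is(catalog, "DataFrame"))
    as.data.frame(catalog) else as.data.frame(variantTable(catalog))
  keep <- v$chrom == as.character(seqnames(region)) &
          v$pos >= start(region) & v$pos <= end(region)
  if (requireDesignable && !is.null(v$designable))
    keep <- keep & v$designable
  v <- v[keep, , drop = FALSE]
  as.character(v$id[order(v$pos)])
}
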