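#' Interpolate genetic position (cM) at base-pair coordinates
#'
#' Piecewise-linear between map anchors, constant beyond the outermost
#' anchors; monotone nondecreasing in `pos`.
#'
#' @param map A [GeneticMap-class].
#' @param chrom Chromosome name.
#' @param pos Base-pair position(s), 1-based.
#' @return Genetic position(s) in cM.
#' @export
interpolateCm <- function(map, chrom, pos) {
  a <- .chromAnchors(map, chrom)
  if (nrow(a) == 1L) return(rep(a$cm, length(pos)))
  stats::approx(a$pos, a$cm, xout = pos, rule = 2, ties = "ordered")$y
}

.chromAnchors <- function(map, chrom) {
  stopifnot(is(map, "GeneticMap"))
  a <- map@anchors
  a <- a[a$chrom == as.character(chrom), , drop = FALSE]
  if (!nrow(a)) stop("chromosome '", chrom, "' not present in the genetic map")
  as.data.frame(a)
}

#' Invert the genetic map: base-pair position at a genetic position
#'
#' Piecewise-linear inversion inside the anchored range (on a zero-rate
#' stretch the left edge is returned, so the inverse is deterministic).
#' Beyond the outermost anchors positions are extrapolated linearly at the
#' terminal interval's rate, falling back to 1 cM/Mb where that rate is 0 —
#' the conversion a flat background map implies.
#'
#' @param map A [GeneticMap-class].
#' @param chrom Chromosome name.
#' @param cm Genetic position(s), cM.
#' @return Base-pair position(s) (possibly < 1 when extrapolating far left;
#'   callers clamp as needed).
#' @export
cmToBp <- function(map, chrom, cm) {
  a <- .chromAnchors(map, chrom)
  n <- nrow(a)
  edgeRate <- function(i1, i2) {
    r <- (a$cm[i2] - a$cm[i1]) / (a$pos[i2] - a$pos[i1]) * 1e6
    if (is.na(r) || r <= 0) 1 else r
  }
  rateL <- if (n >= 2) edgeRate(1, 2) else 1
  rateR <- if (n >= 2) edgeRate(n - 1, n) else 1
  vapply(cm, function(t) {
    if (t <= a$cm[1]) return(a$pos[1] - (a$cm[1] - t) / rateL * 1e6)
    if (t >= a$cm[n]) return(a$pos[n] + (t - a$cm[n]) / rateR * 1e6)
    k <- findInterval(t, a$cm)
    if (a$cm[k + 1] > a$cm[k])
      a$pos[k] + (t - a$cm[k]) / (a$cm[k + 1] - a$cm[k]) *
        (a$pos[k + 1] - a$pos[k])
    else a$pos[k]
  }, numeric(1))
}

#' Detect recombination hotspots in a genetic map
#'
#' Computes the local rate of each inter-anchor interval as
#' `(delta cM / delta bp) * 1e6` and returns maximal runs of intervals at or
#' above `rateThreshold`, adjacent qualifying intervals merged. Output
#' intervals are disjoint and sorted.
#'
#' @param map A [GeneticMap-class].
#' @param rateThreshold Minimum local rate, cM/Mb (default 10, the
#'   conventional hotspot cutoff).
#' @return A [GenomicRanges::GRanges] with metadata column `meanRate`
#'   (bp-weighted mean rate over the merged interval).
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @export
detectHotspots <- function(map, rateThreshold = 10) {
  stopifnot(is(map, "GeneticMap"))
  out <- list()
  for (ch in unique(map@anchors$chrom)) {
    a <- .chromAnchors(map, ch)
    if (nrow(a) < 2) next
    dcm <- diff(a$cm)
    dbp <- diff(a$pos)
    rate <- dcm / dbp * 1e6
    hot <- rate >= rateThreshold
    if (!any(hot)) next
    r <- rle(hot)
    endIdx <- cumsum(r$lengths)
    startIdx <- endIdx - r$lengths + 1L
    for (k in which(r$values)) {
      i1 <- startIdx[k]; i2 <- endIdx[k]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = a$pos[i1], end = a$pos[i2 + 1L],
        meanRate = (a$cm[i2 + 1L] - a$cm[i1]) /
                   (a$pos[i2 + 1L] - a$pos[i1]) * 1e6)
    }
  }
  if (!length(out))
    return(GRanges(seqnames = character(), ranges = IRanges(), meanRate = numeric()))
  d <- do.call(rbind, out)
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  GRanges(seqnames = d$chrom, ranges = IRanges(d$start, d$end),
          meanRate = d$meanRate)
}
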