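#' @name io
#' @title Readers and writers for the standard exchange formats
#'
#' @description
#' VCF 4.x (phased GT) for haplotype panels, 4-column tab-delimited genetic
#' maps (chromosome, position bp, rate cM/Mb, cumulative cM), tab-delimited
#' per-trait summary statistics, BED for regions (written 0-based
#' half-open; all internal coordinates are 1-based inclusive, matching
#' VCF), and a CSV manifest for array designs. Every reader/writer pair is
#' a lossless round trip for the fields the format carries.
NULL

#' Read phased haplotypes from a VCF
#'
#' Retains biallelic SNP records whose GT fields are all phased ("|"
#' separated) and fully called; multiallelic, unphased or incompletely
#' called records are skipped with a message reporting the count.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param regionFilter Optional "chrom:start-end" restriction.
#' @return A [HaplotypePanel-class] with one row per haplotype (two per
#'   sample).
#' @export
readHaplotypeVcf <- function(path, regionFilter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcf@gt[, -1, drop = FALSE]                  # drop FORMAT column
  nIn <- nrow(fix)
  if (nIn == 0) stop("VCF contains no records")
  gtOnly <- sub(":.*$", "", gt)
  phased <- grepl("^[01]\\|[01]$", gtOnly)
  dim(phased) <- dim(gtOnly)
  biallelic <- !grepl(",", fix[, "ALT"]) & !is.na(fix[, "ALT"])
  keep <- biallelic & apply(phased, 1, all)
  if (!is.null(regionFilter)) {
    m <- regmatches(regionFilter,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", regionFilter))[[1]]
    if (length(m) != 4) stop("regionFilter must be 'chrom:start-end'")
    pos <- as.integer(fix[, "POS"])
    keep <- keep & fix[, "CHROM"] == m[2] &
            pos >= as.integer(m[3]) & pos <= as.integer(m[4])
  }
  nSkipped <- sum(biallelic & !apply(phased, 1, all))
  if (nSkipped > 0 || any(!biallelic))
    message(sum(!biallelic), " multiallelic and ", nSkipped,
            " unphased/incomplete record(s) skipped")
  if (!any(keep)) stop("no phased biallelic records", if (!is.null(regionFilter))
    paste0(" in ", regionFilter) else "")
  fix <- fix[keep, , drop = FALSE]
  gtOnly <- gtOnly[keep, , drop = FALSE]
  h1 <- substr(gtOnly, 1, 1) == "1"
  h2 <- substr(gtOnly, 3, 3) == "1"
  nVar <- nrow(fix); nSamp <- ncol(gtOnly)
  alleles <- matrix(0L, nrow = 2L * nSamp, ncol = nVar)
  alleles[2 * seq_len(nSamp) - 1, ] <- t(h1) * 1L
  alleles[2 * seq_len(nSamp), ] <- t(h2) * 1L
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  HaplotypePanel(
    data.frame(id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
               ref = fix[, "REF"], alt = fix[, "ALT"]),
    alleles)
}

#' Write a haplotype panel as a phased VCF
#'
#' @param panel A [HaplotypePanel-class] with an even haplotype count
#'   (haplotypes 2k-1 and 2k become sample k).
#' @param path Output path.
#' @export
writeHaplotypeVcf <- function(panel, path) {
  stopifnot(is(panel, "HaplotypePanel"))
  nh <- nrow(panel@alleles)
  if (nh %% 2 != 0) stop("haplotype count must be even to form diploid samples")
  v <- as.data.frame(panel@variants)
  nSamp <- nh / 2
  samp <- sprintf("sample%04d", seq_len(nSamp))
  a <- panel@alleles
  gtCols <- vapply(seq_len(nSamp), function(s)
    paste0(a[2 * s - 1, ], "|", a[2 * s, ]), character(nrow(v)))
  if (nrow(v) == 1) gtCols <- matrix(gtCols, nrow = 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samp), collapse = "\t")), con)
  body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT", gtCols)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a genetic map
#'
#' Tab-delimited with a header and columns chromosome, position (bp), rate
#' (cM/Mb), cumulative map (cM). Positions must be strictly increasing and
#' cM nondecreasing within each chromosome; violations raise an error
#' naming the offending line.
#'
#' @param path Map file.
#' @return A [GeneticMap-class].
#' @export
readGeneticMap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, header = TRUE)
  if (ncol(d) < 4) stop("genetic map needs 4 columns: chrom, pos, rate, cm")
  names(d)[1:4] <- c("chrom", "pos", "rate", "cm")
  for (ch in unique(d$chrom)) {
    rows <- which(d$chrom == ch)
    dp <- diff(d$pos[rows])
    if (any(dp <= 0)) {
      bad <- rows[which(dp <= 0)[1] + 1L]
      stop("non-increasing/duplicate position at line ", bad + 1L,
           " (chromosome ", ch, ")")
    }
    dc <- diff(d$cm[rows])
    if (any(dc < 0)) {
      bad <- rows[which(dc < 0)[1] + 1L]
      stop("decreasing cumulative cM at line ", bad + 1L,
           " (chromosome ", ch, ")")
    }
  }
  GeneticMap(d[, 1:4])
}

#' @rdname readGeneticMap
#' @param map A [GeneticMap-class].
#' @export
writeGeneticMap <- function(map, path) {
  stopifnot(is(map, "GeneticMap"))
  d <- as.data.frame(map@anchors)
  names(d) <- c("chrom", "position", "rate", "map")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-trait GWAS summary statistics
#'
#' Tab-delimited with header columns id, chrom, pos, pvalue, eaf. Records
#' are sorted by (chrom, pos); a p-value outside (0, 1\] raises an error
#' naming the row.
#'
#' @param path Summary-statistics file.
#' @param trait Trait label to attach.
#' @return A [SummaryStats-class].
#' @export
readSummaryStats <- function(path, trait) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, header = TRUE)
  need <- c("id", "chrom", "pos", "pvalue", "eaf")
  if (!all(need %in% names(d)))
    stop("summary statistics need columns: ", paste(need, collapse = ", "))
  bad <- which(d$pvalue <= 0 | d$pvalue > 1)
  if (length(bad))
    stop("p-value outside (0,1] at row ", bad[1], " (id ", d$id[bad[1]], ")")
  SummaryStats(trait, d[, need])
}

#' @rdname readSummaryStats
#' @param stats A [SummaryStats-class].
#' @export
writeSummaryStats <- function(stats, path) {
  stopifnot(is(stats, "SummaryStats"))
  utils::write.table(as.data.frame(stats@records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write fine-mapping regions as BED
#'
#' Internal 1-based inclusive coordinates become 0-based half-open BED
#' (start-1, end); the name column is `"<kind>:<index ids>:<traits>"` with
#' ids and traits comma-joined.
#'
#' @param regions A region `GRanges` (possibly empty).
#' @param path Output path.
#' @export
writeRegionsBed <- function(regions, path) {
  stopifnot(is(regions, "GRanges"))
  gr <- GRanges(seqnames(regions), IRanges::ranges(regions))
  if (length(regions))
    names(gr) <- sprintf("%s:%s:%s", mcols(regions)$kind,
                         vapply(mcols(regions)$indexIds, paste, "", collapse = ","),
                         vapply(mcols(regions)$traits, paste, "", collapse = ","))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname writeRegionsBed
#' @return `readRegionsBed` returns a `GRanges` with 1-based inclusive
#'   coordinates and the BED name column in `mcols()$name`.
#' @export
readRegionsBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  rtracklayer::import(path, format = "BED")
}

#' Write the array-design manifest
#'
#' One CSV row per unique SNP: id, chrom, pos, alleles (ref/alt),
#' semicolon-joined `category:trait` tags, semicolon-joined source traits,
#' and semicolon-joined alias ids collapsed into the entry.
#'
#' @param design An [ArrayDesign-class].
#' @param path Output path.
#' @export
writeManifest <- function(design, path) {
  stopifnot(is(design, "ArrayDesign"))
  e <- design@entries
  traits <- vapply(e$tags, function(t)
    paste(unique(sub("^[^:]*:", "", t)), collapse = ";"), "")
  d <- data.frame(id = e$id, chrom = e$chrom, pos = e$pos,
                  alleles = paste0(e$ref, "/", e$alt),
                  tags = vapply(e$tags, paste, "", collapse = ";"),
                  traits = traits,
                  aliases = vapply(e$aliases, paste, "", collapse = ";"))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
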