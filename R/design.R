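#' Replication-SNP selection configuration
#'
#' Defaults mirror the array's own pruning conventions: independence means
#' no pair of selected SNPs with r-squared above 0.3 within 1 Mb, and
#' candidates within 250 kb of an excluded known locus are dropped.
#'
#' @param nTarget SNPs to select per trait.
#' @param independenceR2 Maximum r-squared between selected SNPs.
#' @param independenceWindowBp Window within which independence is enforced.
#' @param exclusionBp Exclusion distance around known loci.
#' @return A validated config list.
#' @export
SelectionConfig <- function(nTarget = 5000L, independenceR2 = 0.3,
                            independenceWindowBp = 1e6, exclusionBp = 250000) {
  stopifnot(nTarget >= 1, independenceR2 >= 0, independenceR2 <= 1,
            independenceWindowBp >= 0, exclusionBp >= 0)
  structure(list(nTarget = as.integer(nTarget), independenceR2 = independenceR2,
                 independenceWindowBp = independenceWindowBp,
                 exclusionBp = exclusionBp), class = "SelectionConfig")
}

#' Select replication SNPs: top independent association signals
#'
#' Candidates are ranked by ascending p-value (ties broken by genomic
#' order) and accepted greedily: a candidate is kept iff its r-squared with
#' every previously accepted SNP within the independence window is at most
#' `independenceR2`, and it lies more than `exclusionBp` from every
#' excluded locus. Selection stops at `nTarget` or candidate exhaustion
#' (the latter logs a warning, not an error). Summary-stat variants absent
#' from the panel are skipped with a message.
#'
#' @param stats A [SummaryStats-class].
#' @param panel A [HaplotypePanel-class] providing LD.
#' @param cfg A [SelectionConfig].
#' @param excludeLoci Optional `data.frame(chrom, pos)` of known loci.
#' @return Character vector of selected ids, in acceptance order.
#' @export
selectReplicationSnps <- function(stats, panel, cfg = SelectionConfig(),
                                  excludeLoci = NULL) {
  stopifnot(is(stats, "SummaryStats"), is(panel, "HaplotypePanel"),
            inherits(cfg, "SelectionConfig"))
  r <- as.data.frame(stats@records)
  if (!nrow(r)) stop("summary statistics are empty")
  inPanel <- r$id %in% variantIds(panel)
  if (any(!inPanel))
    message(sum(!inPanel), " summary-stat variant(s) absent from panel; skipped")
  r <- r[inPanel, , drop = FALSE]
  r <- r[order(r$pvalue, r$chrom, r$pos), , drop = FALSE]
  v <- panel@variants
  idx <- match(r$id, v$id)
  r2fun <- .r2PairFun(panel)
  accepted <- integer(0)
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (!is.null(excludeLoci) && nrow(excludeLoci)) {
      same <- excludeLoci$chrom == v$chrom[i]
      if (any(same & abs(excludeLoci$pos - v$pos[i]) <= cfg$exclusionBp)) next
    }
    near <- accepted[v$chrom[accepted] == v$chrom[i] &
                     abs(v$pos[accepted] - v$pos[i]) <= cfg$independenceWindowBp]
    ok <- TRUE
    for (a in near) if (r2fun(a, i) > cfg$independenceR2) { ok <- FALSE; break }
    if (ok) accepted <- c(accepted, i)
    if (length(accepted) >= cfg$nTarget) break
  }
  if (length(accepted) < cfg$nTarget)
    warning("only ", length(accepted), " of ", cfg$nTarget,
            " requested SNPs could be selected")
  as.character(v$id[accepted])
}

#' Assemble multi-trait submissions into an array design
#'
#' Submissions are merged into one entry per unique variant id, tags
#' (category:trait) merged across submissions. Distinct ids at identical
#' (chrom, pos, ref, alt) — unintended duplicates — collapse to a single
#' entry (the alphabetically first id) with the remainder recorded as
#' aliases. Re-assembling a design's own entries changes nothing.
#'
#' @param submissions `data.frame(category, trait, id)`, one row per
#'   submitted SNP, or a list of `list(category=, trait=, ids=)`.
#' @param catalog Variant table resolving ids (data.frame with `id`,
#'   `chrom`, `pos`, `ref`, `alt`, or an object with [variantTable]).
#' @return An [ArrayDesign-class].
#' @export
assembleDesign <- function(submissions, catalog) {
  if (is.list(submissions) && !is.data.frame(submissions))
    submissions <- do.call(rbind, lapply(submissions, function(s)
      data.frame(category = s$category, trait = s$trait, id = s$ids)))
  stopifnot(all(c("category", "trait", "id") %in% names(submissions)))
  bad <- setdiff(unique(submissions$category), .DESIGN_CATEGORIES)
  if (length(bad))
    stop("unknown categories: ", paste(bad, collapse = ", "))
  cat <- if (is.data.frame(catalog) || is(catalog, "DataFrame"))
    as.data.frame(catalog) else as.data.frame(variantTable(catalog))
  if (is.null(cat$ref)) cat$ref <- "A"
  if (is.null(cat$alt)) cat$alt <- "G"
  unresolved <- setdiff(submissions$id, cat$id)
  if (length(unresolved))
    stop("unresolved ids: ", paste(unresolved, collapse = ", "))
  sub <- submissions
  sub$tag <- paste0(sub$category, ":", sub$trait)
  ci <- match(sub$id, cat$id)
  site <- paste(cat$chrom[ci], cat$pos[ci], cat$ref[ci], cat$alt[ci], sep = "\r")
  ## canonical id per physical site: alphabetically first
  canon <- tapply(sub$id, site, function(ids) sort(unique(ids))[1])
  sub$canon <- unname(canon[site])
  entries <- lapply(split(seq_len(nrow(sub)), sub$canon), function(rows) {
    id <- sub$canon[rows[1]]
    k <- match(id, cat$id)
    list(id = id, chrom = as.character(cat$chrom[k]), pos = as.integer(cat$pos[k]),
         ref = cat$ref[k], alt = cat$alt[k],
         tags = sort(unique(sub$tag[rows])),
         aliases = sort(setdiff(unique(sub$id[rows]), id)))
  })
  e <- DataFrame(
    id = vapply(entries, `[[`, "", "id"),
    chrom = vapply(entries, `[[`, "", "chrom"),
    pos = vapply(entries, `[[`, 0L, "pos"),
    ref = vapply(entries, `[[`, "", "ref"),
    alt = vapply(entries, `[[`, "", "alt"),
    tags = IRanges::CharacterList(lapply(entries, `[[`, "tags")),
    aliases = IRanges::CharacterList(lapply(entries, `[[`, "aliases")))
  e <- e[order(e$chrom, e$pos, e$id), ]
  rownames(e) <- NULL
  new("ArrayDesign", entries = e)
}

#' Per-category design summary
#'
#' For each design category (and overall): SNP count, mean MAF, fraction
#' monomorphic, fraction with 0 < MAF < 0.05, and the MAF spectrum over
#' `bins`. A SNP tagged with several categories contributes to each.
#' Design variants absent from the panel are counted as unevaluable and
#' excluded from the frequency summaries.
#'
#' @param design An [ArrayDesign-class].
#' @param panel A [HaplotypePanel-class] supplying frequencies.
#' @param bins MAF bin edges (see [mafSpectrum]).
#' @return List: `table` (data.frame, one row per category plus "all") and
#'   `spectra` (named list of per-category spectra).
#' @export
designSummary <- function(design, panel, bins = .DEFAULT_MAF_BINS) {
  stopifnot(is(design, "ArrayDesign"), is(panel, "HaplotypePanel"))
  e <- design@entries
  pm <- mafs(panel)
  maf <- pm[match(e$id, names(pm))]
  cats <- lapply(e$tags, function(t) unique(sub(":.*$", "", t)))
  allCats <- sort(unique(unlist(cats)))
  summarise <- function(sel) {
    m <- maf[sel]
    ev <- !is.na(m)
    data.frame(n = sum(sel), nUnevaluable = sum(!ev),
               meanMaf = if (any(ev)) mean(m[ev]) else NA_real_,
               fracMonomorphic = if (any(ev)) mean(m[ev] == 0) else NA_real_,
               fracMafLt05 = if (any(ev)) mean(m[ev] > 0 & m[ev] < 0.05) else NA_real_)
  }
  rows <- list()
  spectra <- list()
  for (ct in allCats) {
    sel <- vapply(cats, function(x) ct %in% x, TRUE)
    rows[[ct]] <- cbind(category = ct, summarise(sel))
    m <- maf[sel]
    spectra[[ct]] <- mafSpectrum(m[!is.na(m)], bins)
  }
  rows[["all"]] <- cbind(category = "all", summarise(rep(TRUE, nrow(e))))
  spectra[["all"]] <- mafSpectrum(maf[!is.na(maf)], bins)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, spectra = spectra)
}
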