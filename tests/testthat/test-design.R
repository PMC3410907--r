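test_that("replication selection enforces independence and p-value ranking", {
  x <- c(rep(1L, 40), rep(0L, 40))
  p <- mkPanel(cbind(x, x), pos = c(1000L, 2000L))
  ss <- SummaryStats("t", data.frame(id = c("s1", "s2"), chrom = "1",
                                     pos = c(1000L, 2000L),
                                     pvalue = c(1e-8, 1e-6), eaf = 0.5))
  expect_warning(sel <- selectReplicationSnps(ss, p, SelectionConfig(nTarget = 5)),
                 "only 1 of 5")
  expect_equal(sel, "s1")

  set.seed(1)
  ind <- matrix(rbinom(2000 * 8, 1, 0.5), 2000)
  pi <- mkPanel(ind)
  pv <- c(0.5, 0.001, 0.2, 0.0001, 0.9, 0.01, 0.05, 0.3)
  ssi <- SummaryStats("t", data.frame(id = paste0("s", 1:8), chrom = "1",
                                      pos = 1000L * 1:8, pvalue = pv, eaf = 0.5))
  sel5 <- suppressWarnings(
    selectReplicationSnps(ssi, pi, SelectionConfig(nTarget = 5,
                                                   independenceR2 = 0.05)))
  expect_equal(sel5, paste0("s", order(pv)[1:5]))
})

test_that("known-locus exclusion removes candidates within the radius", {
  set.seed(2)
  ind <- matrix(rbinom(1000 * 3, 1, 0.5), 1000)
  p <- mkPanel(ind, pos = c(100000L, 400000L, 900000L))
  ss <- SummaryStats("t", data.frame(id = paste0("s", 1:3), chrom = "1",
                                     pos = c(100000L, 400000L, 900000L),
                                     pvalue = c(1e-9, 1e-8, 1e-7), eaf = 0.5))
  sel <- suppressWarnings(selectReplicationSnps(
    ss, p, SelectionConfig(nTarget = 3, exclusionBp = 250000),
    excludeLoci = data.frame(chrom = "1", pos = 140000L)))
  expect_equal(sort(sel), c("s2", "s3"))   # s1 is 40 kb from the known locus
})

test_that("ties in p-value resolve by genomic order, deterministically", {
  set.seed(3)
  ind <- matrix(rbinom(1000 * 3, 1, 0.5), 1000)
  p <- mkPanel(ind)
  ss <- SummaryStats("t", data.frame(id = paste0("s", 1:3), chrom = "1",
                                     pos = 1000L * 1:3,
                                     pvalue = c(0.01, 0.01, 0.001), eaf = 0.5))
  sel <- suppressWarnings(selectReplicationSnps(ss, p, SelectionConfig(nTarget = 2)))
  expect_equal(sel, c("s3", "s1"))
})

test_that("planted independent signals occupy the top selections", {
  # many founders keep the background (cross-block) LD near zero, so the
  # three causal signals are genuinely unlinked
  sim <- ldFixture(seed = 55, nHap = 600, len = 6e5, nFound = 80)
  p <- sim$panel
  m <- mafs(p)
  v <- as.data.frame(variantTable(p))
  pick <- function(target) {
    cand <- names(m)[m > 0.15]
    cand[which.min(abs(v$pos[match(cand, v$id)] - target))]
  }
  causal <- vapply(c(1e5, 3e5, 5e5), pick, "")
  hits <- vapply(1:50, function(sd) {
    ss <- simulateSummaryStats(p, data.frame(id = causal, beta = 0.25),
                               nStudy = 20000, seed = sd)
    sel <- selectReplicationSnps(ss, p, SelectionConfig(nTarget = 3))
    all(vapply(causal, function(cz)
      any(vapply(sel, function(s)
        s == cz || r2Phased(p, s, cz) >= 0.5, TRUE)), TRUE))
  }, TRUE)
  expect_gte(sum(hits), 48)
})

test_that("selected replication panels pass a brute-force independence scan", {
  sim <- ldFixture(seed = 20, nHap = 400, len = 2e5, nFound = 10)
  p <- sim$panel
  ss <- simulateSummaryStats(p, nStudy = 5000, seed = 31)
  sel <- suppressWarnings(
    selectReplicationSnps(ss, p, SelectionConfig(nTarget = 40)))
  v <- as.data.frame(variantTable(p))
  si <- match(sel, v$id)
  for (x in seq_along(si)) for (y in seq_len(x - 1L)) {
    if (abs(v$pos[si[x]] - v$pos[si[y]]) <= 1e6)
      expect_lte(r2Phased(p, si[x], si[y]), 0.3 + 1e-9)
  }
})

test_that("design assembly merges tags, collapses duplicates, is idempotent", {
  catalog <- data.frame(id = c("rs1", "rs2", "rs2b", "rs3"), chrom = "1",
                        pos = c(100L, 200L, 200L, 300L),
                        ref = c("A", "C", "C", "G"), alt = c("G", "T", "T", "A"))
  d <- assembleDesign(data.frame(
    category = c("replication", "fine_mapping", "replication", "replication",
                 "mhc"),
    trait = c("T2D", "LDL", "HDL", "HDL", "none"),
    id = c("rs1", "rs1", "rs2", "rs2b", "rs3")), catalog)
  e <- designEntries(d)
  expect_equal(nrow(e), 3L)
  expect_equal(sort(unname(unlist(e$tags[e$id == "rs1"]))),
               c("fine_mapping:LDL", "replication:T2D"))
  # rs2/rs2b are the same physical site under two names
  expect_equal(unname(unlist(e$aliases[e$id == "rs2"])), "rs2b")

  # idempotence: re-submitting the design's own entries changes nothing
  resub <- do.call(rbind, lapply(seq_len(nrow(e)), function(k)
    data.frame(category = sub(":.*$", "", e$tags[[k]]),
               trait = sub("^[^:]*:", "", e$tags[[k]]), id = rep(e$id[k], length(e$tags[[k]])))))
  d2 <- assembleDesign(resub, catalog)
  expect_equal(as.data.frame(designEntries(d2))[, c("id", "chrom", "pos")],
               as.data.frame(e)[, c("id", "chrom", "pos")])
  expect_identical(lapply(designEntries(d2)$tags, sort), lapply(e$tags, sort))

  expect_error(assembleDesign(data.frame(category = "replication", trait = "t",
                                         id = "missing"), catalog),
               "unresolved ids: missing")
  expect_error(assembleDesign(data.frame(category = "bogus", trait = "t",
                                         id = "rs1"), catalog),
               "unknown categories")
})

test_that("single-category designs account exactly in the summary table", {
  sim <- ldFixture(seed = 40, nHap = 200, len = 5e4, nFound = 100)
  p <- sim$panel
  ids <- variantIds(p)
  d <- assembleDesign(data.frame(category = "replication", trait = "t",
                                 id = ids), as.data.frame(variantTable(p)))
  s <- designSummary(d, p)
  tab <- s$table
  expect_equal(tab$n[tab$category == "replication"], length(ids))
  expect_equal(tab$n[tab$category == "all"], nrow(designEntries(d)))
  for (sp in s$spectra) expect_equal(sum(sp), 1)
})

test_that("replication panels drawn from common SNPs have higher mean MAF", {
  sim <- ldFixture(seed = 41, nHap = 1000, len = 1e5, nFound = 500)
  p <- sim$panel
  m <- mafs(p)
  fmIds <- names(m)[m > 0]                    # full spectrum
  replIds <- names(m)[m > 0.1]                # common SNPs only
  d <- assembleDesign(rbind(
    data.frame(category = "fine_mapping", trait = "LDL", id = fmIds),
    data.frame(category = "replication", trait = "LDL", id = replIds)),
    as.data.frame(variantTable(p)))
  tab <- designSummary(d, p)$table
  expect_gt(tab$meanMaf[tab$category == "replication"],
            tab$meanMaf[tab$category == "fine_mapping"])
})

test_that("uniform-MAF designs summarize to zero rare fraction", {
  a <- matrix(rep(c(1L, 1L, 0L, 0L), 5), nrow = 4)
  p <- mkPanel(a)
  d <- assembleDesign(data.frame(category = "replication", trait = "t",
                                 id = variantIds(p)),
                      as.data.frame(variantTable(p)))
  tab <- designSummary(d, p)$table
  expect_equal(tab$meanMaf[tab$category == "all"], 0.5)
  expect_equal(tab$fracMafLt05[tab$category == "all"], 0)
})
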