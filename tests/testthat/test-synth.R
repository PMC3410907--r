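test_that("zero recombination collapses descendants onto founders", {
  sim <- simulatePanel(PanelSimConfig(nHaplotypes = 20, regionLength = 5e4,
                                      nFounders = 2, backgroundRate = 0,
                                      seed = 4))
  a <- alleleMatrix(sim$panel)
  founders <- a[1:2, , drop = FALSE]
  for (h in seq_len(nrow(a)))
    expect_true(identical(a[h, ], founders[1, ]) ||
                identical(a[h, ], founders[2, ]))
})

test_that("panel simulation is deterministic under seed", {
  cfg <- PanelSimConfig(nHaplotypes = 60, regionLength = 5e4, nFounders = 8,
                        hotspots = data.frame(start = 2e4, end = 2.5e4, rate = 80),
                        seed = 99)
  s1 <- simulatePanel(cfg)
  s2 <- simulatePanel(cfg)
  expect_identical(alleleMatrix(s1$panel), alleleMatrix(s2$panel))
  expect_identical(as.data.frame(mapAnchors(s1$map)),
                   as.data.frame(mapAnchors(s2$map)))
})

test_that("config errors on nonpositive sizes", {
  expect_error(PanelSimConfig(nHaplotypes = 0, regionLength = 1e4))
  expect_error(PanelSimConfig(nHaplotypes = 10, regionLength = -1))
  expect_error(PanelSimConfig(nHaplotypes = 4, regionLength = 1e4, nFounders = 8))
})

test_that("LD is depressed across a recombination hotspot (paired sign test)", {
  hot <- data.frame(start = 140000, end = 150000, rate = 100)
  one <- function(sd) {
    sim <- simulatePanel(PanelSimConfig(nHaplotypes = 150, regionLength = 3e5,
                                        nFounders = 8, snpDensity = 0.4,
                                        hotspots = hot, backgroundRate = 0.5,
                                        seed = sd))
    p <- sim$panel
    v <- as.data.frame(variantTable(p))
    poly <- which(unname(mafs(p)) > 0.05)
    left <- poly[v$pos[poly] >= 110000 & v$pos[poly] < 140000]
    right <- poly[v$pos[poly] > 150000 & v$pos[poly] <= 180000]
    cold <- poly[v$pos[poly] < 140000]
    g1 <- expand.grid(i = left, j = right)
    g2 <- expand.grid(i = cold, j = cold)
    g2 <- g2[v$pos[g2$j] - v$pos[g2$i] >= 10000 &
             v$pos[g2$j] - v$pos[g2$i] <= 70000, ]
    if (!nrow(g1) || !nrow(g2)) return(NA)
    mean(mapply(function(i, j) r2Phased(p, i, j), g1$i, g1$j)) <
      mean(mapply(function(i, j) r2Phased(p, i, j), g2$i, g2$j))
  }
  res <- vapply(1:50, one, TRUE)
  res <- res[!is.na(res)]
  # one-sided sign test at p < 0.01
  expect_lt(binom.test(sum(res), length(res), alternative = "greater")$p.value,
            0.01)
})

test_that("pedigree drop yields exact Mendelian truth and simplex IBD fractions", {
  sim <- simulatePanel(PanelSimConfig(nHaplotypes = 40, regionLength = 1e6,
                                      nFounders = 40, backgroundRate = 20,
                                      snpDensity = 0.3, seed = 12))
  ped <- PedigreeSpec(c("F", "M", "C"), c(NA, NA, "F"), c(NA, NA, "M"))
  dp <- dropPedigree(sim$panel, sim$map, ped, seed = 3)
  tr <- dp$truth
  po <- tr[tr$id1 == "F" & tr$id2 == "C", ]
  expect_equal(unlist(po[c("k0", "k1", "k2")]), c(k0 = 0, k1 = 1, k2 = 0))
  un <- tr[tr$id1 == "F" & tr$id2 == "M", ]
  expect_equal(unlist(un[c("k0", "k1", "k2")]), c(k0 = 1, k1 = 0, k2 = 0))
  expect_equal(tr$k0 + tr$k1 + tr$k2, rep(1, nrow(tr)))
  expect_equal(dim(dosageMatrix(dp$geno)), c(3L, nVariants(sim$panel)))
})

test_that("full-sib realized k1 averages one half over seeds", {
  sim <- simulatePanel(PanelSimConfig(nHaplotypes = 50, regionLength = 5e6,
                                      nFounders = 50, backgroundRate = 20,
                                      snpDensity = 0.05, seed = 21))
  ped <- PedigreeSpec(c("F", "M", "C1", "C2"), c(NA, NA, "F", "F"),
                      c(NA, NA, "M", "M"))
  k1s <- vapply(1:100, function(sd) {
    tr <- dropPedigree(sim$panel, sim$map, ped, seed = sd)$truth
    tr$k1[tr$id1 == "C1" & tr$id2 == "C2"]
  }, numeric(1))
  expect_gt(mean(k1s), 0.45)
  expect_lt(mean(k1s), 0.55)
})

test_that("fst = 0 reproduces the base frequencies exactly", {
  base <- c(0.2, 0.5, 0.7)
  s <- simulateStratifiedCC(base, fst = 0, nCases = 10, nControls = 10, seed = 1)
  expect_equal(s$popFreqs[[1]], base)
  expect_equal(s$popFreqs[[2]], base)
  expect_error(simulateStratifiedCC(c(0, 0.5), 0.1, 10, 10), "strictly inside")
})

test_that("unstratified null study is lambda-calibrated; stratification inflates", {
  base <- local({ set.seed(77); runif(5000, 0.1, 0.9) })
  null <- simulateStratifiedCC(base, fst = 0, nCases = 500, nControls = 500,
                               seed = 6)
  lamN <- lambdaValue(lambdaGc(trendScan(null$geno, null$phenotype), "null"))
  expect_gt(lamN, 0.93)
  expect_lt(lamN, 1.07)
  strat <- simulateStratifiedCC(base, fst = 0.05, nCases = 500, nControls = 500,
                                casePop1Fraction = 0.9,
                                controlPop1Fraction = 0.1, seed = 6)
  lamS <- lambdaValue(lambdaGc(trendScan(strat$geno, strat$phenotype), "strat"))
  expect_gt(lamS, 1.2)
})

test_that("null summary statistics are uniform and seeded runs are identical", {
  sim <- simulatePanel(PanelSimConfig(nHaplotypes = 200, regionLength = 5e6,
                                      nFounders = 200, snpDensity = 1,
                                      seed = 15))
  ss <- simulateSummaryStats(sim$panel, causal = NULL, nStudy = 8000,
                             trait = "null", seed = 5)
  pv <- statRecords(ss)$pvalue
  expect_gt(length(pv), 4000)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  ss2 <- simulateSummaryStats(sim$panel, causal = NULL, nStudy = 8000,
                              trait = "null", seed = 5)
  expect_identical(statRecords(ss2)$pvalue, pv)
  expect_error(simulateSummaryStats(sim$panel, data.frame(id = "nope", beta = 1)),
               "unknown variant")
})

test_that("a strong causal signal tops its own LD block in nearly every study", {
  sim <- ldFixture(seed = 33, nHap = 600, len = 5e5, nFound = 30)
  p <- sim$panel
  m <- mafs(p)
  v <- as.data.frame(variantTable(p))
  cand <- names(m)[m > 0.1]
  causal <- cand[which.min(abs(v$pos[match(cand, v$id)] - 250000))]
  hits <- vapply(1:50, function(sd) {
    ss <- simulateSummaryStats(p, data.frame(id = causal, beta = 0.2),
                               nStudy = 20000, seed = sd)
    r <- statRecords(ss)
    top <- r$id[which.min(r$pvalue)]
    top == causal || r2Phased(p, top, causal) >= 0.5
  }, TRUE)
  expect_gte(sum(hits), 48)     # >= 95% of studies
})

test_that("simulated MAF spectrum is dominated by rare variants (1/x law)", {
  fr <- vapply(1:20, function(sd) {
    sim <- simulatePanel(PanelSimConfig(nHaplotypes = 1000, regionLength = 1e5,
                                        nFounders = 500, seed = sd))
    mafSpectrum(sim$panel)
  }, numeric(9))
  avg <- rowMeans(fr)
  expect_gt(avg[["(0,0.01]"]], avg[["(0.01,0.02]"]] + avg[["(0.02,0.05]"]])
  expect_gt(avg[["(0,0.01]"]], avg[["(0.1,0.2]"]])
  expect_equal(colSums(fr), rep(1, 20))
})
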