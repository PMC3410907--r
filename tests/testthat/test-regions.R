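# Fixture: hotspots flanking a 1.20-1.30 Mb seed span, as in the worked
# boundary example: [1.18,1.19] Mb and [1.33,1.34] Mb at 100 cM/Mb.
flankMap <- function()
  mkMap(c(1, 1180000, 1190000, 1330000, 1340000, 2000000),
        c(1, 100, 1, 100, 1, 1))

# Panel: index at 1.25 Mb in perfect LD with partners at 1.20 / 1.30 Mb.
flankPanel <- function() {
  set.seed(10)
  n <- 200
  core <- rbinom(n, 1, 0.3)
  oth <- matrix(rbinom(n * 2, 1, 0.5), n)
  mkPanel(cbind(oth[, 1], core, core, core, oth[, 2]),
          pos = c(1100000L, 1200000L, 1250000L, 1300000L, 1500000L))
}

test_that("cM interpolation is exact at anchors, linear between, invertible", {
  gm <- mkMap(c(1000, 2000), c(100, 100))
  expect_equal(interpolateCm(gm, "1", 1000), 0)
  expect_equal(interpolateCm(gm, "1", 2000), 0.1)
  expect_equal(interpolateCm(gm, "1", 1500), 0.05)
  # constant extrapolation beyond anchors
  expect_equal(interpolateCm(gm, "1", 5000), 0.1)
  expect_error(interpolateCm(gm, "7", 1000), "not present")

  gm2 <- mkMap(c(1, 5e4, 2e5, 1e6), c(0.5, 3, 1, 1))
  pos <- seq(2, 999999, length.out = 50)
  back <- cmToBp(gm2, "1", interpolateCm(gm2, "1", pos))
  expect_true(all(abs(back - pos) <= 1))
  expect_true(all(diff(interpolateCm(gm2, "1", pos)) >= 0))
})

test_that("hotspot detection applies the local-rate rule and merges runs", {
  expect_equal(length(detectHotspots(mkMap(c(1, 1e4, 2e4, 3e4), 1), 10)), 0L)

  gm <- mkMap(c(1000, 10000, 11000, 20000), c(1, 490, 1, 1))
  hs <- detectHotspots(gm, 10)
  expect_equal(length(hs), 1L)
  expect_equal(regionStart(hs), 10000)
  expect_equal(regionEnd(hs), 11000)
  expect_equal(regionMcols(hs)$meanRate, 490)

  # adjacent qualifying intervals merge; output disjoint and sorted
  gm2 <- mkMap(c(1, 1e4, 1.1e4, 1.2e4, 2e4, 3e4, 3.1e4, 4e4),
               c(1, 50, 80, 1, 1, 60, 1, 1))
  hs2 <- detectHotspots(gm2, 10)
  expect_equal(length(hs2), 2L)
  expect_equal(regionStart(hs2), c(10000, 30000))
  expect_equal(regionEnd(hs2), c(12000, 31000))
  expect_true(all(diff(regionStart(hs2)) > 0))
})

test_that("SFM boundaries land on hotspot inner edges when hotspots are near", {
  sfm <- buildSfmRegion(flankPanel(), flankMap(), "s3", trait = "T2D")
  expect_equal(regionStart(sfm), 1190000)
  expect_equal(regionEnd(sfm), 1330000)
  expect_equal(regionMcols(sfm)$kind, "SFM")
  expect_match(regionMcols(sfm)$provenance, "hotspot inner edge")
})

test_that("without a nearby hotspot the 0.02 cM shoulder fires (~20 kb at 1 cM/Mb)", {
  flat <- mkMap(c(1, 2000000), c(1, 1))
  sfm <- buildSfmRegion(flankPanel(), flat, "s1")   # s1 has no LD partners
  expect_equal(regionStart(sfm), 1100000 - 20000)
  expect_equal(regionEnd(sfm), 1100000 + 20000)
  expect_match(regionMcols(sfm)$provenance, "shoulder")
})

test_that("r2 seed threshold 1 degenerates the seed interval to the index", {
  flat <- mkMap(c(1, 2000000), c(1, 1))
  p <- flankPanel()
  sfm <- buildSfmRegion(p, flat, "s3", r2Seed = 1.000001)
  # no partner passes r2 >= 1.000001, so the seed is the index alone
  expect_equal(regionStart(sfm), 1250000 - 20000)
  expect_equal(regionEnd(sfm), 1250000 + 20000)
  expect_error(buildSfmRegion(mkPanel(cbind(rep(1L, 4), c(0L, 1L, 0L, 1L))),
                              flat, "s1"), "monomorphic")
})

test_that("SFM regions contain the index and all its seed-LD partners", {
  sim <- ldFixture(seed = 18, nHap = 300, len = 2e5, nFound = 8)
  p <- sim$panel
  m <- mafs(p)
  v <- as.data.frame(variantTable(p))
  idx <- names(m)[which(m > 0.2)[1]]
  sfm <- buildSfmRegion(p, sim$map, idx)
  poly <- names(m)[m > 0]
  partners <- poly[vapply(poly, function(id)
    id != idx && r2Phased(p, id, idx) >= 0.5, TRUE)]
  pp <- v$pos[match(c(idx, partners), v$id)]
  expect_true(all(pp >= regionStart(sfm) & pp <= regionEnd(sfm)))
  sfm2 <- buildSfmRegion(p, sim$map, idx)
  expect_identical(c(regionStart(sfm), regionEnd(sfm)),
                   c(regionStart(sfm2), regionEnd(sfm2)))
})

test_that("LFM expansion absorbs overlapping genes to transitive closure", {
  sfm <- fineMapRegion("1", 100, 120, "SFM", "idx", "t")
  lfm0 <- buildLfmRegion(sfm, data.frame(chrom = "1", start = 500, end = 600,
                                         name = "far"))
  expect_equal(c(regionStart(lfm0), regionEnd(lfm0)), c(100, 120))
  expect_equal(regionMcols(lfm0)$kind, "LFM")

  sfm2 <- fineMapRegion("1", 100000, 120000, "SFM", "idx", "t")
  lfm1 <- buildLfmRegion(sfm2, data.frame(chrom = "1", start = 95000,
                                          end = 101000, name = "g1"))
  expect_equal(regionStart(lfm1), 95000)

  lfm2 <- buildLfmRegion(sfm, data.frame(chrom = "1", start = c(90, 105),
                                         end = c(110, 130),
                                         name = c("A", "B")))
  expect_equal(c(regionStart(lfm2), regionEnd(lfm2)), c(90, 130))
  # containment: LFM always includes its SFM
  expect_true(regionStart(lfm2) <= regionStart(sfm) &&
              regionEnd(lfm2) >= regionEnd(sfm))
})

test_that("region merging unions strict overlaps only and is idempotent", {
  r1 <- fineMapRegion("1", 100, 200, "SFM", "a", "t1")
  r2 <- fineMapRegion("1", 150, 300, "LFM", "b", "t2")
  r3 <- fineMapRegion("2", 100, 200, "SFM", "c", "t3")
  m <- mergeRegions(suppressWarnings(c(r1, r2, r3)))
  expect_equal(length(m), 2L)
  on1 <- m[as.character(GenomicRanges::seqnames(m)) == "1"]
  expect_equal(c(regionStart(on1), regionEnd(on1)), c(100, 300))
  expect_equal(sort(unlist(regionMcols(on1)$indexIds)), c("a", "b"))
  expect_equal(regionMcols(on1)$kind, "LFM")

  ab <- mergeRegions(c(fineMapRegion("1", 100, 200, "SFM"),
                       fineMapRegion("1", 201, 300, "SFM")))
  expect_equal(length(ab), 2L)

  m2 <- mergeRegions(m)
  expect_equal(as.data.frame(m2)[, 1:3], as.data.frame(m)[, 1:3])
  mPerm <- mergeRegions(suppressWarnings(c(r3, r2, r1)))
  expect_equal(as.data.frame(mPerm)[, 1:3], as.data.frame(m)[, 1:3])
})

test_that("fine-mapping SNP enumeration filters by interval and designability", {
  reg <- fineMapRegion("1", 150, 450, "SFM")
  expect_equal(enumerateFinemappingSnps(
    data.frame(id = character(), chrom = character(), pos = integer()), reg),
    character())
  cat10 <- data.frame(id = paste0("v", 1:10), chrom = "1",
                      pos = c(100, 160, 200, 300, 440, 500, 700, 800, 900, 1000),
                      designable = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                                     TRUE, TRUE, TRUE, TRUE))
  expect_equal(enumerateFinemappingSnps(cat10, reg), paste0("v", 2:5))
  expect_equal(enumerateFinemappingSnps(cat10, reg, requireDesignable = TRUE),
               paste0("v", c(2, 4, 5)))
})
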