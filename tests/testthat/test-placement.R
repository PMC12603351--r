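# Length sampling, zygosity, placement ordering, constraint modes and
# determinism of the placement engine.

test_that("degenerate and uniform ranges sample as expected", {
  set.seed(1)
  cat <- mkCategory("DEL", list(A = c(5, 5)))
  expect_equal(unname(sampleLengths(cat)["A"]), 5)

  cat <- mkCategory("DEL", list(A = c(1000, 10000)))
  draws <- replicate(1e4, sampleLengths(cat)[["A"]])
  expect_true(all(draws >= 1000 & draws <= 10000))
  se <- (10000 - 1000) / sqrt(12) / sqrt(1e4)
  expect_lt(abs(mean(draws) - 5500), 3 * se)
})

test_that("derived lengths follow their expression", {
  cat <- mkCategory("delINV", list(B = c(8, 8), A = "0.5*length(B)"))
  lens <- sampleLengths(cat)
  expect_equal(unname(lens["A"]), 4)
  expect_equal(unname(lens["B"]), 8)
  # rounding floor of 1 bp
  cat <- mkCategory("delINV", list(B = c(1, 1), A = "0.1*length(B)"))
  expect_equal(unname(sampleLengths(cat)[["A"]]), 1)
})

test_that("zygosity assignment follows the homozygosity policy", {
  mk <- function(n) replicate(n, mkPlacedSV(mkRecord("DEL", "c", 0, 1)),
                              simplify = FALSE)
  set.seed(2)
  all1 <- assignZygosity(mk(50), 1.0)
  expect_true(all(vapply(all1, function(s) identical(svHaplotypes(s), 0:1), TRUE)))
  all0 <- assignZygosity(mk(50), 0.0)
  expect_true(all(vapply(all0, function(s) length(svHaplotypes(s)) == 1L, TRUE)))
  half <- assignZygosity(mk(1e4), 0.5)
  fr <- mean(vapply(half, function(s) length(svHaplotypes(s)) == 2L, TRUE))
  expect_lt(abs(fr - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("the placement queue is most-restrictive-first with span ties", {
  mkSpan <- function(len, fixed = FALSE) {
    sv <- mkPlacedSV(mkRecord("DEL", "c", 0, len))
    sv@fixed <- fixed
    sv
  }
  svs <- list(mkSpan(100), mkSpan(100), mkSpan(100, fixed = TRUE))
  cons <- list(list(), list(list(mode = "exact", labels = "x")), list())
  expect_equal(orderCategories(svs, cons), c(3L, 2L, 1L))

  # all unconstrained with equal spans: stable input order
  svs <- replicate(4, mkSpan(50), simplify = FALSE)
  cons <- replicate(4, list(), simplify = FALSE)
  expect_equal(orderCategories(svs, cons), 1:4)

  # two exact SVs: larger span first
  svs <- list(mkSpan(1000), mkSpan(5000))
  cons <- replicate(2, list(list(mode = "exact", labels = "x")),
                    simplify = FALSE)
  expect_equal(orderCategories(svs, cons), c(2L, 1L))
})

test_that("exact mode with a degenerate length occupies the ROI precisely", {
  set.seed(3)
  ref <- tinyRef(chr1 = strrep("ACGTAGGCTA", 100))  # 1 kb
  rois <- grTrack("chr1", 100, 200, "x")
  cat <- mkCategory("DEL", list(A = c(100, 100)),
                    constraints = list(list(mode = "exact", labels = "x")))
  svs <- placeAll(list(cat), ref, rois = rois)
  iv <- svIntervals(svs[[1]])
  expect_equal(iv$start, 100)
  expect_equal(iv$end, 200)
  expect_true(isTRUE(auditPlacement(svs[[1]], list(mode = "exact", labels = "x"),
                                    rois)))
})

test_that("an infeasible exact constraint is diagnosed before sampling", {
  ref <- tinyRef(chr1 = strrep("ACGT", 250))
  rois <- grTrack("chr1", 100, 200, "x")   # width 100
  cat <- mkCategory("DEL", list(A = c(500, 600)),
                    constraints = list(list(mode = "exact", labels = "x")))
  expect_error(placeAll(list(cat), ref, rois = rois), "feasible anchored range")
})

test_that("a genome-wide blacklist makes placement fail with context", {
  ref <- tinyRef(chr1 = strrep("ACGT", 250))
  bl <- grTrack("chr1", 0, 1000, "bl")
  cat <- mkCategory("DEL", list(A = c(10, 20)), count = 1L)
  expect_error(placeAll(list(cat), ref, blacklist = bl),
               "placement failed.*DEL")
})

test_that("contained placements always fall inside their ROI", {
  set.seed(4)
  ref <- tinyRef(chr1 = strrep("ACGTAGGCTA", 1000))  # 10 kb
  rois <- grTrack("chr1", 0, 1000, "z")
  cat <- mkCategory("DEL", list(A = c(100, 100)),
                    constraints = list(list(mode = "contained", labels = "z")))
  for (i in 1:200) {
    svs <- placeAll(list(cat), ref, rois = rois)
    iv <- svIntervals(svs[[1]])
    expect_gte(iv$start, 0)
    expect_lte(iv$end, 1000)
  }
})

test_that("minimum inter-SV distance holds between all breakends", {
  set.seed(5)
  ref <- tinyRef(chr1 = strrep("ACGTAGGCTA", 5000))  # 50 kb
  cat <- mkCategory("DEL", list(A = c(100, 300)), count = 30L,
                    homozygousProb = 0.5)
  params <- defaultParams(minInterSVDist = 500)
  svs <- placeAll(list(cat), ref, params = params)
  bks <- sort(unlist(lapply(svs, function(s) breakendsOf(s)$pos)))
  # within-SV breakends (start/end pairs) may be close; between SVs >= 500
  perSV <- lapply(svs, function(s) breakendsOf(s)$pos)
  for (i in seq_along(perSV)) for (j in seq_along(perSV)) {
    if (i >= j) next
    d <- min(abs(outer(perSV[[i]], perSV[[j]], "-")))
    expect_gte(d, 500)
  }
})

test_that("placement is deterministic given configuration and seed", {
  dir <- withr::local_tempdir()
  fx <- makeReference(fixtureSpec(chromLengths = c(chr1 = 30000), seed = 9),
                      dir)
  run <- function() {
    set.seed(77)
    cats <- list(mkCategory("DEL", list(A = c(50, 200)), count = 5L,
                            homozygousProb = 0.5),
                 mkCategory("dDUP", defaultDistances("dDUP"), count = 3L,
                            homozygousProb = 0.5))
    placeAll(cats, fx$reference)
  }
  a <- run(); b <- run()
  expect_identical(lapply(a, svIntervals), lapply(b, svIntervals))
  expect_identical(lapply(a, svRecords), lapply(b, svRecords))
  expect_identical(lapply(a, svHaplotypes), lapply(b, svHaplotypes))
})

test_that("homozygous SVs book both haplotypes at identical coordinates", {
  set.seed(6)
  ref <- tinyRef(chr1 = strrep("ACGTAGGCTA", 2000))
  cat <- mkCategory("INV", list(A = c(100, 200)), count = 5L,
                    homozygousProb = 1)
  svs <- placeAll(list(cat), ref)
  for (sv in svs) expect_equal(svHaplotypes(sv), 0:1)
  hapA <- buildHaplotype(ref, svs, 0L)$sequences
  hapB <- buildHaplotype(ref, svs, 1L)$sequences
  expect_equal(as.character(hapA[[1]]), as.character(hapB[[1]]))
})

test_that("same-haplotype intervals never overlap across many placements", {
  set.seed(8)
  ref <- tinyRef(chr1 = strrep("ACGTAGGCTA", 10000))  # 100 kb
  cats <- list(mkCategory("DEL", list(A = c(200, 500)), count = 40L,
                          homozygousProb = 0.3),
               mkCategory("DUP", list(A = c(200, 500)), count = 30L,
                          homozygousProb = 0.3))
  svs <- placeAll(cats, ref)
  for (h in 0:1) {
    iv <- do.call(rbind, lapply(Filter(function(s) h %in% svHaplotypes(s), svs),
                                svIntervals))
    iv <- iv[iv$end > iv$start, ]
    ir <- IRanges::IRanges(iv$start + 1, iv$end)
    expect_equal(sum(IRanges::countOverlaps(ir, ir) > 1), 0)
  }
})
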