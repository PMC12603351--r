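# Truthset serialization: VCF records and linkage, PAF lines and liftover,
# statistics accounting.

test_that("a homozygous deletion serializes to one correct VCF record", {
  ref <- tinyRef(chr1 = "AAAACGTTTT")
  sv <- mkPlacedSV(mkRecord("DEL", "chr1", 4, 8), id = "d1", rule = "A->")
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "one.vcf")
  writeVcfTruthset(list(sv), ref, vcf)
  body <- grep("^#", readLines(vcf), invert = TRUE, value = TRUE)
  expect_length(body, 1)
  f <- strsplit(body, "\t")[[1]]
  expect_equal(f[1], "chr1")
  expect_equal(f[2], "4")                  # 1-based padding base before [4,8)
  expect_equal(f[5], "<DEL>")
  expect_match(f[8], "SVLEN=-4")
  expect_match(f[8], "END=8")
  expect_equal(f[10], "1|1")
})

test_that("zero SVs give a header-only VCF that tools accept", {
  ref <- tinyRef(chr1 = strrep("ACGT", 30))
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "empty.vcf")
  writeVcfTruthset(list(), ref, vcf)
  lines <- readLines(vcf)
  expect_true(all(startsWith(lines, "#")))
  v <- VariantAnnotation::readVcf(vcf)
  expect_length(v, 0)
})

test_that("complex SVs emit linked multi-record entries", {
  set.seed(31)
  ref <- tinyRef(chr1 = strrep("ACGTTAGCCA", 500))
  cx <- mkCategory("delINVdel", defaultDistances("delINVdel"), count = 1L)
  svs <- placeAll(list(cx), ref)
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "cx.vcf")
  writeVcfTruthset(svs, ref, vcf)
  body <- grep("^#", readLines(vcf), invert = TRUE, value = TRUE)
  expect_length(body, 3)
  parents <- sub(".*PARENT_SVID=([^;\t]+).*", "\\1", body)
  expect_length(unique(parents), 1)
  expect_true(all(grepl("GRAMMAR=ABC->b", body, fixed = TRUE)))
  kinds <- sub(".*SVTYPE=([^;\t]+).*", "\\1", body)
  expect_setequal(kinds, c("DEL", "INV"))
  expect_equal(sum(kinds == "DEL"), 2)
})

test_that("PAF lines follow the block walk of the assembly", {
  ref <- tinyRef(chr1 = strrep("ACGTTAGCCA", 100))   # 1 kb
  dir <- withr::local_tempdir()

  # SV-free: one full-length + strand line
  out <- buildHaplotype(ref, list(), 0L)
  paf <- file.path(dir, "plain.paf")
  writePaf(out$assembly, paf)
  f <- strsplit(readLines(paf), "\t")
  expect_length(f, 1)
  expect_equal(f[[1]][3:5], c("0", "1000", "+"))
  expect_equal(f[[1]][7:9], c("1000", "0", "1000"))

  # single inversion: three lines, middle one on the minus strand
  inv <- mkPlacedSV(mkRecord("INV", "chr1", 400, 600))
  out <- buildHaplotype(ref, list(inv), 0L)
  writePaf(out$assembly, paf)
  f <- strsplit(readLines(paf), "\t")
  expect_length(f, 3)
  expect_equal(vapply(f, `[[`, "", 5), c("+", "-", "+"))

  # single deletion: two lines whose target gap equals the deleted length
  del <- mkPlacedSV(mkRecord("DEL", "chr1", 400, 650))
  out <- buildHaplotype(ref, list(del), 0L)
  writePaf(out$assembly, paf)
  f <- strsplit(readLines(paf), "\t")
  expect_length(f, 2)
  gap <- as.numeric(f[[2]][8]) - as.numeric(f[[1]][9])
  expect_equal(gap, 250)
})

test_that("lifting sampled haplotype positions recovers the reference base", {
  set.seed(32)
  dir <- withr::local_tempdir()
  fx <- oracleFixture(33, dir)
  cats <- lapply(c("DEL", "INV", "dDUP", "INS"), function(tp)
    mkCategory(tp, defaultDistances(tp), count = 3L, homozygousProb = 0.5))
  svs <- placeAll(cats, fx$reference, rois = fx$rois)
  out <- buildHaplotype(fx$reference, svs, 0L)
  for (qn in names(out$assembly@qlens)) {
    qlen <- out$assembly@qlens[[qn]]
    for (qpos in sort(sample.int(qlen, 100) - 1)) {
      hit <- liftToReference(out$assembly, qn, qpos)
      if (is.null(hit)) next   # novel-origin block
      hb <- as.character(subseq(out$sequences[[qn]], qpos + 1, qpos + 1))
      rb <- as.character(subseq(fx$reference[[hit$tname]],
                                hit$tpos + 1, hit$tpos + 1))
      if (hit$strand == "-")
        rb <- as.character(reverseComplement(DNAString(rb)))
      expect_equal(hb, rb)
    }
  }
})

test_that("statistics account for counts, sizes and chromosome deltas", {
  ref <- tinyRef(chr1 = "AAAACGTTTT")
  sv <- mkPlacedSV(mkRecord("DEL", "chr1", 4, 8), id = "d1", type = "DEL",
                   rule = "A->")
  hapA <- buildHaplotype(ref, list(sv), 0L)
  hapB <- buildHaplotype(ref, list(sv), 1L)
  dir <- withr::local_tempdir()
  statsPath <- file.path(dir, "stats.tsv")
  tab <- writeStats(list(sv), list(hapA$assembly, hapB$assembly), statsPath)
  expect_equal(tab$value[tab$metric == "count" & tab$group == "DEL"], 1)
  expect_equal(tab$value[tab$metric == "length_delta"], c(-4, -4))
  onDisk <- read.delim(statsPath)
  expect_equal(onDisk$value, tab$value)

  # zero SVs: all deltas zero
  h0 <- buildHaplotype(ref, list(), 0L)
  tab0 <- writeStats(list(), list(h0$assembly, h0$assembly),
                     file.path(dir, "s0.tsv"))
  expect_true(all(tab0$value[tab0$metric == "length_delta"] == 0))
})

test_that("truthsets round-trip: import reproduces type, coords, zygosity", {
  set.seed(33)
  dir <- withr::local_tempdir()
  fx <- oracleFixture(34, dir)
  cats <- lapply(c("DEL", "INV", "DUP", "dDUP", "delINVdel"), function(tp)
    mkCategory(tp, defaultDistances(tp), count = 2L, homozygousProb = 0.5))
  svs <- placeAll(cats, fx$reference, rois = fx$rois)
  vcf <- file.path(dir, "rt.vcf")
  writeVcfTruthset(svs, fx$reference, vcf)
  imp <- importVcfSVs(vcf, fx$reference)
  expect_length(imp, length(svs))
  impById <- setNames(imp, vapply(imp, svId, ""))
  for (sv in svs) {
    got <- impById[[svId(sv)]]
    expect_false(is.null(got))
    expect_equal(svHaplotypes(got), svHaplotypes(sv))
    expect_equal(gsub("→", "->", got@type, fixed = TRUE),
                 gsub("→", "->", ruleIdentifier(svRule(sv)), fixed = TRUE))
    a <- svRecords(got)[, c("kind", "chrom", "start", "end")]
    b <- svRecords(sv)[, c("kind", "chrom", "start", "end")]
    expect_equal(a[do.call(order, a), ], b[do.call(order, b), ],
                 ignore_attr = TRUE)
  }
  # re-simulating the imported truthset reproduces the haplotypes
  re <- placeAll(list(new("SVCategory", type = "vcf_import",
                          rule = parseRule("A→A"), distances = list(),
                          constraints = list(), count = 1L,
                          homozygousProb = 0.5, interchromosomal = FALSE,
                          insertionSource = "random", copyRange = c(1L, 1L),
                          vcfPath = vcf)),
                fx$reference)
  for (h in 0:1) {
    expect_equal(
      as.character(buildHaplotype(fx$reference, re, h)$sequences),
      as.character(buildHaplotype(fx$reference, svs, h)$sequences))
  }
})
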