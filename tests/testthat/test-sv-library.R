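# Predefined SV type registry, VCF import, SNPs and tandem-repeat events.

test_that("the registry holds exactly 26 unique, parseable types", {
  reg <- svTypeRegistry()
  expect_equal(nrow(reg), 26L)
  expect_equal(registrySize(), 26L)
  expect_false(anyDuplicated(reg$name) > 0)
  for (i in seq_len(nrow(reg))) {
    rule <- parseRule(reg$rule[i])
    ops <- deriveOperations(rule)
    expect_true(nrow(ops) >= 0, label = reg$name[i])
  }
})

test_that("the registry covers the canonical SV class families", {
  nm <- svTypeRegistry()$name
  required <- c("DEL", "INS", "INV", "DUP", "dDUP", "INV_dDUP", "invDUP",
                "delINV", "INVdel", "delINVdel", "dupINV", "INVdup",
                "dupINVdup", "rTRA", "rTRA_INTER", "TR_EXPANSION",
                "TR_CONTRACTION", "SNP")
  expect_true(all(required %in% nm))
})

test_that("lookup returns rules by name and fails helpfully otherwise", {
  expect_equal(ruleIdentifier(lookupType("DEL")$rule), "A→")
  expect_equal(ruleIdentifier(lookupType("delINVdel")$rule), "ABC→b")
  expect_true(lookupType("rTRA_INTER")$interchromosomal)
  expect_error(lookupType(""), "non-empty")
  expect_error(lookupType("DELL"), "valid names")
})

test_that("fixed SVs round-trip through VCF emission and import", {
  ref <- tinyRef(chr1 = strrep("ACGTTGCA", 200))   # 1600 bp
  svs <- list(
    mkPlacedSV(mkRecord("DEL", "chr1", 100, 200), id = "svA", rule = "A->",
               haplotypes = 0:1),
    mkPlacedSV(mkRecord("INV", "chr1", 400, 480), id = "svB", rule = "A->a",
               haplotypes = 0L))
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "t.vcf")
  writeVcfTruthset(svs, ref, vcf)
  imp <- importVcfSVs(vcf, ref)
  expect_length(imp, 2)
  byId <- setNames(imp, vapply(imp, svId, ""))
  expect_true(all(vapply(imp, function(s) s@fixed, TRUE)))
  expect_equal(svRecords(byId[["svA"]])$start, 100)
  expect_equal(svRecords(byId[["svA"]])$end, 200)
  expect_equal(svRecords(byId[["svA"]])$kind, "DEL")
  expect_equal(svHaplotypes(byId[["svA"]]), 0:1)
  expect_equal(svHaplotypes(byId[["svB"]]), 0L)
  expect_equal(svRecords(byId[["svB"]])$kind, "INV")
})

test_that("a header-only VCF imports as an empty SV list", {
  ref <- tinyRef(chr1 = strrep("ACGT", 100))
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "empty.vcf")
  writeVcfTruthset(list(), ref, vcf)
  expect_length(importVcfSVs(vcf, ref), 0)
})

test_that("records beyond the contig bounds are rejected by name", {
  ref <- tinyRef(chr1 = strrep("ACGT", 50))   # 200 bp
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "bad.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=200>",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\tbadrec\tA\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=900\tGT\t1|1"),
    vcf)
  expect_error(importVcfSVs(vcf, ref), "badrec.*bounds")
})

test_that("imported complex SVs without grammar annotation fail loudly", {
  ref <- tinyRef(chr1 = strrep("ACGT", 500))
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "cx.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=2000>",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=PARENT_SVID,Number=1,Type=String,Description=\"p\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\tr1\tA\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=150;PARENT_SVID=cx1\tGT\t1|1",
    "chr1\t150\tr2\tA\t<INV>\t.\tPASS\tSVTYPE=INV;END=250;PARENT_SVID=cx1\tGT\t1|1"),
    vcf)
  expect_error(importVcfSVs(vcf, ref), "GRAMMAR")
})

test_that("SNP expansion substitutes single bases with a different allele", {
  set.seed(42)
  ref <- tinyRef(chr1 = strrep("ACGTGGCCAT", 1000))  # 10 kb
  cat <- mkCategory("SNP", list(A = c(1, 1)), count = 10L)
  svs <- expandSmallVariants(cat, ref)
  expect_length(svs, 10)
  for (sv in svs) {
    r <- svRecords(sv)
    expect_equal(r$kind, "SNP")
    refBase <- as.character(subseq(ref[["chr1"]], r$start + 1, r$end))
    expect_true(r$seq %in% c("A", "C", "G", "T"))
    expect_false(r$seq == refBase)
  }
  expect_length(expandSmallVariants(cat, ref, n = 0), 0)
})

test_that("a SNP forced under a near-total blacklist lands on the free base", {
  set.seed(7)
  ref <- tinyRef(chr1 = paste(rep("ACGT", 3), collapse = ""))  # 12 bp
  bl <- grTrack("chr1", 0, 11, "bl")
  cat <- mkCategory("SNP", list(A = c(1, 1)), count = 1L)
  params <- defaultParams(maxPlacementAttempts = 500L)
  svs <- expandSmallVariants(cat, ref, blacklist = bl, params = params)
  expect_equal(svRecords(svs[[1]])$start, 11)
})

test_that("tandem repeat events expand and contract motif copies exactly", {
  motif <- "CAG"
  flank <- strrep("TTTTAATTCC", 20)
  ref <- tinyRef(chr1 = paste0(flank, strrep(motif, 10), flank))
  s0 <- nchar(flank); e0 <- s0 + 30
  roi <- list(chrom = "chr1", start = s0, end = e0, label = "TR_CAG")

  sv <- tandemRepeatEvent(roi, ref, delta = 5)
  hap <- buildHaplotype(ref, list(sv), 0L)$sequences[[1]]
  locus <- as.character(subseq(hap, s0 + 1, s0 + 15 * 3))
  expect_equal(locus, strrep(motif, 15))
  # the base right after the expanded locus is non-motif flank
  expect_equal(as.character(subseq(hap, s0 + 45 + 1, s0 + 45 + 1)), "T")

  sv0 <- tandemRepeatEvent(roi, ref, delta = 0)
  hap0 <- buildHaplotype(ref, list(sv0), 0L)$sequences[[1]]
  expect_equal(as.character(hap0), as.character(ref[[1]]))

  sv3 <- tandemRepeatEvent(roi, ref, delta = -3)
  hap3 <- buildHaplotype(ref, list(sv3), 0L)$sequences[[1]]
  expect_equal(as.character(subseq(hap3, s0 + 1, s0 + 21)), strrep(motif, 7))

  expect_error(tandemRepeatEvent(roi, ref, delta = -12), "underflow")
})

test_that("replaying one simulated instance of every registry type matches", {
  # one homozygous instance per type on a fixture; emitted VCF replayed by
  # the naive editor must equal the built haplotype byte-for-byte
  dir <- withr::local_tempdir()
  fx <- oracleFixture(101, dir)
  ref <- fx$reference
  for (tp in allRegistryTypes()) {
    set.seed(match(tp, allRegistryTypes()) * 13)
    cat <- mkCategory(tp, defaultDistances(tp), count = 1L,
                      homozygousProb = 1)
    svs <- placeAll(list(cat), ref, rois = fx$rois,
                    params = defaultParams(maxPlacementAttempts = 300L))
    vcf <- file.path(dir, paste0(tp, ".vcf"))
    writeVcfTruthset(svs, ref, vcf)
    built <- buildHaplotype(ref, svs, 0L)$sequences
    replayed <- replayOracle(ref, vcf)[[1]]
    expect_identical(as.character(built), as.character(replayed), label = tp)
  }
})
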