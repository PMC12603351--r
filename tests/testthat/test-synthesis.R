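# Haplotype construction against naive string-splice oracles, assembly
# tiling, length accounting and insertion sequence generation.

test_that("single edits reproduce hand-computed splices", {
  ref <- tinyRef(chr1 = "AAAACGTTTT")

  inv <- mkPlacedSV(mkRecord("INV", "chr1", 4, 8))
  expect_equal(as.character(buildHaplotype(ref, list(inv), 0L)$sequences[[1]]),
               "AAAAAACGTT")   # revcomp("CGTT") = "AACG"

  del <- mkPlacedSV(mkRecord("DEL", "chr1", 4, 8))
  expect_equal(as.character(buildHaplotype(ref, list(del), 0L)$sequences[[1]]),
               "AAAATT")

  dup <- mkPlacedSV(mkRecord("DUP", "chr1", 4, 8, srcChrom = "chr1",
                             srcStart = 4, srcEnd = 8))
  seq <- as.character(buildHaplotype(ref, list(dup), 0L)$sequences[[1]])
  expect_equal(seq, "AAAACGTTCGTTTT")
  expect_equal(nchar(seq), 14)
})

test_that("an SV-free genome is the reference with one full-length block", {
  ref <- tinyRef(chr1 = strrep("ACGT", 25), chr2 = strrep("TTGCA", 10))
  out <- buildHaplotype(ref, list(), 0L)
  expect_equal(as.character(out$sequences),
               setNames(as.character(ref), c("chr1_hapA", "chr2_hapA")))
  b <- assemblyBlocks(out$assembly)
  expect_equal(nrow(b), 2)
  expect_equal(b$qstart, c(0, 0))
  expect_equal(b$qend, c(100, 50))
  expect_equal(b$strand, c("+", "+"))
})

test_that("haplotype length equals reference plus insertions minus deletions", {
  set.seed(11)
  dir <- withr::local_tempdir()
  fx <- oracleFixture(31, dir)
  ref <- fx$reference
  cats <- list(mkCategory("DEL", list(A = c(100, 400)), count = 5L),
               mkCategory("INS", list(A = c(50, 150)), count = 4L),
               mkCategory("DUP", list(A = c(100, 200)), count = 3L))
  svs <- placeAll(cats, ref, rois = fx$rois)
  out <- buildHaplotype(ref, svs, 0L)
  delta <- 0
  for (sv in svs) {
    r <- svRecords(sv)
    for (i in seq_len(nrow(r))) {
      delta <- delta + switch(r$kind[i],
        DEL = -(r$end[i] - r$start[i]),
        DUP = r$copies[i] * (r$srcEnd[i] - r$srcStart[i]),
        INS = r$copies[i] * nchar(r$seq[i]),
        0)
    }
  }
  expect_equal(sum(width(out$sequences)), sum(width(ref)) + delta)
})

test_that("assembly blocks tile every synthetic contig without gaps", {
  set.seed(12)
  dir <- withr::local_tempdir()
  fx <- oracleFixture(32, dir)
  cats <- lapply(c("DEL", "INV", "dDUP", "delINVdel", "nrTRA"),
                 function(tp) mkCategory(tp, defaultDistances(tp), count = 2L,
                                         homozygousProb = 0.5))
  svs <- placeAll(cats, fx$reference, rois = fx$rois)
  for (h in 0:1) {
    out <- buildHaplotype(fx$reference, svs, h)
    b <- assemblyBlocks(out$assembly)
    for (qn in names(out$assembly@qlens)) {
      bb <- b[b$qname == qn, ]
      bb <- bb[order(bb$qstart), ]
      expect_equal(bb$qstart[1], 0)
      expect_equal(bb$qend[nrow(bb)], unname(out$assembly@qlens[qn]))
      if (nrow(bb) > 1)
        expect_equal(bb$qstart[-1], bb$qend[-nrow(bb)])
    }
    # concatenated block sequences equal the emitted haplotype
    for (qn in names(out$assembly@qlens)) {
      bb <- b[b$qname == qn, ]
      bb <- bb[order(bb$qstart), ]
      pieces <- vapply(seq_len(nrow(bb)), function(i) {
        r <- bb[i, ]
        if (r$origin == "novel") return(r$seq)
        s <- subseq(fx$reference[[r$tname]], r$tstart + 1, r$tend)
        if (r$strand == "-") s <- reverseComplement(s)
        as.character(s)
      }, "")
      expect_equal(paste(pieces, collapse = ""),
                   as.character(out$sequences[[qn]]))
    }
  }
})

test_that("dispersed duplications copy their segment across the dispersion", {
  set.seed(13)
  ref <- tinyRef(chr1 = strrep("ACGTTAGCCA", 500))  # 5 kb
  cat <- mkCategory("dDUP", list(A = c(40, 40), "_1" = c(100, 100)),
                    count = 1L, homozygousProb = 1)
  svs <- placeAll(list(cat), ref)
  iv <- svIntervals(svs[[1]])
  a <- iv[iv$symbol == "A", ]
  d <- iv[iv$symbol == "_1", ]
  refStr <- as.character(ref[[1]])
  aSeq <- substr(refStr, a$start + 1, a$end)
  expected <- paste0(substr(refStr, 1, d$end),        # through the dispersion
                     aSeq,                            # the dispersed copy
                     substr(refStr, d$end + 1, nchar(refStr)))
  hap <- as.character(buildHaplotype(ref, svs, 0L)$sequences[[1]])
  expect_equal(hap, expected)

  # cut-paste across the dispersion (nrTRA): A moves, origin is deleted
  cat <- mkCategory("nrTRA", list(A = c(40, 40), "_1" = c(100, 100)),
                    count = 1L, homozygousProb = 1)
  svs <- placeAll(list(cat), ref)
  iv <- svIntervals(svs[[1]])
  a <- iv[iv$symbol == "A", ]
  d <- iv[iv$symbol == "_1", ]
  aSeq <- substr(refStr, a$start + 1, a$end)
  expected <- paste0(substr(refStr, 1, a$start),
                     substr(refStr, a$end + 1, d$end),
                     aSeq,
                     substr(refStr, d$end + 1, nchar(refStr)))
  hap <- as.character(buildHaplotype(ref, svs, 0L)$sequences[[1]])
  expect_equal(hap, expected)
})

test_that("inverting the same interval twice returns the original sequence", {
  ref <- tinyRef(chr1 = strrep("ACGTTAGCCA", 20))
  inv <- mkPlacedSV(mkRecord("INV", "chr1", 50, 120))
  once <- buildHaplotype(ref, list(inv), 0L)$sequences
  refOnce <- Biostrings::DNAStringSet(setNames(as.character(once), "chr1"))
  twice <- buildHaplotype(refOnce, list(inv), 0L)$sequences
  expect_equal(as.character(twice[[1]]), as.character(ref[[1]]))
})

test_that("insertion sequences honour length, seed and file sources", {
  set.seed(21)
  a <- generateInsertionSequence(4)
  set.seed(21)
  b <- generateInsertionSequence(4)
  expect_identical(a, b)
  expect_equal(nchar(a), 4)
  expect_error(generateInsertionSequence(0), ">= 1")

  dir <- withr::local_tempdir()
  pool <- file.path(dir, "ins.fa")
  writeLines(c(">rec1", "ACGTACGTAC"), pool)
  expect_equal(generateInsertionSequence(10, pool), "ACGTACGTAC")
  sub <- generateInsertionSequence(4, pool)
  expect_true(grepl(sub, "ACGTACGTAC", fixed = TRUE))
  expect_error(generateInsertionSequence(11, pool), "ins.fa")
})

test_that("the naive replay oracle agrees on simple and complex truthsets", {
  set.seed(22)
  ref <- tinyRef(chr1 = strrep("ACGTTAGCCA", 500))  # 5 kb
  dir <- withr::local_tempdir()

  # empty truthset: both haplotypes equal the reference
  vcf0 <- file.path(dir, "none.vcf")
  writeVcfTruthset(list(), ref, vcf0)
  rep0 <- replayOracle(ref, vcf0)
  expect_equal(as.character(rep0[[1]][[1]]), as.character(ref[[1]]))

  # one deletion
  del <- mkCategory("DEL", list(A = c(200, 400)), count = 1L)
  svs <- placeAll(list(del), ref)
  vcf1 <- file.path(dir, "del.vcf")
  writeVcfTruthset(svs, ref, vcf1)
  expect_identical(
    as.character(replayOracle(ref, vcf1)[[1]]),
    as.character(buildHaplotype(ref, svs, 0L)$sequences))

  # a three-record complex SV
  cx <- mkCategory("delINVdel", defaultDistances("delINVdel"), count = 1L)
  svs <- placeAll(list(cx), ref)
  vcf2 <- file.path(dir, "cx.vcf")
  writeVcfTruthset(svs, ref, vcf2)
  expect_identical(
    as.character(replayOracle(ref, vcf2)[[1]]),
    as.character(buildHaplotype(ref, svs, 0L)$sequences))
})
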