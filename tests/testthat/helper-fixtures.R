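# In-code fixtures shared across the suite: tiny references, category
# builders and a record constructor matching the PlacedSV record schema.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

tinyRef <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

writeRefFasta <- function(reference, dir = withr::local_tempdir()) {
  path <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(reference, path, width = 60)
  path
}

grTrack <- function(chrom, start0, end0, label = "roi") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         label = label)
}

defaultParams <- function(...) new("SimulationParams", ...)

# build a category directly in code, bypassing YAML
mkCategory <- function(type, distances = list(), count = 1L,
                       constraints = list(), homozygousProb = 1,
                       interchromosomal = NULL, copyRange = c(1L, 3L),
                       insertionSource = "random") {
  entry <- tryCatch(lookupType(type), error = function(e) NULL)
  rule <- if (is.null(entry)) parseRule(type) else entry$rule
  inter <- if (!is.null(interchromosomal)) interchromosomal
           else if (!is.null(entry)) entry$interchromosomal else FALSE
  new("SVCategory", type = type, rule = rule, distances = distances,
      constraints = constraints, count = as.integer(count),
      homozygousProb = homozygousProb, interchromosomal = inter,
      insertionSource = insertionSource,
      copyRange = as.integer(copyRange), vcfPath = NA_character_)
}

# default distance list for a registry type: every length-bearing symbol
# gets `letters`, dispersions get `disp`
defaultDistances <- function(type, letterRange = c(50, 200),
                             dispRange = c(300, 600)) {
  entry <- tryCatch(lookupType(type), error = function(e) NULL)
  rule <- if (is.null(entry)) parseRule(type) else entry$rule
  inter <- if (!is.null(entry)) entry$interchromosomal else FALSE
  syms <- svforge:::lengthBearingSymbols(rule, inter)
  if (!is.null(entry) && !is.na(entry$special)) {
    if (entry$special == "SNP") return(list(A = c(1, 1)))
    if (startsWith(entry$special, "TR_")) return(list(A = c(1, 5)))
  }
  d <- list()
  for (s in syms)
    d[[s]] <- if (startsWith(s, "_")) dispRange else letterRange
  d
}

# a PlacedSV built from an explicit record table (schema of svRecords())
mkRecord <- function(kind, chrom, start, end, srcChrom = NA_character_,
                     srcStart = NA_real_, srcEnd = NA_real_,
                     srcInverted = FALSE, copies = 1L, seq = NA_character_,
                     symbol = "A", operation = kind, slot = 1L) {
  data.frame(kind = kind, chrom = chrom, start = start, end = end,
             srcChrom = srcChrom, srcStart = srcStart, srcEnd = srcEnd,
             srcInverted = srcInverted, copies = as.integer(copies),
             seq = seq, symbol = symbol, operation = operation,
             slot = as.integer(slot), stringsAsFactors = FALSE)
}

mkPlacedSV <- function(records, id = "sv1", type = "custom",
                       rule = "A->A", haplotypes = 0:1,
                       intervals = NULL) {
  if (is.null(intervals)) {
    w <- records$end > records$start
    intervals <- data.frame(symbol = records$symbol[w],
                            chrom = records$chrom[w],
                            start = records$start[w], end = records$end[w],
                            stringsAsFactors = FALSE)
  }
  new("PlacedSV", id = id, type = type, rule = parseRule(rule),
      intervals = intervals, targetInfo = data.frame(), records = records,
      haplotypes = as.integer(haplotypes), fixed = FALSE)
}

# write a YAML config + return its path
writeConfig <- function(dir, reference, sets, global = list()) {
  cfg <- c(list(reference = reference), global, list(variant_sets = sets))
  path <- file.path(dir, "sim.yaml")
  yaml::write_yaml(cfg, path)
  path
}

varset <- function(type, number, length_ranges = NULL, ...) {
  s <- list(type = type, number = number, ...)
  if (!is.null(length_ranges)) s$length_ranges <- length_ranges
  s
}

allRegistryTypes <- function() svTypeRegistry()$name

# random test genome with TR loci and two chromosomes (for inter-chrom SVs)
oracleFixture <- function(seed, dir) {
  spec <- fixtureSpec(
    chromLengths = c(chrA = 50000, chrB = 30000), gc = 0.45,
    repeatPlan = data.frame(motif = "CAG", copies = 30L, count = 5L,
                            stringsAsFactors = FALSE),
    seed = seed)
  makeReference(spec, dir)
}
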