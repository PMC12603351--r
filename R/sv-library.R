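# Built-in library of predefined SV types, VCF import of fixed SVs, and the
# small-variant / tandem-repeat event machinery.

# name -> (rule, roles, interchromosomal default, special handling tag)
.registryEntry <- function(name, rule, desc, interchromosomal = FALSE,
                           special = NA_character_) {
  list(name = name, ruleString = rule, description = desc,
       interchromosomal = interchromosomal, special = special)
}

.SV_REGISTRY <- list(
  .registryEntry("DEL", "A→", "deletion of A"),
  .registryEntry("INS", "→A", "novel insertion of A"),
  .registryEntry("INV", "A→a", "inversion of A"),
  .registryEntry("DUP", "A→AA", "tandem duplication of A"),
  .registryEntry("invDUP", "A→Aa", "inverted tandem duplication (copy after)"),
  .registryEntry("invDUP2", "A→aA", "inverted tandem duplication (copy before)"),
  .registryEntry("mCNV", "A→AA+", "multi-copy tandem amplification of A"),
  .registryEntry("SNP", "A→A", "single-nucleotide substitution",
                 special = "SNP"),
  .registryEntry("dDUP", "A_→A_A", "dispersed duplication of A"),
  .registryEntry("INV_dDUP", "A_→A_a", "inverted dispersed duplication of A"),
  .registryEntry("nrTRA", "A_→_A", "non-reciprocal translocation of A"),
  .registryEntry("INV_nrTRA", "A_→_a", "inverted non-reciprocal translocation"),
  .registryEntry("rTRA", "A_B→B_A", "reciprocal translocation (intra-chromosomal)"),
  .registryEntry("rTRA_INTER", "A_B→B_A",
                 "reciprocal translocation (inter-chromosomal)",
                 interchromosomal = TRUE),
  .registryEntry("delINV", "AB→b", "deletion of A, inversion of B"),
  .registryEntry("INVdel", "AB→a", "inversion of A, deletion of B"),
  .registryEntry("delINVdel", "ABC→b", "inversion flanked by two deletions"),
  .registryEntry("dupINV", "AB→Aba", "inverted duplication at an inversion (left flank)"),
  .registryEntry("INVdup", "AB→baB", "inverted duplication at an inversion (right flank)"),
  .registryEntry("dupINVdup", "ABC→AcbaC", "inversion flanked by two inverted duplications"),
  .registryEntry("delINVdup", "ABC→cbC", "deletion, inversion, inverted duplication"),
  .registryEntry("dupINVdel", "ABC→Aba", "inverted duplication, inversion, deletion"),
  .registryEntry("dDUP_iDEL", "A_B→A_A", "dispersed duplication with deletion at the insertion site"),
  .registryEntry("INS_iDEL", "A_B→_A", "translocated insertion with deletion at the insertion site"),
  .registryEntry("TR_EXPANSION", "A→AA+", "tandem repeat expansion",
                 special = "TR_EXPANSION"),
  .registryEntry("TR_CONTRACTION", "A→", "tandem repeat contraction",
                 special = "TR_CONTRACTION")
)
names(.SV_REGISTRY) <- vapply(.SV_REGISTRY, `[[`, "", "name")

#' The predefined SV type registry
#'
#' The library of 26 predefined SV types. Each entry carries a name, its
#' rearrangement rule and a one-line description. Types can equally be
#' simulated by their grammar expression; the registry only provides the
#' conventional names.
#'
#' @return a data.frame with columns \code{name, rule, description,
#'   interchromosomal, special}.
#' @export
svTypeRegistry <- function() {
  data.frame(
    name = vapply(.SV_REGISTRY, `[[`, "", "name"),
    rule = vapply(.SV_REGISTRY, `[[`, "", "ruleString"),
    description = vapply(.SV_REGISTRY, `[[`, "", "description"),
    interchromosomal = vapply(.SV_REGISTRY, `[[`, FALSE, "interchromosomal"),
    special = vapply(.SV_REGISTRY, `[[`, "", "special"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Number of predefined SV types
#' @return the registry size (26).
#' @export
registrySize <- function() length(.SV_REGISTRY)

#' Look up a predefined SV type by name
#'
#' @param name registry identifier (case-sensitive), e.g. \code{"delINVdel"}.
#' @return a list with elements \code{name}, \code{rule} (a parsed
#'   [RearrangementRule-class]), \code{description}, \code{interchromosomal}
#'   and \code{special}.
#' @export
lookupType <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    svError("SV type name must be a non-empty string", "svforgeLookupError")
  entry <- .SV_REGISTRY[[name]]
  if (is.null(entry)) {
    near <- agrep(name, names(.SV_REGISTRY), max.distance = 2, value = TRUE)
    hint <- if (length(near))
      sprintf(" (did you mean %s?)", paste(near, collapse = ", ")) else ""
    svError(sprintf(
      "unknown SV type '%s'%s; valid names: %s", name, hint,
      paste(names(.SV_REGISTRY), collapse = ", ")), "svforgeLookupError")
  }
  entry$rule <- parseRule(entry$ruleString)
  entry
}

# ---- VCF import of fixed SVs ----------------------------------------------

parseGT <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(0:1)
  al <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
  if (length(al) != 2L || any(is.na(al))) return(0:1)
  haps <- which(al > 0) - 1L
  if (!length(haps)) 0:1 else as.integer(haps)
}

#' Import pre-specified SVs from a VCF
#'
#' Reads a VCF of existing SVs to be incorporated verbatim: the exact type
#' and breakpoint positions from the file are used and random placement is
#' bypassed. Simple symbolic records (\code{<DEL>}, \code{<INV>},
#' \code{<DUP>}, \code{<INS>}) and SNP-like base records are understood
#' directly; complex multi-record SVs require the \code{GRAMMAR} and
#' \code{PARENT_SVID} annotations emitted by [writeVcfTruthset()].
#'
#' @param path VCF file.
#' @param reference optional \code{DNAStringSet}; when given, record
#'   coordinates are validated against its contig bounds (otherwise the VCF
#'   header contig lengths are used when present).
#' @return a list of [PlacedSV-class] objects with \code{fixed = TRUE}.
#' @export
importVcfSVs <- function(path, reference = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  if (n == 0L) return(list())
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  getInfo <- function(key, i, default = NA) {
    if (!key %in% colnames(info)) return(default)
    v <- info[[key]][i]
    if (is(v, "List") || is.list(v)) v <- unlist(v)
    if (!length(v) || is.na(v[1])) default else v[1]
  }
  bounds <- if (!is.null(reference)) {
    stats::setNames(Biostrings::width(reference), names(reference))
  } else {
    sl <- GenomeInfoDb::seqlengths(rr)
    sl[!is.na(sl)]
  }
  gts <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    chrom <- as.character(GenomicRanges::seqnames(rr))[i]
    pos <- GenomicRanges::start(rr)[i]
    id <- names(rr)[i]
    alt <- as.character(unlist(rr$ALT[i]))[1]
    ref <- as.character(rr$REF[i])
    svtype <- getInfo("SVTYPE", i, NA_character_)
    if (is.na(svtype)) {
      svtype <- if (nchar(ref) == 1L && !is.na(alt) && nchar(alt) == 1L &&
                    !grepl("[<>]", alt)) "SNP"
      else svError(sprintf("record %s: unparseable SVTYPE", id),
                   "svforgeImportError")
    }
    zstart <- isTRUE(getInfo("ZSTART", i, FALSE))
    start0 <- if (zstart) 0 else pos
    end0 <- as.numeric(getInfo("END", i, start0))
    if (svtype == "SNP") { start0 <- pos - 1; end0 <- pos }
    if (svtype == "INS") end0 <- start0
    if (length(bounds) && chrom %in% names(bounds)) {
      if (max(start0, end0) > bounds[[chrom]] || min(start0, end0) < 0)
        svError(sprintf("record %s: coordinates beyond contig %s bounds",
                        id, chrom), "svforgeImportError")
    } else if (length(bounds)) {
      svError(sprintf("record %s: contig %s not present in reference",
                      id, chrom), "svforgeImportError")
    }
    srcStart <- getInfo("SRC_START", i, NA)
    recs[[i]] <- data.frame(
      kind = if (svtype == "SNP") "SNP" else svtype,
      chrom = chrom, start = start0, end = end0,
      srcChrom = as.character(getInfo("SRC_CHROM", i, NA_character_)),
      srcStart = if (is.na(srcStart)) NA_real_ else as.numeric(srcStart) - 1,
      srcEnd = as.numeric(getInfo("SRC_END", i, NA)),
      srcInverted = isTRUE(getInfo("SRC_INVERTED", i, FALSE)),
      copies = as.integer(getInfo("COPIES", i, 1L)),
      seq = {
        s <- as.character(getInfo("INSSEQ", i, NA_character_))
        if (svtype == "SNP") alt else s
      },
      symbol = as.character(getInfo("SYMBOL", i, "A")),
      operation = as.character(getInfo("OPERATION", i, svtype)),
      slot = as.integer(getInfo("SLOT", i, 1L)),
      parent = as.character(getInfo("PARENT_SVID", i, NA_character_)),
      grammar = as.character(getInfo("GRAMMAR", i, NA_character_)),
      gt = if (!is.null(gts)) as.character(gts[i, 1]) else NA_character_,
      recId = if (is.null(id) || is.na(id) || id == ".") sprintf("rec%d", i) else id,
      stringsAsFactors = FALSE
    )
    if (!svtype %in% c("DEL", "INV", "DUP", "INS", "SNP"))
      svError(sprintf("record %s: unsupported SVTYPE '%s'", id, svtype),
              "svforgeImportError")
  }
  tab <- do.call(rbind, recs)
  tab$parent[is.na(tab$parent)] <- tab$recId[is.na(tab$parent)]
  out <- list()
  for (p in unique(tab$parent)) {
    sub <- tab[tab$parent == p, , drop = FALSE]
    grammar <- sub$grammar[!is.na(sub$grammar)]
    typeName <- if (length(grammar)) grammar[1] else sub$kind[1]
    rule <- if (length(grammar)) parseRule(grammar[1]) else {
      tryCatch(lookupType(typeName)$rule, error = function(e) parseRule("A→A"))
    }
    if (nrow(sub) > 1 && !length(grammar))
      svError(sprintf(
        "multi-record SV %s lacks a GRAMMAR annotation or registry type", p),
        "svforgeImportError")
    haps <- parseGT(sub$gt[1])
    records <- sub[, c("kind", "chrom", "start", "end", "srcChrom",
                       "srcStart", "srcEnd", "srcInverted", "copies", "seq",
                       "symbol", "operation", "slot"), drop = FALSE]
    rownames(records) <- NULL
    iv <- recordIntervals(records)
    out[[length(out) + 1L]] <- new("PlacedSV", id = p, type = typeName,
      rule = rule, intervals = iv, targetInfo = data.frame(),
      records = records, haplotypes = haps, fixed = TRUE)
  }
  out
}

# Approximate symbol intervals from a resolved record table (used for
# imported SVs, overlap booking and audits).
recordIntervals <- function(records) {
  rows <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$kind %in% c("DEL", "INV", "DUP", "SNP") && r$end > r$start) {
      rows[[length(rows) + 1L]] <- data.frame(
        symbol = r$symbol, chrom = r$chrom, start = r$start, end = r$end,
        stringsAsFactors = FALSE)
    } else if (r$kind == "INS" && !is.na(r$srcStart)) {
      rows[[length(rows) + 1L]] <- data.frame(
        symbol = r$symbol, chrom = r$srcChrom, start = r$srcStart,
        end = r$srcEnd, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(symbol = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, rows))
}
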