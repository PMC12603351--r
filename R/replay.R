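# Independent naive replay oracle: reconstructs both haplotypes from an
# emitted truthset VCF by plain string splicing, record by record, with no
# assembly bookkeeping. Used to cross-check buildHaplotype() in tests.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
          a = "t", c = "g", g = "c", t = "a", n = "n")

naiveRevcomp <- function(s) {
  chars <- rev(strsplit(s, "")[[1]])
  paste(COMP[chars], collapse = "")
}

parseInfoField <- function(info) {
  out <- list()
  for (kv in strsplit(info, ";", fixed = TRUE)[[1]]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) out[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    else out[[kv]] <- TRUE
  }
  out
}

readVcfNaive <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(list())
  lapply(body, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    info <- parseInfoField(f[8])
    gt <- if (length(f) >= 10) f[10] else "1|1"
    num <- function(key, default = NA_real_) {
      v <- info[[key]]
      if (is.null(v)) default else as.numeric(v)
    }
    svtype <- if (is.null(info$SVTYPE)) "SNP" else info$SVTYPE
    pos <- as.numeric(f[2])
    zstart <- isTRUE(info$ZSTART)
    start0 <- if (svtype == "SNP") pos - 1 else if (zstart) 0 else pos
    list(chrom = f[1], pos = pos, ref = f[4], alt = f[5], svtype = svtype,
         start0 = start0, end0 = num("END", start0),
         srcChrom = if (is.null(info$SRC_CHROM)) NA_character_ else info$SRC_CHROM,
         srcStart0 = num("SRC_START") - 1, srcEnd0 = num("SRC_END"),
         srcInverted = isTRUE(info$SRC_INVERTED),
         copies = if (is.null(info$COPIES)) 1L else as.integer(info$COPIES),
         insseq = if (is.null(info$INSSEQ)) NA_character_ else info$INSSEQ,
         slot = if (is.null(info$SLOT)) 0L else as.integer(info$SLOT),
         gt = gt)
  })
}

gtHasHap <- function(gt, hap) {
  al <- strsplit(gt, "[/|]")[[1]]
  length(al) >= hap + 1 && al[hap + 1] == "1"
}

#' Replay a truthset VCF with a naive string editor
#'
#' A deliberately simple, operation-by-operation reconstruction of both
#' haplotypes from the reference and an emitted VCF: records are applied per
#' chromosome in descending coordinate order (point insertions after the
#' interval operations that start at the same coordinate, and in descending
#' slot order among themselves) by direct substring splicing. Copy sources
#' always read from the original reference. This shares no code with
#' [buildHaplotype()] and serves as its independent oracle.
#'
#' @param reference \code{DNAStringSet}.
#' @param vcfPath truthset VCF emitted by [writeVcfTruthset()].
#' @return list of two \code{DNAStringSet}s (haplotypes 0 and 1), contig
#'   names carrying the \code{_hapA}/\code{_hapB} suffix.
#' @export
replayOracle <- function(reference, vcfPath) {
  recs <- readVcfNaive(vcfPath)
  refStr <- stats::setNames(as.character(reference), names(reference))
  out <- list()
  for (hap in 0:1) {
    hapRecs <- Filter(function(r) gtHasHap(r$gt, hap), recs)
    chromSeqs <- refStr
    byChrom <- split(hapRecs, vapply(hapRecs, `[[`, "", "chrom"))
    for (chrom in names(byChrom)) {
      rs <- byChrom[[chrom]]
      # effective coordinate: point ops sort at their insertion point
      key <- vapply(rs, function(r) {
        switch(r$svtype, INS = r$start0, DUP = r$end0, r$start0)
      }, 0)
      isPoint <- vapply(rs, function(r) r$svtype %in% c("INS", "DUP"), TRUE)
      slot <- vapply(rs, `[[`, 0L, "slot")
      # descending position; interval ops before point ops at equal
      # position; descending slot among point ops at the same position
      ord <- order(-key, isPoint, -slot)
      s <- chromSeqs[[chrom]]
      for (r in rs[ord]) {
        if (r$svtype == "DEL") {
          s <- paste0(substr(s, 1, r$start0), substr(s, r$end0 + 1, nchar(s)))
        } else if (r$svtype == "INV") {
          s <- paste0(substr(s, 1, r$start0),
                      naiveRevcomp(substr(refStr[[chrom]], r$start0 + 1, r$end0)),
                      substr(s, r$end0 + 1, nchar(s)))
        } else if (r$svtype == "DUP") {
          piece <- substr(refStr[[r$chrom]], r$start0 + 1, r$end0)
          s <- paste0(substr(s, 1, r$end0),
                      strrep(piece, r$copies),
                      substr(s, r$end0 + 1, nchar(s)))
        } else if (r$svtype == "INS") {
          piece <- if (!is.na(r$insseq)) r$insseq
          else {
            p <- substr(refStr[[r$srcChrom]], r$srcStart0 + 1, r$srcEnd0)
            if (r$srcInverted) naiveRevcomp(p) else p
          }
          s <- paste0(substr(s, 1, r$start0),
                      strrep(piece, r$copies),
                      substr(s, r$start0 + 1, nchar(s)))
        } else if (r$svtype == "SNP") {
          substr(s, r$start0 + 1, r$start0 + 1) <- r$alt
        }
      }
      chromSeqs[[chrom]] <- s
    }
    dss <- Biostrings::DNAStringSet(chromSeqs)
    names(dss) <- paste0(names(chromSeqs), hapSuffix(hap))
    out[[hap + 1]] <- dss
  }
  out
}
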