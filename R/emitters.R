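# Truthset serialization: linked multi-record VCF with grammar annotations,
# PAF liftover files, and the statistics summary.
#
# VCF dialect: one record per atomic operation; symbolic ALT alleles for
# SVs (<DEL>, <INV>, <DUP>, <INS>), base alleles for SNPs. POS is the
# 1-based position of the padding base preceding the event; events starting
# at reference position 0 carry the ZSTART flag with POS=1. END is the
# 1-based inclusive end (== the 0-based half-open end). Records of one
# complex SV share PARENT_SVID and carry GRAMMAR (canonical rule, ASCII
# arrow), SYMBOL, OPERATION and SLOT. Dispersed/inverted copies are <INS> at
# the target with SRC_CHROM/SRC_START/SRC_END (1-based start) provenance.

vcfHeaderLines <- function(reference) {
  c("##fileformat=VCFv4.2",
    "##source=svforge",
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            Biostrings::width(reference)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT alleles\">",
    "##INFO=<ID=PARENT_SVID,Number=1,Type=String,Description=\"Identifier linking the records of one SV\">",
    "##INFO=<ID=GRAMMAR,Number=1,Type=String,Description=\"Rearrangement rule of the parent SV\">",
    "##INFO=<ID=SYMBOL,Number=1,Type=String,Description=\"Rule symbol this record operates on\">",
    "##INFO=<ID=OPERATION,Number=1,Type=String,Description=\"Edit operation this record represents\">",
    "##INFO=<ID=SLOT,Number=1,Type=Integer,Description=\"Target-side token index of the operation\">",
    "##INFO=<ID=SRC_CHROM,Number=1,Type=String,Description=\"Source chromosome of a copied segment\">",
    "##INFO=<ID=SRC_START,Number=1,Type=Integer,Description=\"1-based start of the copied source segment\">",
    "##INFO=<ID=SRC_END,Number=1,Type=Integer,Description=\"1-based inclusive end of the copied source segment\">",
    "##INFO=<ID=SRC_INVERTED,Number=0,Type=Flag,Description=\"Copied segment is reverse-complemented\">",
    "##INFO=<ID=COPIES,Number=1,Type=Integer,Description=\"Number of inserted copies\">",
    "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Inserted novel sequence\">",
    "##INFO=<ID=ZSTART,Number=0,Type=Flag,Description=\"Event starts at reference position 0 (no padding base)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
}

gtString <- function(haplotypes) {
  if (all(0:1 %in% haplotypes)) "1|1"
  else if (0 %in% haplotypes) "1|0"
  else "0|1"
}

recordSVLEN <- function(r) {
  switch(r$kind,
         DEL = -(r$end - r$start),
         INV = r$end - r$start,
         DUP = r$copies * (r$srcEnd - r$srcStart),
         INS = r$copies * (if (!is.na(r$srcStart)) r$srcEnd - r$srcStart
                           else nchar(r$seq)),
         SNP = 0)
}

#' Write the truthset VCF
#'
#' One coordinate-sorted record per atomic operation of every placed SV,
#' with genotype columns reflecting the haplotype assignment. See the
#' package vignette for the full dialect.
#'
#' @param svs list of [PlacedSV-class].
#' @param reference \code{DNAStringSet} (for padding bases and contig
#'   headers).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeVcfTruthset <- function(svs, reference, path) {
  rows <- list()
  for (sv in svs) {
    recs <- sv@records
    grammar <- gsub("→", "->", sv@rule@canonical, fixed = TRUE)
    nrec <- nrow(recs)
    for (i in seq_len(nrec)) {
      r <- recs[i, ]
      zstart <- r$start == 0 && r$kind != "SNP"
      pos1 <- if (r$kind == "SNP") r$start + 1 else max(1, r$start)
      refBase <- as.character(
        Biostrings::subseq(reference[[r$chrom]], pos1, pos1))
      if (r$kind == "SNP") {
        ref <- refBase; alt <- r$seq
      } else {
        ref <- refBase; alt <- sprintf("<%s>", r$kind)
      }
      info <- c(sprintf("SVTYPE=%s", r$kind),
                sprintf("END=%d", as.integer(if (r$kind == "SNP") r$end
                                             else max(r$end, pos1))),
                sprintf("SVLEN=%d", as.integer(recordSVLEN(r))),
                sprintf("PARENT_SVID=%s", sv@id),
                sprintf("GRAMMAR=%s", grammar),
                if (!is.na(r$symbol)) sprintf("SYMBOL=%s", r$symbol),
                sprintf("OPERATION=%s", r$operation),
                sprintf("SLOT=%d", r$slot),
                if (!is.na(r$srcStart)) c(
                  sprintf("SRC_CHROM=%s", r$srcChrom),
                  sprintf("SRC_START=%d", as.integer(r$srcStart + 1)),
                  sprintf("SRC_END=%d", as.integer(r$srcEnd))),
                if (isTRUE(r$srcInverted)) "SRC_INVERTED",
                if (r$copies != 1L) sprintf("COPIES=%d", r$copies),
                if (r$kind == "INS" && is.na(r$srcStart))
                  sprintf("INSSEQ=%s", r$seq),
                if (zstart) "ZSTART")
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = r$chrom, pos = as.integer(pos1),
        id = sprintf("%s_%d", sv@id, i), ref = ref, alt = alt,
        info = paste(info, collapse = ";"), gt = gtString(sv@haplotypes),
        slot = r$slot, parent = sv@id, stringsAsFactors = FALSE)
    }
  }
  lines <- vcfHeaderLines(reference)
  if (length(rows)) {
    tab <- do.call(rbind, rows)
    chromOrder <- match(tab$chrom, names(reference))
    tab <- tab[order(chromOrder, tab$pos, tab$parent, tab$slot), , drop = FALSE]
    lines <- c(lines, sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tGT\t%s",
                              tab$chrom, tab$pos, tab$id, tab$ref, tab$alt,
                              tab$info, tab$gt))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a PAF liftover file for one haplotype
#'
#' One line per reference-origin assembly block: query is the synthetic
#' haplotype contig, target the reference chromosome, with the strand column
#' carrying the block orientation and the SV identifier in an \code{sv:Z:}
#' tag. Novel-origin blocks have no reference provenance and are skipped by
#' default; with \code{includeNovel = TRUE} they are emitted as
#' unmapped-style lines with \code{*} as target.
#'
#' @param assembly a [HaplotypeAssembly-class].
#' @param path output file.
#' @param includeNovel emit novel-origin blocks as unmapped-style records.
#' @return \code{path}, invisibly.
#' @export
writePaf <- function(assembly, path, includeNovel = FALSE) {
  b <- assembly@blocks
  lines <- character(0)
  for (i in seq_len(nrow(b))) {
    r <- b[i, ]
    if (r$qend == r$qstart) next
    tag <- if (!is.na(r$svId)) sprintf("\tsv:Z:%s", r$svId) else ""
    if (r$origin == "reference") {
      blen <- as.integer(r$qend - r$qstart)
      lines <- c(lines, sprintf(
        "%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t60%s",
        r$qname, as.integer(assembly@qlens[[r$qname]]),
        as.integer(r$qstart), as.integer(r$qend), r$strand,
        r$tname, as.integer(assembly@tlens[[r$tname]]),
        as.integer(r$tstart), as.integer(r$tend), blen, blen, tag))
    } else if (includeNovel) {
      lines <- c(lines, sprintf(
        "%s\t%d\t%d\t%d\t+\t*\t0\t0\t0\t0\t%d\t0%s",
        r$qname, as.integer(assembly@qlens[[r$qname]]),
        as.integer(r$qstart), as.integer(r$qend),
        as.integer(r$qend - r$qstart), tag))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

svTotalSize <- function(sv) {
  recs <- sv@records
  if (!nrow(recs)) return(0)
  sum(vapply(seq_len(nrow(recs)), function(i) abs(recordSVLEN(recs[i, ])),
             0))
}

#' Write the summary statistics table
#'
#' Tab-separated summary with per-type SV counts, per-type size
#' distributions (min/mean/max of the total affected bases per SV) and the
#' per-chromosome length difference between each haplotype and the
#' reference.
#'
#' @param svs list of [PlacedSV-class].
#' @param assemblies list of two [HaplotypeAssembly-class].
#' @param path output file.
#' @return the summary data.frame, invisibly.
#' @export
writeStats <- function(svs, assemblies, path) {
  rows <- list()
  types <- vapply(svs, svType, "")
  sizes <- vapply(svs, svTotalSize, 0)
  for (tp in unique(types)) {
    sz <- sizes[types == tp]
    rows[[length(rows) + 1L]] <- data.frame(
      metric = c("count", "size_min", "size_mean", "size_max"),
      group = tp,
      value = c(length(sz), min(sz), mean(sz), max(sz)),
      stringsAsFactors = FALSE)
  }
  for (asm in assemblies) {
    for (qn in names(asm@qlens)) {
      tn <- sub("_hap[AB]$", "", qn)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = "length_delta", group = qn,
        value = asm@qlens[[qn]] - asm@tlens[[tn]],
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metric = character(0), group = character(0),
               value = numeric(0), stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Lift a haplotype position to the reference through an assembly
#'
#' @param assembly a [HaplotypeAssembly-class].
#' @param qname synthetic contig name.
#' @param qpos 0-based position on the synthetic contig.
#' @return list with \code{tname, tpos} (0-based reference position) and
#'   \code{strand}, or \code{NULL} when the position falls in a
#'   novel-origin block.
#' @export
liftToReference <- function(assembly, qname, qpos) {
  b <- assembly@blocks
  hit <- which(b$qname == qname & b$qstart <= qpos & qpos < b$qend)
  if (!length(hit)) return(NULL)
  r <- b[hit[1], ]
  if (r$origin != "reference") return(NULL)
  off <- qpos - r$qstart
  tpos <- if (r$strand == "+") r$tstart + off else r$tend - 1 - off
  list(tname = r$tname, tpos = tpos, strand = r$strand)
}
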