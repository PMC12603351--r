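# Haplotype construction: apply placed SVs to the reference, tracking block
# provenance so each synthetic contig can be lifted back to the reference.

revcompStr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

randomSeqStr <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a novel insertion sequence
#'
#' Random mode draws i.i.d. uniform A/C/G/T of the exact length; file mode
#' returns a whole record of matching length when one exists, otherwise a
#' uniformly chosen subsequence of a record at least as long.
#'
#' @param length insertion length in bp (>= 1).
#' @param source \code{"random"} or path to a FASTA of candidate sequences.
#' @return a character string of exactly \code{length} bases.
#' @export
generateInsertionSequence <- function(length, source = "random") {
  if (length < 1) svError("insertion length must be >= 1", "svforgeInsertionError")
  if (identical(source, "random")) return(randomSeqStr(length))
  pool <- Biostrings::readDNAStringSet(source)
  w <- Biostrings::width(pool)
  exact <- which(w == length)
  if (length(exact)) {
    i <- if (length(exact) == 1) exact else sample(exact, 1)
    return(as.character(pool[[i]]))
  }
  ok <- which(w >= length)
  if (!length(ok))
    svError(sprintf("no record of length >= %d in insertion file '%s'",
                    length, source), "svforgeInsertionError")
  i <- if (length(ok) == 1) ok else sample(ok, 1)
  off <- uniformInt(0, w[i] - length)
  as.character(Biostrings::subseq(pool[[i]], off + 1, off + length))
}

# One edit: a replaced reference span plus the blocks that replace it.
# Point edits (start == end) are insertions before the material at `start`.
# Blocks: list(origin, chrom, start, end, strand, seq, svId, symbol).
recordsToEdits <- function(records, svId) {
  edits <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$kind == "DEL") {
      edits[[length(edits) + 1L]] <- list(chrom = r$chrom, start = r$start,
                                          end = r$end, slot = r$slot,
                                          blocks = list())
    } else if (r$kind == "INV") {
      edits[[length(edits) + 1L]] <- list(chrom = r$chrom, start = r$start,
        end = r$end, slot = r$slot,
        blocks = list(list(origin = "reference", chrom = r$chrom,
                           start = r$start, end = r$end, strand = "-",
                           seq = NA_character_, svId = svId,
                           symbol = r$symbol)))
    } else if (r$kind == "DUP") {
      blocks <- rep(list(list(origin = "reference", chrom = r$srcChrom,
                              start = r$srcStart, end = r$srcEnd,
                              strand = "+", seq = NA_character_,
                              svId = svId, symbol = r$symbol)), r$copies)
      edits[[length(edits) + 1L]] <- list(chrom = r$chrom, start = r$end,
                                          end = r$end, slot = r$slot,
                                          blocks = blocks)
    } else if (r$kind == "INS") {
      block <- if (!is.na(r$srcStart)) {
        list(origin = "reference", chrom = r$srcChrom, start = r$srcStart,
             end = r$srcEnd, strand = if (r$srcInverted) "-" else "+",
             seq = NA_character_, svId = svId, symbol = r$symbol)
      } else {
        list(origin = "novel", chrom = NA_character_, start = NA_real_,
             end = NA_real_, strand = "+", seq = r$seq, svId = svId,
             symbol = r$symbol)
      }
      edits[[length(edits) + 1L]] <- list(chrom = r$chrom, start = r$start,
                                          end = r$start, slot = r$slot,
                                          blocks = rep(list(block), r$copies))
    } else if (r$kind == "SNP") {
      edits[[length(edits) + 1L]] <- list(chrom = r$chrom, start = r$start,
        end = r$end, slot = r$slot,
        blocks = list(list(origin = "novel", chrom = NA_character_,
                           start = NA_real_, end = NA_real_, strand = "+",
                           seq = r$seq, svId = svId, symbol = r$symbol)))
    }
  }
  edits
}

hapSuffix <- function(hap) c("_hapA", "_hapB")[hap + 1]

#' Build one synthetic haplotype
#'
#' Walks each reference chromosome left to right, emitting identity blocks
#' between SVs and the blocks implied by each SV's resolved operations at
#' its site. The returned assembly tiles every synthetic contig exactly and
#' maps each block back to its reference provenance and orientation.
#'
#' @param reference \code{DNAStringSet}.
#' @param svs list of [PlacedSV-class]; only those assigned to \code{hap}
#'   are applied.
#' @param hap haplotype index (0 or 1).
#' @return list with elements \code{sequences} (\code{DNAStringSet}, contig
#'   names suffixed \code{_hapA}/\code{_hapB}) and \code{assembly}
#'   (a [HaplotypeAssembly-class]).
#' @export
buildHaplotype <- function(reference, svs, hap = 0L) {
  hap <- as.integer(hap)
  svs <- Filter(function(sv) hap %in% sv@haplotypes, svs)
  editsByChrom <- list()
  for (sv in svs) {
    for (ed in recordsToEdits(sv@records, sv@id)) {
      editsByChrom[[ed$chrom]] <- c(editsByChrom[[ed$chrom]], list(ed))
    }
  }
  blockRows <- list()
  seqs <- vector("list", length(reference))
  names(seqs) <- paste0(names(reference), hapSuffix(hap))
  for (ci in seq_along(reference)) {
    chrom <- names(reference)[ci]
    qname <- paste0(chrom, hapSuffix(hap))
    L <- Biostrings::width(reference)[ci]
    eds <- editsByChrom[[chrom]]
    if (length(eds)) {
      starts <- vapply(eds, `[[`, 0, "start")
      ends <- vapply(eds, `[[`, 0, "end")
      slots <- vapply(eds, `[[`, 0L, "slot")
      eds <- eds[order(starts, ends, slots)]
    }
    blocks <- list()
    pos <- 0
    for (ed in eds) {
      if (ed$start > pos) {
        blocks[[length(blocks) + 1L]] <- list(origin = "reference",
          chrom = chrom, start = pos, end = ed$start, strand = "+",
          seq = NA_character_, svId = NA_character_, symbol = NA_character_)
      } else if (ed$start < pos) {
        svError(sprintf("overlapping edits on %s at %g (internal error)",
                        chrom, ed$start), "svforgeInternalError")
      }
      blocks <- c(blocks, ed$blocks)
      pos <- ed$end
    }
    if (pos < L || !length(blocks)) {
      blocks[[length(blocks) + 1L]] <- list(origin = "reference",
        chrom = chrom, start = pos, end = L, strand = "+",
        seq = NA_character_, svId = NA_character_, symbol = NA_character_)
    }
    pieces <- vector("list", length(blocks))
    q <- 0
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      piece <- if (b$origin == "reference") {
        s <- Biostrings::subseq(reference[[b$chrom]], b$start + 1, b$end)
        if (b$strand == "-") Biostrings::reverseComplement(s) else s
      } else {
        Biostrings::DNAString(b$seq)
      }
      pieces[[bi]] <- piece
      blen <- length(piece)
      blockRows[[length(blockRows) + 1L]] <- data.frame(
        qname = qname, qstart = q, qend = q + blen,
        tname = if (b$origin == "reference") b$chrom else NA_character_,
        tstart = if (b$origin == "reference") b$start else NA_real_,
        tend = if (b$origin == "reference") b$end else NA_real_,
        strand = b$strand, origin = b$origin,
        svId = if (is.null(b$svId)) NA_character_ else b$svId,
        seq = if (b$origin == "novel") b$seq else NA_character_,
        stringsAsFactors = FALSE)
      q <- q + blen
    }
    seqs[[paste0(chrom, hapSuffix(hap))]] <-
      unlist(Biostrings::DNAStringSet(pieces))
  }
  blockDf <- if (length(blockRows)) do.call(rbind, blockRows) else
    data.frame(qname = character(0), qstart = numeric(0), qend = numeric(0),
               tname = character(0), tstart = numeric(0), tend = numeric(0),
               strand = character(0), origin = character(0),
               svId = character(0), seq = character(0),
               stringsAsFactors = FALSE)
  dss <- Biostrings::DNAStringSet(seqs)
  assembly <- new("HaplotypeAssembly", hap = hap, blocks = blockDf,
                  qlens = stats::setNames(as.numeric(Biostrings::width(dss)),
                                          names(dss)),
                  tlens = stats::setNames(as.numeric(Biostrings::width(reference)),
                                          names(reference)))
  validObject(assembly)
  list(sequences = dss, assembly = assembly)
}
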