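# Breakend-distance sampling, zygosity assignment, greedy constraint-aware
# placement, and the standalone placement audit.
#
# Internal coordinates are 0-based half-open throughout. A "breakend" is a
# point between bases where the SV creates a novel junction; breakends are
# derived from the resolved record table so untouched copy-source flanks do
# not count as junctions.

#' @importFrom IRanges IRanges countOverlaps
#' @importFrom GenomicRanges GRanges seqnames start end width
NULL

placementError <- function(msg) svError(msg, "svforgePlacementError")

DNA_BASES <- c("A", "C", "G", "T")

uniformInt <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (hi < lo) placementError("empty integer range")
  min(hi, lo + floor(stats::runif(1) * (hi - lo + 1)))
}

#' Sample breakend distances for one SV instance
#'
#' Independent symbols are drawn uniformly on their integer \code{[min,max]}
#' range; derived symbols (\code{"k*length(X)"}) are computed after their
#' referenced symbol is sampled, rounded to the nearest integer with a floor
#' of 1 bp.
#'
#' @param category an [SVCategory-class] (validated, acyclic derivations).
#' @return named numeric vector of lengths in bp, one per length-bearing
#'   symbol.
#' @export
sampleLengths <- function(category) {
  dists <- category@distances
  out <- stats::setNames(rep(NA_real_, length(dists)), names(dists))
  # numeric ranges first, then derivations until fixpoint
  for (nm in names(dists)) {
    if (is.numeric(dists[[nm]]))
      out[nm] <- uniformInt(dists[[nm]][1], dists[[nm]][2])
  }
  repeat {
    progressed <- FALSE
    for (nm in names(dists)) {
      if (!is.na(out[nm]) || !is.character(dists[[nm]])) next
      m <- regmatches(dists[[nm]], regexec(
        "^\\s*([0-9]*\\.?[0-9]+)\\s*\\*\\s*length\\(\\s*(_?[A-Z0-9]+)\\s*\\)\\s*$",
        dists[[nm]]))[[1]]
      k <- as.numeric(m[2]); ref <- m[3]
      if (!is.na(out[ref])) {
        out[nm] <- max(1, round(k * out[ref]))
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  if (anyNA(out))
    placementError(sprintf("unresolvable length derivation for symbol(s) %s",
                           paste(names(out)[is.na(out)], collapse = ",")))
  out
}

#' Assign zygosity to a set of SVs
#'
#' Each SV is homozygous with probability \code{policy} (haplotypes
#' \code{{0,1}}, identical coordinates on both) and otherwise heterozygous
#' on one haplotype chosen uniformly.
#'
#' @param svs list of [PlacedSV-class].
#' @param policy probability of homozygosity in \code{[0,1]}.
#' @return the list with updated \code{haplotypes}.
#' @export
assignZygosity <- function(svs, policy) {
  stopifnot(policy >= 0, policy <= 1)
  lapply(svs, function(sv) {
    sv@haplotypes <- if (stats::runif(1) < policy) 0:1
                     else sample(0:1, 1L)
    sv
  })
}

constraintRank <- function(constraints, fixed = FALSE) {
  if (fixed) return(1L)
  modes <- vapply(constraints, `[[`, "", "mode")
  positive <- setdiff(modes, "blacklist")
  if (!length(positive)) return(7L)
  switch(positive[1],
         exact = 2L, partial = 3L, containing = 4L, contained = 5L,
         terminal = 6L, whole_chromosome = 6L, 7L)
}

#' Order SVs for greedy most-restrictive-first placement
#'
#' Queue order: (1) VCF-fixed SVs, (2) exact, (3) partial, (4) containing an
#' ROI, (5) contained in an ROI, (6) terminal / whole-chromosome, then (7)
#' unconstrained and blacklist-only SVs. Ties are broken by descending total
#' SV span, then by stable input order.
#'
#' @param svs list of [PlacedSV-class] (spans are taken from their sampled
#'   symbol lengths).
#' @param constraints list (parallel to \code{svs}) of constraint lists.
#' @return integer permutation of \code{seq_along(svs)}.
#' @export
orderCategories <- function(svs, constraints) {
  stopifnot(length(svs) == length(constraints))
  ranks <- mapply(function(sv, cc) constraintRank(cc, sv@fixed),
                  svs, constraints)
  spans <- vapply(svs, function(sv) {
    iv <- sv@intervals
    if (!nrow(iv)) return(0)
    sum(iv$end - iv$start, na.rm = TRUE)
  }, 0)
  order(ranks, -spans, seq_along(svs))
}

# ---- placement state -------------------------------------------------------

placementState <- function(reference) {
  st <- new.env(parent = emptyenv())
  st$chromLens <- stats::setNames(as.numeric(Biostrings::width(reference)),
                                  names(reference))
  st$occ <- list(`0` = list(), `1` = list())
  st$bks <- list()
  st$usedROI <- integer(0)
  st
}

occAdd <- function(st, hap, chrom, start0, end0) {
  key <- as.character(hap)
  ir <- st$occ[[key]][[chrom]]
  add <- IRanges::IRanges(start = start0 + 1, end = max(end0, start0 + 1))
  st$occ[[key]][[chrom]] <- if (is.null(ir)) add else c(ir, add)
}

occOverlaps <- function(st, hap, chrom, start0, end0) {
  ir <- st$occ[[as.character(hap)]][[chrom]]
  if (is.null(ir)) return(FALSE)
  q <- IRanges::IRanges(start = start0 + 1, end = max(end0, start0 + 1))
  sum(IRanges::countOverlaps(q, ir)) > 0
}

# breakends implied by a resolved record table: data.frame(chrom, pos)
recordBreakends <- function(records) {
  if (!nrow(records)) return(data.frame(chrom = character(0), pos = numeric(0)))
  rows <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    pos <- if (r$kind == "INS" && r$end == r$start) r$start
           else c(r$start, r$end)
    if (r$kind == "DUP") pos <- c(pos, r$end)
    rows[[i]] <- data.frame(chrom = r$chrom, pos = pos)
  }
  unique(do.call(rbind, rows))
}

#' Breakends of a placed SV
#'
#' @param sv a [PlacedSV-class].
#' @return a data.frame with columns \code{chrom} and \code{pos} (0-based
#'   inter-base positions of the novel junctions the SV induces).
#' @export
breakendsOf <- function(sv) recordBreakends(sv@records)

pointInRanges <- function(chrom, pos, gr, strict = TRUE) {
  if (is.null(gr) || length(gr) == 0) return(FALSE)
  onChrom <- as.character(GenomicRanges::seqnames(gr)) == chrom
  if (!any(onChrom)) return(FALSE)
  s <- GenomicRanges::start(gr)[onChrom] - 1  # back to 0-based
  e <- GenomicRanges::end(gr)[onChrom]
  if (strict) any(s < pos & pos < e) else any(s <= pos & pos <= e)
}

checkProposal <- function(st, sv, params, blacklist) {
  iv <- sv@intervals
  for (i in seq_len(nrow(iv))) {
    if (is.na(iv$start[i])) next
    len <- st$chromLens[[iv$chrom[i]]]
    if (is.null(len) || iv$start[i] < 0 || iv$end[i] > len) return(FALSE)
  }
  bks <- recordBreakends(sv@records)
  minD <- max(1, params@minInterSVDist)
  for (i in seq_len(nrow(bks))) {
    v <- st$bks[[bks$chrom[i]]]
    if (is.null(v) || !length(v)) next
    j <- findInterval(bks$pos[i], v)
    near <- c(if (j >= 1) v[j], if (j < length(v)) v[j + 1])
    if (length(near) && min(abs(near - bks$pos[i])) < minD) return(FALSE)
  }
  haps <- if (params@allowCrossHapOverlap) sv@haplotypes else 0:1
  # dispersion intervals are untouched reference: other SVs may use them
  occRows <- iv[!is.na(iv$start) & iv$end > iv$start &
                !startsWith(iv$symbol, "_"), , drop = FALSE]
  junctions <- bks  # width-1 booking of junction points
  for (h in haps) {
    for (i in seq_len(nrow(occRows)))
      if (occOverlaps(st, h, occRows$chrom[i], occRows$start[i], occRows$end[i]))
        return(FALSE)
    for (i in seq_len(nrow(junctions)))
      if (occOverlaps(st, h, junctions$chrom[i], junctions$pos[i],
                      junctions$pos[i] + 1))
        return(FALSE)
  }
  if (length(blacklist)) {
    for (i in seq_len(nrow(bks)))
      if (pointInRanges(bks$chrom[i], bks$pos[i], blacklist)) return(FALSE)
  }
  TRUE
}

commitSV <- function(st, sv) {
  iv <- sv@intervals
  bks <- recordBreakends(sv@records)
  for (h in sv@haplotypes) {
    for (i in seq_len(nrow(iv))) {
      if (is.na(iv$start[i]) || iv$end[i] <= iv$start[i] ||
          startsWith(iv$symbol[i], "_")) next
      occAdd(st, h, iv$chrom[i], iv$start[i], iv$end[i])
    }
    for (i in seq_len(nrow(bks)))
      occAdd(st, h, bks$chrom[i], bks$pos[i], bks$pos[i] + 1)
  }
  for (ch in unique(bks$chrom))
    st$bks[[ch]] <- sort(c(st$bks[[ch]], bks$pos[bks$chrom == ch]))
  invisible(st)
}

# ---- coordinate proposal ---------------------------------------------------

# symbols of the rule source in order with lengths; dispersions carry their
# sampled length (intra) or 0 (inter)
layoutSymbols <- function(rule, lengths, interchromosomal = FALSE) {
  src <- rule@source
  if (!nrow(src)) {
    return(data.frame(symbol = character(0), dispersion = logical(0),
                      seg = integer(0), len = numeric(0), offset = numeric(0)))
  }
  len <- vapply(seq_len(nrow(src)), function(i) {
    s <- src$symbol[i]
    if (src$dispersion[i] && interchromosomal) 0
    else if (!is.null(lengths[s]) && !is.na(lengths[s])) unname(lengths[s])
    else placementError(sprintf("no sampled length for symbol %s", s))
  }, 0)
  data.frame(symbol = src$symbol, dispersion = src$dispersion, seg = src$seg,
             len = len, offset = cumsum(c(0, utils::head(len, -1))),
             stringsAsFactors = FALSE)
}

# anchored sub-span (offset, length) within the layout; default whole span
anchorWindow <- function(rule, layout) {
  if (length(rule@anchorSymbols)) {
    idx <- which(rule@source$anchor)
    lo <- min(idx); hi <- max(idx)
    off <- layout$offset[lo]
    list(offset = off,
         len = layout$offset[hi] + layout$len[hi] - off)
  } else if (!is.na(rule@anchorJunction)) {
    j <- rule@anchorJunction
    off <- if (j == 0) 0
           else layout$offset[j] + layout$len[j]
    list(offset = off, len = 0)
  } else {
    list(offset = 0, len = sum(layout$len))
  }
}

sampleGenomicStart <- function(chromLens, span) {
  ok <- chromLens >= span
  if (!any(ok)) placementError("no chromosome can hold the SV span")
  w <- (chromLens - span + 1) * ok
  chrom <- sample(names(chromLens), 1, prob = w / sum(w))
  list(chrom = chrom, start = uniformInt(0, chromLens[[chrom]] - span))
}

roisWithLabels <- function(rois, labels) {
  if (is.null(rois) || length(rois) == 0) return(rois)
  if (!length(labels)) return(rois)
  rois[S4Vectors::mcols(rois)$label %in% labels]
}

# Propose the anchored-span position for one attempt; returns
# list(chrom, anchorStart, anchorLen override or NA) or NULL if the draw is
# infeasible.
proposeAnchor <- function(mode, labels, rois, chromLens, alen, total,
                         anchorOffset) {
  if (is.null(mode)) {
    g <- sampleGenomicStart(chromLens, total)
    return(list(chrom = g$chrom, anchorStart = g$start + anchorOffset,
                forcedLen = NA_real_))
  }
  cand <- roisWithLabels(rois, labels)
  if (mode %in% c("exact", "partial", "contained", "containing") &&
      (is.null(cand) || length(cand) == 0))
    placementError(sprintf("constraint mode '%s' has no candidate ROIs", mode))
  if (mode == "exact") {
    i <- sample(length(cand), 1)
    s <- GenomicRanges::start(cand)[i] - 1
    e <- GenomicRanges::end(cand)[i]
    if (alen == 0) {   # single-breakend anchor: snap to a boundary
      b <- if (stats::runif(1) < 0.5) s else e
      return(list(chrom = as.character(GenomicRanges::seqnames(cand))[i],
                  anchorStart = b, forcedLen = 0))
    }
    return(list(chrom = as.character(GenomicRanges::seqnames(cand))[i],
                anchorStart = s, forcedLen = e - s))
  }
  if (mode == "partial") {
    i <- sample(length(cand), 1)
    s <- GenomicRanges::start(cand)[i] - 1
    e <- GenomicRanges::end(cand)[i]
    if (e - s < 2) return(NULL)
    b <- uniformInt(s + 1, e - 1)          # strictly inside
    chrom <- as.character(GenomicRanges::seqnames(cand))[i]
    if (alen == 0) return(list(chrom = chrom, anchorStart = b, forcedLen = 0))
    side <- stats::runif(1) < 0.5
    aStart <- if (side) b else b - alen
    other <- if (side) b + alen else b - alen
    if (s < other && other < e) return(NULL)  # other breakend must be outside
    list(chrom = chrom, anchorStart = aStart, forcedLen = NA_real_)
  } else if (mode == "contained") {
    i <- sample(length(cand), 1)
    s <- GenomicRanges::start(cand)[i] - 1
    e <- GenomicRanges::end(cand)[i]
    if (e - s < alen) return(NULL)
    list(chrom = as.character(GenomicRanges::seqnames(cand))[i],
         anchorStart = uniformInt(s, e - alen), forcedLen = NA_real_)
  } else if (mode == "containing") {
    i <- sample(length(cand), 1)
    s <- GenomicRanges::start(cand)[i] - 1
    e <- GenomicRanges::end(cand)[i]
    if (alen < e - s) return(NULL)
    lo <- e - alen; hi <- s
    if (lo > hi) return(NULL)
    list(chrom = as.character(GenomicRanges::seqnames(cand))[i],
         anchorStart = uniformInt(lo, hi), forcedLen = NA_real_)
  } else if (mode == "terminal") {
    ok <- names(chromLens)[chromLens >= total]
    if (!length(ok)) placementError("no chromosome can hold a terminal SV")
    chrom <- if (length(ok) == 1) ok else sample(ok, 1)
    atStart <- stats::runif(1) < 0.5
    layStart <- if (atStart) 0 else chromLens[[chrom]] - total
    list(chrom = chrom, anchorStart = layStart + anchorOffset,
         forcedLen = NA_real_)
  } else if (mode == "whole_chromosome") {
    chrom <- if (length(chromLens) == 1) names(chromLens)
             else sample(names(chromLens), 1)
    list(chrom = chrom, anchorStart = 0, forcedLen = chromLens[[chrom]],
         wholeChrom = TRUE)
  } else {  # blacklist handled by checkProposal; place genome-wide
    g <- sampleGenomicStart(chromLens, total)
    list(chrom = g$chrom, anchorStart = g$start + anchorOffset,
         forcedLen = NA_real_)
  }
}

# Distribute a forced total length over the anchored symbols, preserving the
# sampled proportions (rounding fixed on the last symbol).
forceAnchorLengths <- function(lengths, symbols, forcedLen) {
  cur <- lengths[symbols]
  tot <- sum(cur)
  if (tot == forcedLen) return(lengths)
  scaled <- pmax(1, round(cur * forcedLen / tot))
  scaled[length(scaled)] <- forcedLen - sum(scaled[-length(scaled)])
  if (scaled[length(scaled)] < 1)
    return(NULL)
  lengths[symbols] <- scaled
  lengths
}

positiveConstraint <- function(constraints) {
  for (cc in constraints) if (cc$mode != "blacklist") return(cc)
  NULL
}

categoryBlacklist <- function(constraints, rois) {
  labs <- unlist(lapply(constraints,
                        function(cc) if (cc$mode == "blacklist") cc$labels))
  grs <- list()
  for (cc in constraints) {
    if (cc$mode != "blacklist") next
    grs[[length(grs) + 1L]] <- roisWithLabels(rois, cc$labels)
  }
  if (!length(grs)) return(NULL)
  do.call(c, grs)
}

#' Place one SV subject to its constraints
#'
#' Rejection-samples coordinates for one SV: lengths are (re)drawn each
#' attempt, the anchored span is positioned according to the constraint mode
#' (ROI-bound modes enumerate admissible ROIs directly; unconstrained and
#' blacklist modes sample genome-wide), flanking symbols extend around the
#' anchor, and the proposal is audited against chromosome bounds, the
#' occupied per-haplotype interval index, the minimum inter-SV breakend
#' distance and all blacklists. On success the SV is committed to the state.
#'
#' @param sv a skeleton [PlacedSV-class] (id, rule, haplotypes set).
#' @param category its [SVCategory-class].
#' @param state placement state environment from \code{placementState()}
#'   (created internally by [placeAll()]).
#' @param rois labeled \code{GRanges} of regions of interest.
#' @param blacklist \code{GRanges} of globally blacklisted regions.
#' @param params a [SimulationParams-class].
#' @param reference \code{DNAStringSet} reference (needed for novel
#'   insertion sequences and SNP alleles).
#' @return the placed [PlacedSV-class] with resolved coordinates.
#' @export
placeSV <- function(sv, category, state, rois, blacklist, params, reference) {
  rule <- sv@rule
  special <- categorySpecial(category)
  if (!is.na(special) && special %in% c("TR_EXPANSION", "TR_CONTRACTION"))
    return(placeTR(sv, category, state, rois, blacklist, params, reference))
  constraint <- positiveConstraint(category@constraints)
  catBl <- categoryBlacklist(category@constraints, rois)
  allBl <- if (is.null(catBl)) blacklist
           else if (is.null(blacklist)) catBl else c(blacklist, catBl)
  mode <- constraint$mode
  labels <- constraint$labels

  # early feasibility diagnostic for exact mode
  if (!is.null(mode) && mode == "exact") {
    cand <- roisWithLabels(rois, labels)
    if (is.null(cand) || !length(cand))
      placementError(sprintf(
        "SV %s (%s): exact constraint has no ROIs with label(s) %s",
        sv@id, category@type, paste(labels, collapse = ",")))
    aSyms <- if (length(rule@anchorSymbols)) rule@anchorSymbols
             else lengthBearingSymbols(rule, category@interchromosomal)
    aSyms <- intersect(aSyms, names(category@distances))
    rng <- sapply(aSyms, function(s) {
      d <- category@distances[[s]]
      if (is.numeric(d)) d else c(1, Inf)
    })
    if (length(rng)) {
      lo <- sum(rng[1, ]); hi <- sum(rng[2, ])
      w <- GenomicRanges::width(cand)
      if (!any(w >= lo & w <= hi))
        placementError(sprintf(
          "SV %s (%s): no ROI width in the feasible anchored range [%g,%g]",
          sv@id, category@type, lo, hi))
    }
  }

  for (attempt in seq_len(params@maxPlacementAttempts)) {
    lengths <- sampleLengths(category)
    layout <- layoutSymbols(rule, lengths, category@interchromosomal)
    aw <- anchorWindow(rule, layout)
    prop <- tryCatch(
      proposeAnchor(mode, labels, rois, state$chromLens, aw$len,
                    sum(layout$len), aw$offset),
      svforgePlacementError = function(e) stop(e))
    if (is.null(prop)) next
    if (!is.na(prop$forcedLen) && prop$forcedLen > 0) {
      aSyms <- if (length(rule@anchorSymbols)) rule@anchorSymbols
               else layout$symbol
      if (isTRUE(prop$wholeChrom)) aSyms <- layout$symbol
      lengths <- forceAnchorLengths(lengths, aSyms, prop$forcedLen)
      if (is.null(lengths)) next
      layout <- layoutSymbols(rule, lengths, category@interchromosomal)
      aw <- anchorWindow(rule, layout)
    }
    layStart <- prop$anchorStart - aw$offset
    iv <- if (nrow(layout)) {
      data.frame(symbol = layout$symbol, chrom = prop$chrom,
                 start = layStart + layout$offset,
                 end = layStart + layout$offset + layout$len,
                 stringsAsFactors = FALSE)
    } else {
      # empty source side (pure insertion): a zero-width locus row
      data.frame(symbol = "@", chrom = prop$chrom, start = layStart,
                 end = layStart, stringsAsFactors = FALSE)
    }
    if (category@interchromosomal) {
      iv <- interchromosomalSplit(iv, layout, state$chromLens, prop$chrom)
      if (is.null(iv)) next
    }
    cand <- finalizeSV(sv, category, iv, lengths, reference,
                       snp = !is.na(special) && special == "SNP")
    if (is.null(cand)) next
    if (checkProposal(state, cand, params, allBl)) {
      commitSV(state, cand)
      return(cand)
    }
  }
  placementError(sprintf(
    "placement failed for SV %s (category %s) after %d attempts%s",
    sv@id, category@type, params@maxPlacementAttempts,
    if (!is.null(mode)) sprintf(" under constraint '%s'", mode) else ""))
}

# re-home all segments after the (single) dispersion onto another chromosome
interchromosomalSplit <- function(iv, layout, chromLens, chrom1) {
  dIdx <- which(layout$dispersion)
  if (length(dIdx) != 1L)
    placementError("interchromosomal dispersion requires exactly one '_'")
  others <- setdiff(names(chromLens), chrom1)
  if (!length(others))
    placementError("interchromosomal SV requires at least two chromosomes")
  chrom2 <- if (length(others) == 1) others else sample(others, 1)
  after <- seq_len(nrow(iv)) > dIdx
  part2Len <- sum(layout$len[after])
  if (chromLens[[chrom2]] < part2Len) return(NULL)
  p2 <- uniformInt(0, chromLens[[chrom2]] - part2Len)
  iv$chrom[dIdx] <- chrom2
  iv$start[dIdx] <- p2
  iv$end[dIdx] <- p2
  off <- cumsum(c(0, layout$len[after][-sum(after)]))
  iv$chrom[after] <- chrom2
  iv$start[after] <- p2 + off
  iv$end[after] <- p2 + off + layout$len[after]
  iv
}

# Build targetInfo + records for resolved coordinates; returns NULL when a
# novel sequence cannot be generated (e.g. file source too short).
finalizeSV <- function(sv, category, iv, lengths, reference, snp = FALSE) {
  sv@intervals <- iv
  if (snp) {
    chrom <- iv$chrom[1]; p <- iv$start[1]
    refBase <- as.character(Biostrings::subseq(reference[[chrom]], p + 1, p + 1))
    alt <- sample(setdiff(DNA_BASES, toupper(refBase)), 1)
    sv@records <- recordRow(kind = "SNP", chrom = chrom, start = p, end = p + 1,
                            seq = alt, symbol = "A", operation = "SNP",
                            slot = 1L)
    sv@targetInfo <- data.frame()
    return(sv)
  }
  tgt <- sv@rule@target
  copies <- rep(1L, nrow(tgt))
  if (any(tgt$plus)) {
    for (k in which(tgt$plus))
      copies[k] <- uniformInt(category@copyRange[1], category@copyRange[2])
  }
  novelSeq <- rep(NA_character_, nrow(tgt))
  srcLetters <- sv@rule@source$letter[!sv@rule@source$dispersion]
  for (k in seq_len(nrow(tgt))) {
    if (tgt$dispersion[k] || tgt$letter[k] %in% srcLetters) next
    len <- lengths[tgt$letter[k]]
    seq <- tryCatch(
      generateInsertionSequence(len, category@insertionSource),
      svforgeError = function(e) NULL)
    if (is.null(seq)) return(NULL)
    if (tgt$inverted[k]) seq <- revcompStr(seq)
    novelSeq[k] <- seq
  }
  sv@targetInfo <- data.frame(copies = copies, novelSeq = novelSeq,
                              stringsAsFactors = FALSE)
  sv@records <- buildRecords(sv)
  sv
}

recordRow <- function(kind, chrom, start, end, srcChrom = NA_character_,
                      srcStart = NA_real_, srcEnd = NA_real_,
                      srcInverted = FALSE, copies = 1L, seq = NA_character_,
                      symbol = NA_character_, operation = kind, slot = 0L) {
  data.frame(kind = kind, chrom = chrom, start = start, end = end,
             srcChrom = srcChrom, srcStart = srcStart, srcEnd = srcEnd,
             srcInverted = srcInverted, copies = as.integer(copies),
             seq = seq, symbol = symbol, operation = operation,
             slot = as.integer(slot), stringsAsFactors = FALSE)
}

emptyRecords <- function() recordRow("DEL", "x", 0, 0)[0, ]

# Resolve the grammar operations of a placed SV into atomic records.
buildRecords <- function(sv) {
  rule <- sv@rule
  iv <- sv@intervals
  ops <- deriveOperations(rule)
  tgt <- rule@target
  ivOf <- function(sym) iv[iv$symbol == sym, , drop = FALSE]
  out <- list()
  # deletions of vanishing source letters
  del <- ops[ops$kind == "DELETE", , drop = FALSE]
  for (i in seq_len(nrow(del))) {
    r <- ivOf(del$symbol[i])
    out[[length(out) + 1L]] <- recordRow("DEL", r$chrom, r$start, r$end,
                                         symbol = del$symbol[i],
                                         operation = "DELETE")
  }
  # segments are delimited by dispersions; a segment may hold target tokens
  # but no source letters (e.g. the copy of a dispersed duplication)
  segs <- seq_len(sum(rule@source$dispersion) + 1L)
  srcLetters <- rule@source$letter[!rule@source$dispersion]
  tokenOps <- ops[!is.na(ops$targetSlot), , drop = FALSE]
  for (sg in segs) {
    segRows <- which(!rule@source$dispersion & rule@source$seg == sg)
    anchor <- if (length(segRows)) {
      list(chrom = iv$chrom[segRows[1]], pos = iv$start[segRows[1]])
    } else {
      dRow <- which(rule@source$dispersion & rule@source$seg == sg - 1L)
      if (length(dRow))
        list(chrom = iv$chrom[dRow], pos = iv$end[dRow])
      else list(chrom = iv$chrom[1], pos = iv$start[1])
    }
    tkIdx <- which(!tgt$dispersion & tgt$seg == sg)
    for (k in tkIdx) {
      op <- tokenOps[tokenOps$targetSlot == k, , drop = FALSE]
      kind <- op$kind[1]
      cp <- sv@targetInfo$copies[k]
      if (kind == "IDENTITY") {
        anchor <- { r <- ivOf(tgt$letter[k]); list(chrom = r$chrom, pos = r$end) }
      } else if (kind == "INVERT_IN_PLACE") {
        r <- ivOf(tgt$letter[k])
        out[[length(out) + 1L]] <- recordRow("INV", r$chrom, r$start, r$end,
                                             symbol = tgt$letter[k],
                                             operation = "INVERT_IN_PLACE",
                                             slot = k)
        anchor <- list(chrom = r$chrom, pos = r$end)
      } else if (kind == "NOVEL_INSERT") {
        out[[length(out) + 1L]] <- recordRow("INS", anchor$chrom, anchor$pos,
                                             anchor$pos, copies = cp,
                                             seq = sv@targetInfo$novelSeq[k],
                                             symbol = tgt$letter[k],
                                             operation = "NOVEL_INSERT",
                                             slot = k)
      } else {
        r <- ivOf(tgt$letter[k])
        tandemRun <- kind == "TANDEM_COPY" && !tgt$inverted[k] &&
          anchor$chrom == r$chrom && anchor$pos == r$end
        if (tandemRun) {
          out[[length(out) + 1L]] <- recordRow("DUP", r$chrom, r$start, r$end,
                                               srcChrom = r$chrom,
                                               srcStart = r$start,
                                               srcEnd = r$end, copies = cp,
                                               symbol = tgt$letter[k],
                                               operation = "TANDEM_COPY",
                                               slot = k)
          anchor <- list(chrom = r$chrom, pos = r$end)
        } else {
          out[[length(out) + 1L]] <- recordRow("INS", anchor$chrom, anchor$pos,
                                               anchor$pos, srcChrom = r$chrom,
                                               srcStart = r$start,
                                               srcEnd = r$end,
                                               srcInverted = tgt$inverted[k],
                                               copies = cp,
                                               symbol = tgt$letter[k],
                                               operation = kind, slot = k)
          if (kind == "CUT_PASTE") {
            out[[length(out) + 1L]] <- recordRow("DEL", r$chrom, r$start,
                                                 r$end,
                                                 symbol = tgt$letter[k],
                                                 operation = "CUT_PASTE_SRC",
                                                 slot = k)
          }
        }
      }
    }
  }
  if (!length(out)) return(emptyRecords())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- tandem repeat events --------------------------------------------------

trMotif <- function(label) sub("^TR_", "", label)

trEventRecords <- function(chrom, start0, end0, motif, delta) {
  L <- nchar(motif)
  copies <- floor((end0 - start0) / L)
  if (delta >= 0) {
    if (delta == 0) return(emptyRecords())
    recordRow("INS", chrom, end0, end0, copies = 1L,
              seq = strrep(motif, delta), symbol = "A",
              operation = "TR_EXPANSION", slot = 1L)
  } else {
    k <- -delta
    if (k > copies)
      placementError(sprintf(
        "tandem repeat contraction of %d copies underflows a %d-copy locus",
        k, copies))
    recordRow("DEL", chrom, end0 - k * L, end0, symbol = "A",
              operation = "TR_CONTRACTION", slot = 1L)
  }
}

#' Build a tandem-repeat expansion or contraction at a repeat locus
#'
#' The locus is an ROI labeled \code{"TR_<motif>"} whose reference sequence
#' holds an integer number of motif copies. An expansion of \code{delta}
#' copies inserts \code{delta} additional motif copies at the locus end; a
#' contraction removes \code{-delta} copies and fails when the locus holds
#' fewer copies than requested.
#'
#' @param roi list or single-row data.frame with \code{chrom, start, end}
#'   (0-based half-open) and \code{label}.
#' @param reference \code{DNAStringSet} (used to sanity-check the motif).
#' @param delta signed copy-number change (positive = expansion).
#' @param id SV identifier.
#' @param haplotypes haplotype assignment.
#' @return a [PlacedSV-class].
#' @export
tandemRepeatEvent <- function(roi, reference, delta, id = "tr1",
                              haplotypes = 0:1) {
  motif <- trMotif(roi$label)
  recs <- trEventRecords(roi$chrom, roi$start, roi$end, motif, delta)
  type <- if (delta >= 0) "TR_EXPANSION" else "TR_CONTRACTION"
  new("PlacedSV", id = id, type = type, rule = lookupType(type)$rule,
      intervals = data.frame(symbol = "A", chrom = roi$chrom,
                             start = roi$start, end = roi$end,
                             stringsAsFactors = FALSE),
      targetInfo = data.frame(), records = recs,
      haplotypes = as.integer(haplotypes), fixed = FALSE)
}

placeTR <- function(sv, category, state, rois, blacklist, params, reference) {
  special <- categorySpecial(category)
  labels <- unlist(lapply(category@constraints, function(cc)
    if (cc$mode != "blacklist") cc$labels))
  cand <- if (length(labels)) roisWithLabels(rois, labels)
          else rois[startsWith(S4Vectors::mcols(rois)$label, "TR_")]
  if (is.null(cand) || !length(cand))
    placementError(sprintf("SV %s: no tandem-repeat ROI available", sv@id))
  for (attempt in seq_len(params@maxPlacementAttempts)) {
    i <- sample(length(cand), 1)
    roi <- list(chrom = as.character(GenomicRanges::seqnames(cand))[i],
                start = GenomicRanges::start(cand)[i] - 1,
                end = GenomicRanges::end(cand)[i],
                label = S4Vectors::mcols(cand)$label[i])
    k <- uniformInt(category@distances[["A"]][1], category@distances[["A"]][2])
    delta <- if (special == "TR_CONTRACTION") -k else k
    tr <- tryCatch(
      tandemRepeatEvent(roi, reference, delta, id = sv@id,
                        haplotypes = sv@haplotypes),
      svforgePlacementError = function(e) NULL)
    if (is.null(tr)) next
    tr@fixed <- FALSE
    if (checkProposal(state, tr, params, blacklist)) {
      commitSV(state, tr)
      return(tr)
    }
  }
  placementError(sprintf(
    "placement failed for tandem-repeat SV %s after %d attempts",
    sv@id, params@maxPlacementAttempts))
}

# ---- SNP expansion ---------------------------------------------------------

#' Simulate small variants for a SNP category
#'
#' Places \code{category@count} single-base substitutions on the reference,
#' honouring the same constraint machinery as SVs (including blacklists and
#' the minimum inter-variant distance); each ALT is drawn uniformly from the
#' three non-reference bases.
#'
#' @param category an [SVCategory-class] with type \code{SNP}.
#' @param reference \code{DNAStringSet}.
#' @param rois labeled \code{GRanges} (optional).
#' @param blacklist \code{GRanges} (optional).
#' @param params a [SimulationParams-class].
#' @param n number of SNPs (defaults to the category count; 0 gives an
#'   empty list).
#' @return list of [PlacedSV-class], one per SNP.
#' @export
expandSmallVariants <- function(category, reference,
                                rois = GenomicRanges::GRanges(),
                                blacklist = GenomicRanges::GRanges(),
                                params = new("SimulationParams"),
                                n = category@count) {
  st <- placementState(reference)
  out <- vector("list", n)
  for (j in seq_len(n)) {
    sv <- new("PlacedSV", id = sprintf("snp%d", j), type = "SNP",
              rule = category@rule, intervals = data.frame(),
              targetInfo = data.frame(), records = emptyRecords(),
              haplotypes = 0:1, fixed = FALSE)
    sv <- assignZygosity(list(sv), category@homozygousProb)[[1]]
    out[[j]] <- placeSV(sv, category, st, rois, blacklist, params, reference)
  }
  out
}

# ---- top-level placement ---------------------------------------------------

#' Place all SVs of a configuration
#'
#' Instantiates every category (sampling lengths, copy numbers and
#' zygosity), orders the resulting SVs most-restrictive-first (VCF-fixed,
#' exact, partial, containing, contained, terminal/whole-chromosome, then
#' unconstrained) with ties broken by descending span, and places them one
#' by one against a shared occupied-interval index.
#'
#' @param categories list of [SVCategory-class].
#' @param reference \code{DNAStringSet}.
#' @param rois labeled \code{GRanges} of regions of interest.
#' @param params a [SimulationParams-class].
#' @param blacklist \code{GRanges} of globally blacklisted regions.
#' @return list of placed [PlacedSV-class], in instantiation order.
#' @export
placeAll <- function(categories, reference,
                     rois = GenomicRanges::GRanges(),
                     params = new("SimulationParams"),
                     blacklist = GenomicRanges::GRanges()) {
  items <- list()
  counter <- 0L
  for (ci in seq_along(categories)) {
    cat <- categories[[ci]]
    if (!is.na(cat@vcfPath)) {
      for (sv in importVcfSVs(cat@vcfPath, reference)) {
        items[[length(items) + 1L]] <- list(sv = sv, category = cat)
      }
      next
    }
    for (j in seq_len(cat@count)) {
      counter <- counter + 1L
      sv <- new("PlacedSV", id = sprintf("sv%d", counter), type = cat@type,
                rule = cat@rule, intervals = data.frame(),
                targetInfo = data.frame(), records = emptyRecords(),
                haplotypes = 0:1, fixed = FALSE)
      sv <- assignZygosity(list(sv), cat@homozygousProb)[[1]]
      # provisional lengths: used for span-based ordering only
      lens <- sampleLengths(cat)
      if (length(lens) && !categoryIsSpecialTR(cat)) {
        sv@intervals <- data.frame(symbol = names(lens),
                                   chrom = NA_character_, start = 0,
                                   end = unname(lens),
                                   stringsAsFactors = FALSE)
      }
      items[[length(items) + 1L]] <- list(sv = sv, category = cat)
    }
  }
  if (!length(items)) return(list())
  ord <- orderCategories(lapply(items, `[[`, "sv"),
                         lapply(items, function(it) it$category@constraints))
  st <- placementState(reference)
  placed <- vector("list", length(items))
  for (k in ord) {
    it <- items[[k]]
    sv <- it$sv
    if (sv@fixed) {
      if (!checkProposal(st, sv, params, blacklist))
        placementError(sprintf(
          "imported SV %s violates placement rules (overlap, distance or blacklist)",
          sv@id))
      commitSV(st, sv)
      placed[[k]] <- sv
    } else {
      sv@intervals <- data.frame()
      placed[[k]] <- placeSV(sv, it$category, st, rois, blacklist, params,
                             reference)
    }
  }
  placed
}

categoryIsSpecialTR <- function(cat) {
  sp <- categorySpecial(cat)
  !is.na(sp) && sp %in% c("TR_EXPANSION", "TR_CONTRACTION")
}

# ---- standalone audit ------------------------------------------------------

#' Independently audit a placed SV against its constraint
#'
#' A standalone checker, separate from the placement sampler: it recomputes
#' the anchored span from the SV's symbol intervals and verifies the
#' declared constraint mode against the ROI set by direct coordinate
#' comparison.
#'
#' @param sv a placed [PlacedSV-class].
#' @param constraint \code{list(mode =, labels =)}.
#' @param rois labeled \code{GRanges}.
#' @param chromLens named lengths of the reference chromosomes (needed for
#'   terminal and whole-chromosome modes).
#' @return \code{TRUE}, or a character vector of violations.
#' @export
auditPlacement <- function(sv, constraint, rois, chromLens = NULL) {
  iv <- sv@intervals
  rule <- sv@rule
  fails <- character(0)
  # anchored span from resolved intervals
  if (length(rule@anchorSymbols)) {
    rows <- iv[iv$symbol %in% rule@anchorSymbols, , drop = FALSE]
  } else if (!is.na(rule@anchorJunction)) {
    j <- rule@anchorJunction
    p <- if (j == 0) iv$start[1] else iv$end[j]
    rows <- data.frame(chrom = iv$chrom[max(j, 1)], start = p, end = p)
  } else {
    rows <- iv
  }
  rows <- rows[!is.na(rows$start), , drop = FALSE]
  chrom <- rows$chrom[1]
  aStart <- min(rows$start); aEnd <- max(rows$end)
  mode <- constraint$mode
  cand <- roisWithLabels(rois, constraint$labels)
  onChrom <- if (length(cand))
    cand[as.character(GenomicRanges::seqnames(cand)) == chrom] else cand
  s <- if (length(onChrom)) GenomicRanges::start(onChrom) - 1 else numeric(0)
  e <- if (length(onChrom)) GenomicRanges::end(onChrom) else numeric(0)
  if (mode == "exact") {
    if (aEnd > aStart) {
      if (!any(s == aStart & e == aEnd))
        fails <- c(fails, sprintf("exact: span %s:%g-%g matches no ROI",
                                  chrom, aStart, aEnd))
    } else if (!any(s == aStart | e == aStart)) {
      fails <- c(fails, "exact: anchored breakend is at no ROI boundary")
    }
  } else if (mode == "partial") {
    insideStart <- any(s < aStart & aStart < e)
    insideEnd <- any(s < aEnd & aEnd < e)
    if (aEnd > aStart) {
      if (sum(insideStart, insideEnd) != 1L)
        fails <- c(fails, sprintf(
          "partial: expected exactly one breakend inside an ROI, got %d",
          sum(insideStart, insideEnd)))
    } else if (!insideStart) {
      fails <- c(fails, "partial: anchored breakend not inside an ROI")
    }
  } else if (mode == "contained") {
    if (!any(s <= aStart & aEnd <= e))
      fails <- c(fails, sprintf("contained: span %s:%g-%g is inside no ROI",
                                chrom, aStart, aEnd))
  } else if (mode == "containing") {
    if (!any(aStart <= s & e <= aEnd))
      fails <- c(fails, "containing: span contains no ROI")
  } else if (mode == "terminal") {
    if (is.null(chromLens)) fails <- c(fails, "terminal: chromLens required")
    else if (aStart != 0 && aEnd != chromLens[[chrom]])
      fails <- c(fails, "terminal: no breakend at a chromosome end")
  } else if (mode == "whole_chromosome") {
    if (is.null(chromLens)) fails <- c(fails, "whole_chromosome: chromLens required")
    else if (!(aStart == 0 && aEnd == chromLens[[chrom]]))
      fails <- c(fails, "whole_chromosome: span does not cover the chromosome")
  } else if (mode == "blacklist") {
    bks <- breakendsOf(sv)
    for (i in seq_len(nrow(bks))) {
      bl <- roisWithLabels(rois, constraint$labels)
      if (pointInRanges(bks$chrom[i], bks$pos[i], bl))
        fails <- c(fails, sprintf("blacklist: breakend %s:%g inside a blacklisted ROI",
                                  bks$chrom[i], bks$pos[i]))
    }
  }
  if (length(fails)) fails else TRUE
}
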