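#' @import methods
#' @importFrom S4Vectors mcols
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' RearrangementRule: a parsed rearrangement expression
#'
#' A rearrangement rule maps an ordered set of reference intervals (the
#' source side, capital letters plus \code{_} dispersion symbols) to an
#' alternative allele structure (the target side, where lowercase letters
#' denote inversion, repeated letters denote copies, a \code{+} suffix marks
#' a variable copy number and letters absent from the source denote novel
#' insertions). Parentheses on the source side mark the anchored sub-span
#' used by placement constraints.
#'
#' Token tables have one row per token with columns \code{symbol} (letter or
#' \code{_k} for the k-th dispersion), \code{letter}, \code{inverted},
#' \code{dispersion}, \code{plus}, \code{anchor} and \code{seg} (1-based
#' segment index, segments being the runs between dispersions).
#'
#' @slot source data.frame of source-side tokens.
#' @slot target data.frame of target-side tokens.
#' @slot canonical normalized string form \code{"SRC→TGT"}.
#' @slot anchorSymbols letters inside \code{()} on the source side
#'   (length 0 when the rule has no anchor).
#' @slot anchorJunction for an empty \code{()} anchor, the 0-based junction
#'   index between source symbols it constrains; \code{NA_integer_} otherwise.
#' @export
setClass("RearrangementRule",
  representation(
    source = "data.frame",
    target = "data.frame",
    canonical = "character",
    anchorSymbols = "character",
    anchorJunction = "integer"
  )
)

#' SVCategory: one simulation unit
#'
#' The simulation unit is the 4-tuple (type, breakend distance ranges,
#' placement constraints, count): a rearrangement rule (named or custom), a
#' distance specification per symbol, optional placement constraints and the
#' number of events to draw.
#'
#' @slot type registry name or custom grammar expression.
#' @slot rule the parsed [RearrangementRule-class].
#' @slot distances named list mapping each length-bearing symbol to either a
#'   numeric \code{c(min, max)} range in bp or a derivation string of the
#'   form \code{"k*length(X)"}.
#' @slot constraints list of constraints, each \code{list(mode =, labels =)};
#'   at most one non-blacklist mode per category.
#' @slot count number of SVs to simulate.
#' @slot homozygousProb probability an event is homozygous.
#' @slot interchromosomal whether the dispersion spans two chromosomes.
#' @slot insertionSource \code{"random"} or path to a FASTA of candidate
#'   novel-insertion sequences.
#' @slot copyRange integer \code{c(min, max)} copies for \code{+} tokens.
#' @slot vcfPath path of a VCF of fixed SVs (import mode), else \code{NA}.
#' @export
setClass("SVCategory",
  representation(
    type = "character",
    rule = "RearrangementRule",
    distances = "list",
    constraints = "list",
    count = "integer",
    homozygousProb = "numeric",
    interchromosomal = "logical",
    insertionSource = "character",
    copyRange = "integer",
    vcfPath = "character"
  )
)

#' SimulationParams: global simulation parameters
#'
#' @slot referencePath path to the reference FASTA.
#' @slot roiFiles BED files providing labeled regions of interest.
#' @slot blacklistFiles BED files whose intervals no breakend may hit.
#' @slot minInterSVDist minimum breakend-to-breakend distance between
#'   distinct SVs, in bp (a floor of 1 bp is always enforced).
#' @slot allowCrossHapOverlap if \code{TRUE}, SVs on different haplotypes may
#'   occupy overlapping reference intervals.
#' @slot homozygousProb default homozygosity probability.
#' @slot randomSeed integer seed recorded in the config.
#' @slot maxPlacementAttempts rejection-sampling cap per SV.
#' @export
setClass("SimulationParams",
  representation(
    referencePath = "character",
    roiFiles = "character",
    blacklistFiles = "character",
    minInterSVDist = "numeric",
    allowCrossHapOverlap = "logical",
    homozygousProb = "numeric",
    randomSeed = "integer",
    maxPlacementAttempts = "integer"
  ),
  prototype(
    referencePath = NA_character_,
    roiFiles = character(0),
    blacklistFiles = character(0),
    minInterSVDist = 0,
    allowCrossHapOverlap = FALSE,
    homozygousProb = 0.5,
    randomSeed = NA_integer_,
    maxPlacementAttempts = 100L
  )
)

#' PlacedSV: an SV with resolved reference coordinates
#'
#' All coordinates are 0-based half-open internally; conversion to 1-based
#' happens only at VCF emission.
#'
#' @slot id unique identifier (also the VCF PARENT_SVID).
#' @slot type category type string.
#' @slot rule the rearrangement rule.
#' @slot intervals data.frame with one row per source symbol (letters and
#'   dispersions): \code{symbol, chrom, start, end}. Interchromosomal
#'   dispersions have \code{NA} coordinates.
#' @slot targetInfo data.frame mirroring the rule's target tokens with the
#'   per-instance sampled \code{copies} and any \code{novelSeq}.
#' @slot records data.frame of resolved atomic operations, one row per
#'   eventual VCF record (see \code{\link{svRecords}}).
#' @slot haplotypes integer subset of \code{0:1}.
#' @slot fixed \code{TRUE} for VCF-imported SVs with fixed coordinates.
#' @export
setClass("PlacedSV",
  representation(
    id = "character",
    type = "character",
    rule = "RearrangementRule",
    intervals = "data.frame",
    targetInfo = "data.frame",
    records = "data.frame",
    haplotypes = "integer",
    fixed = "logical"
  )
)

#' HaplotypeAssembly: block provenance of one synthetic haplotype
#'
#' Ordered blocks tile each synthetic contig with no gaps or overlaps; every
#' reference-origin block maps a query interval back to a reference interval
#' and strand, and novel-origin blocks carry their inserted sequence.
#'
#' @slot hap haplotype index, 0 or 1.
#' @slot blocks data.frame with columns \code{qname, qstart, qend, tname,
#'   tstart, tend, strand, origin, svId, seq}.
#' @slot qlens named numeric of synthetic contig lengths.
#' @slot tlens named numeric of reference contig lengths.
#' @export
setClass("HaplotypeAssembly",
  representation(
    hap = "integer",
    blocks = "data.frame",
    qlens = "numeric",
    tlens = "numeric"
  )
)

#' SimulationResult: everything produced by one simulation run
#'
#' @slot svs list of [PlacedSV-class].
#' @slot assemblies list of two [HaplotypeAssembly-class] (haplotypes 0, 1).
#' @slot sequences list of two \code{DNAStringSet} haplotype sequences.
#' @slot params the [SimulationParams-class] used.
#' @slot paths named character vector of emitted files.
#' @export
setClass("SimulationResult",
  representation(
    svs = "list",
    assemblies = "list",
    sequences = "list",
    params = "SimulationParams",
    paths = "character"
  )
)

#' FixtureSpec: plan for a synthetic test reference
#'
#' Describes a reproducible synthetic reference genome: chromosome lengths,
#' GC content, a plan of labeled ROI tracks (non-overlapping intervals with a
#' minimum spacing) and a plan of tandem-repeat loci whose motifs are planted
#' into the sequence.
#'
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @slot gc GC fraction of the random background sequence.
#' @slot roiPlan data.frame with columns \code{label, count, minLen, maxLen,
#'   spacing}.
#' @slot repeatPlan data.frame with columns \code{motif, copies, count}.
#' @slot seed integer seed making the fixture reproducible.
#' @export
setClass("FixtureSpec",
  representation(
    chromLengths = "numeric",
    gc = "numeric",
    roiPlan = "data.frame",
    repeatPlan = "data.frame",
    seed = "integer"
  )
)

setValidity("RearrangementRule", function(object) {
  msgs <- character(0)
  src <- object@source
  tgt <- object@target
  letters_src <- src$letter[!src$dispersion]
  if (anyDuplicated(letters_src))
    msgs <- c(msgs, "source letters must not repeat")
  if (sum(src$dispersion) != sum(tgt$dispersion))
    msgs <- c(msgs, "dispersion count must match between source and target")
  if (any(tgt$dispersion & tgt$inverted) || any(src$dispersion & src$inverted))
    msgs <- c(msgs, "dispersion tokens cannot be inverted")
  if (any(src$plus))
    msgs <- c(msgs, "'+' is only valid on target-side tokens")
  if (length(msgs)) msgs else TRUE
})

setValidity("SVCategory", function(object) {
  msgs <- character(0)
  if (length(object@count) != 1L || is.na(object@count) || object@count < 1L)
    msgs <- c(msgs, "count must be a positive integer")
  if (object@homozygousProb < 0 || object@homozygousProb > 1)
    msgs <- c(msgs, "homozygousProb must be in [0,1]")
  # range sanity is reported as diagnostics by validateCategory(), not here
  if (length(msgs)) msgs else TRUE
})

setValidity("PlacedSV", function(object) {
  msgs <- character(0)
  if (!all(object@haplotypes %in% 0:1))
    msgs <- c(msgs, "haplotypes must be a subset of 0:1")
  iv <- object@intervals
  if (nrow(iv)) {
    ok <- is.na(iv$start) | is.na(iv$end) | iv$start <= iv$end
    if (!all(ok)) msgs <- c(msgs, "intervals must have start <= end")
  }
  if (length(msgs)) msgs else TRUE
})

setValidity("HaplotypeAssembly", function(object) {
  b <- object@blocks
  if (nrow(b) == 0) return(TRUE)
  for (qn in unique(b$qname)) {
    bb <- b[b$qname == qn, , drop = FALSE]
    bb <- bb[order(bb$qstart), , drop = FALSE]
    if (bb$qstart[1] != 0)
      return(sprintf("blocks of %s do not start at 0", qn))
    if (nrow(bb) > 1 && any(bb$qstart[-1] != bb$qend[-nrow(bb)]))
      return(sprintf("blocks of %s do not tile the contig", qn))
  }
  TRUE
})

setMethod("show", "RearrangementRule", function(object) {
  cat("RearrangementRule:", object@canonical, "\n")
  cat("  source symbols:", paste(object@source$symbol, collapse = " "), "\n")
  cat("  target tokens: ",
      paste(tokenDisplay(object@target), collapse = " "), "\n")
  if (length(object@anchorSymbols))
    cat("  anchor:", paste(object@anchorSymbols, collapse = ""), "\n")
  else if (!is.na(object@anchorJunction))
    cat("  anchor: breakend at junction", object@anchorJunction, "\n")
  invisible(NULL)
})

setMethod("show", "SVCategory", function(object) {
  cat(sprintf("SVCategory: %s (n = %d)\n", object@type, object@count))
  cat("  rule:", object@rule@canonical, "\n")
  if (length(object@constraints)) {
    for (cc in object@constraints)
      cat(sprintf("  constraint: %s [%s]\n", cc$mode,
                  paste(cc$labels, collapse = ",")))
  }
  invisible(NULL)
})

setMethod("show", "PlacedSV", function(object) {
  cat(sprintf("PlacedSV %s: %s on haplotype(s) %s%s\n", object@id,
              object@type, paste(object@haplotypes, collapse = ","),
              if (object@fixed) " [fixed]" else ""))
  iv <- object@intervals
  iv <- iv[!is.na(iv$start), , drop = FALSE]
  if (nrow(iv))
    cat(paste(sprintf("  %s: %s:%d-%d", iv$symbol, iv$chrom,
                      as.integer(iv$start), as.integer(iv$end)),
              collapse = "\n"), "\n")
  invisible(NULL)
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d SVs on %d reference contig(s)\n",
              length(object@svs), length(object@assemblies[[1]]@tlens)))
  if (length(object@paths))
    cat(paste0("  ", names(object@paths), ": ", object@paths, collapse = "\n"),
        "\n")
  invisible(NULL)
})

# ---- accessors -------------------------------------------------------------

#' Accessors for simulation objects
#'
#' Slot accessors for the package's S4 classes: identifiers, types, rules,
#' resolved intervals and haplotype assignments of placed SVs, assembly
#' blocks, and the pieces of a [SimulationResult-class].
#'
#' @name accessors
#' @return the corresponding component of \code{x}.
NULL

#' @rdname accessors
#' @param x an svforge S4 object.
#' @export
setGeneric("svId", function(x) standardGeneric("svId"))
#' @rdname accessors
#' @export
setMethod("svId", "PlacedSV", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("svType", function(x) standardGeneric("svType"))
#' @rdname accessors
#' @export
setMethod("svType", "PlacedSV", function(x) x@type)
#' @rdname accessors
#' @export
setMethod("svType", "SVCategory", function(x) x@type)

#' @rdname accessors
#' @export
setGeneric("svRule", function(x) standardGeneric("svRule"))
#' @rdname accessors
#' @export
setMethod("svRule", "PlacedSV", function(x) x@rule)
#' @rdname accessors
#' @export
setMethod("svRule", "SVCategory", function(x) x@rule)

#' @rdname accessors
#' @export
setGeneric("svIntervals", function(x) standardGeneric("svIntervals"))
#' @rdname accessors
#' @export
setMethod("svIntervals", "PlacedSV", function(x) x@intervals)

#' @rdname accessors
#' @export
setGeneric("svHaplotypes", function(x) standardGeneric("svHaplotypes"))
#' @rdname accessors
#' @export
setMethod("svHaplotypes", "PlacedSV", function(x) x@haplotypes)

#' Resolved atomic operations of a placed SV
#'
#' One row per eventual VCF record, with 0-based half-open coordinates.
#' Columns: \code{kind} (DEL, INV, DUP, INS, SNP), \code{chrom, start, end}
#' (affected reference span; \code{start == end} for point insertions),
#' \code{srcChrom, srcStart, srcEnd, srcInverted} (copy provenance),
#' \code{copies}, \code{seq} (novel sequence or SNP ALT), \code{symbol},
#' \code{operation} (grammar-level classification) and \code{slot}.
#'
#' @param x a [PlacedSV-class].
#' @return a data.frame.
#' @export
setGeneric("svRecords", function(x) standardGeneric("svRecords"))
#' @rdname svRecords
#' @export
setMethod("svRecords", "PlacedSV", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("assemblyBlocks", function(x) standardGeneric("assemblyBlocks"))
#' @rdname accessors
#' @export
setMethod("assemblyBlocks", "HaplotypeAssembly", function(x) x@blocks)

#' @rdname accessors
#' @export
setGeneric("placedSVs", function(x) standardGeneric("placedSVs"))
#' @rdname accessors
#' @export
setMethod("placedSVs", "SimulationResult", function(x) x@svs)

#' @rdname accessors
#' @export
setGeneric("outputPaths", function(x) standardGeneric("outputPaths"))
#' @rdname accessors
#' @export
setMethod("outputPaths", "SimulationResult", function(x) x@paths)

#' @rdname accessors
#' @export
setGeneric("haplotypeSequences", function(x) standardGeneric("haplotypeSequences"))
#' @rdname accessors
#' @export
setMethod("haplotypeSequences", "SimulationResult", function(x) x@sequences)
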