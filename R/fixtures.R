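# Synthetic reference fixtures: reproducible random genomes with planted,
# labeled ROI tracks and tandem-repeat loci, plus the scaled case-study
# configuration trio (blacklist / exact / containing deletion placement).

withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Construct a fixture specification
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param gc GC fraction of the random background.
#' @param roiPlan data.frame with columns \code{label, count, minLen,
#'   maxLen, spacing} (spacing = minimum gap to any other planned interval).
#' @param repeatPlan data.frame with columns \code{motif, copies, count}
#'   describing tandem-repeat loci planted into the sequence and labeled
#'   \code{TR_<motif>}.
#' @param seed integer seed.
#' @return a [FixtureSpec-class].
#' @export
fixtureSpec <- function(chromLengths = c(chr1 = 1e5), gc = 0.41,
                        roiPlan = NULL, repeatPlan = NULL, seed = 1L) {
  empty <- data.frame(label = character(0), count = integer(0),
                      minLen = numeric(0), maxLen = numeric(0),
                      spacing = numeric(0), stringsAsFactors = FALSE)
  emptyRep <- data.frame(motif = character(0), copies = integer(0),
                         count = integer(0), stringsAsFactors = FALSE)
  new("FixtureSpec", chromLengths = chromLengths, gc = gc,
      roiPlan = if (is.null(roiPlan)) empty else roiPlan,
      repeatPlan = if (is.null(repeatPlan)) emptyRep else repeatPlan,
      seed = as.integer(seed))
}

# non-overlapping interval sampling with spacing against prior intervals
sampleFixtureIntervals <- function(chromLengths, count, minLen, maxLen,
                                   spacing, existing) {
  out <- existing
  added <- list()
  for (k in seq_len(count)) {
    placedOk <- FALSE
    for (attempt in 1:500) {
      len <- round(minLen + stats::runif(1) * (maxLen - minLen))
      w <- pmax(chromLengths - len + 1, 0)
      chrom <- sample(names(chromLengths), 1, prob = w / sum(w))
      start <- floor(stats::runif(1) * (chromLengths[[chrom]] - len + 1))
      end <- start + len
      conflict <- FALSE
      prior <- out[[chrom]]
      if (!is.null(prior) && nrow(prior)) {
        conflict <- any(start < prior$end + spacing &
                        prior$start - spacing < end)
      }
      if (!conflict) {
        row <- data.frame(start = start, end = end, stringsAsFactors = FALSE)
        out[[chrom]] <- rbind(prior, row)
        added[[k]] <- data.frame(chrom = chrom, start = start, end = end,
                                 stringsAsFactors = FALSE)
        placedOk <- TRUE
        break
      }
    }
    if (!placedOk)
      svError("infeasible ROI plan: could not place all planned intervals",
              "svforgeFixtureError")
  }
  list(occupied = out, added = do.call(rbind, added))
}

#' Generate a synthetic reference with labeled ROI tracks
#'
#' Deterministic given the spec's seed: a random background genome at the
#' requested GC content, labeled ROI intervals placed without overlap, and
#' tandem-repeat loci whose motif copies are planted into the sequence.
#' Writes the reference FASTA and one BED per label under \code{dir}.
#'
#' @param spec a [FixtureSpec-class].
#' @param dir output directory (created if needed).
#' @return list with \code{fasta} (path), \code{beds} (named paths per
#'   label), \code{rois} (labeled \code{GRanges}) and \code{reference}
#'   (\code{DNAStringSet}).
#' @export
makeReference <- function(spec, dir) {
  stopifnot(is(spec, "FixtureSpec"))
  # feasibility check before any file is written
  need <- 0
  if (nrow(spec@roiPlan))
    need <- need + sum(spec@roiPlan$count *
                       (spec@roiPlan$maxLen + spec@roiPlan$spacing))
  if (nrow(spec@repeatPlan))
    need <- need + sum(spec@repeatPlan$count *
                       (nchar(spec@repeatPlan$motif) * spec@repeatPlan$copies + 500))
  if (need > 0.95 * sum(spec@chromLengths))
    svError("infeasible ROI plan: planned intervals exceed genome capacity",
            "svforgeFixtureError")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withSeed(spec@seed, {
    seqs <- lapply(spec@chromLengths, function(L) randomSeqStr(L, spec@gc))
    occupied <- list()
    roiRows <- list()
    for (i in seq_len(nrow(spec@roiPlan))) {
      p <- spec@roiPlan[i, ]
      res <- sampleFixtureIntervals(spec@chromLengths, p$count, p$minLen,
                                    p$maxLen, p$spacing, occupied)
      occupied <- res$occupied
      if (!is.null(res$added)) {
        res$added$label <- p$label
        roiRows[[length(roiRows) + 1L]] <- res$added
      }
    }
    for (i in seq_len(nrow(spec@repeatPlan))) {
      p <- spec@repeatPlan[i, ]
      L <- nchar(p$motif) * p$copies
      res <- sampleFixtureIntervals(spec@chromLengths, p$count, L, L, 500,
                                    occupied)
      occupied <- res$occupied
      if (!is.null(res$added)) {
        res$added$label <- paste0("TR_", p$motif)
        for (j in seq_len(nrow(res$added))) {
          a <- res$added[j, ]
          substr(seqs[[a$chrom]], a$start + 1, a$end) <-
            strrep(p$motif, p$copies)
        }
        roiRows[[length(roiRows) + 1L]] <- res$added
      }
    }
    reference <- Biostrings::DNAStringSet(unlist(seqs))
    names(reference) <- names(spec@chromLengths)
    fastaPath <- file.path(dir, "reference.fa")
    Biostrings::writeXStringSet(reference, fastaPath, width = 60)
    rois <- if (length(roiRows)) do.call(rbind, roiRows) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 label = character(0), stringsAsFactors = FALSE)
    beds <- character(0)
    for (lab in unique(rois$label)) {
      sub <- rois[rois$label == lab, , drop = FALSE]
      sub <- sub[order(sub$chrom, sub$start), , drop = FALSE]
      bedPath <- file.path(dir, paste0(lab, ".bed"))
      writeLines(sprintf("%s\t%d\t%d\t%s", sub$chrom, as.integer(sub$start),
                         as.integer(sub$end), sub$label), bedPath)
      beds[lab] <- bedPath
    }
    gr <- if (nrow(rois)) {
      GenomicRanges::GRanges(rois$chrom,
                             IRanges::IRanges(rois$start + 1, rois$end),
                             label = rois$label)
    } else GenomicRanges::GRanges()
    list(fasta = fastaPath, beds = beds, rois = gr, reference = reference)
  })
}

#' Fixture emulating the deletion-placement case study at desk scale
#'
#' A 10 Mb single-chromosome reference with a LINE-1-like track (labeled
#' \code{L1HS}) and a satellite-like track (labeled \code{ALR}), standing in
#' for a human chromosome with RepeatMasker annotations. The repeat tracks
#' are random-sequence intervals: only their coordinates, not their sequence
#' content, drive placement.
#'
#' @param dir output directory.
#' @param seed fixture seed.
#' @param scale genome scale factor (1 = 10 Mb); ROI counts scale with it.
#' @return as [makeReference()].
#' @export
caseStudyFixture <- function(dir, seed = 1L, scale = 1) {
  spec <- fixtureSpec(
    chromLengths = c(chr1 = round(1e7 * scale)),
    gc = 0.41,
    roiPlan = data.frame(
      label = c("L1HS", "ALR"),
      count = c(round(200 * scale), round(150 * scale)),
      minLen = c(6000, 2000), maxLen = c(7000, 4000),
      spacing = c(3000, 12000),
      stringsAsFactors = FALSE),
    seed = seed)
  makeReference(spec, dir)
}

#' Write the three case-study deletion configurations
#'
#' Three YAML configurations over a case-study fixture, all simulating
#' deletions of 1--10 kbp with a minimum inter-SV distance of 1 kbp:
#' \describe{
#'   \item{blacklist}{breakends excluded from every ROI track (unique-region
#'     placement), \code{nBlacklist} deletions;}
#'   \item{exact}{deletion breakends coinciding exactly with L1HS-like
#'     interval boundaries, \code{nConstrained} deletions;}
#'   \item{containing}{each deletion fully containing an ALR-like interval,
#'     \code{nConstrained} deletions.}
#' }
#'
#' @param fixture result of [caseStudyFixture()].
#' @param dir directory for the YAML files (defaults to the fixture's).
#' @param nBlacklist deletions in the blacklist configuration.
#' @param nConstrained deletions in each constrained configuration.
#' @param seed seed recorded in the configs.
#' @return named character vector of the three config paths.
#' @export
caseStudyConfigs <- function(fixture, dir = dirname(fixture$fasta),
                             nBlacklist = 500, nConstrained = 100,
                             seed = 1L) {
  relOrAbs <- function(p) {
    if (dirname(normalizePath(p, mustWork = FALSE)) ==
        normalizePath(dir, mustWork = FALSE)) basename(p) else p
  }
  base <- list(
    reference = relOrAbs(fixture$fasta),
    overlap_regions = as.list(unname(vapply(fixture$beds, relOrAbs, ""))),
    min_intersv_dist = 1000L,
    random_seed = as.integer(seed))
  mkset <- function(number, extra = list()) {
    c(list(type = "DEL", number = as.integer(number),
           length_ranges = list(list(1000L, 10000L))), extra)
  }
  cfgs <- list(
    blacklist = c(base, list(variant_sets = list(mkset(nBlacklist, list(
      overlap_mode = "blacklist",
      overlap_region_type = as.list(names(fixture$beds))))))),
    exact = c(base, list(variant_sets = list(mkset(nConstrained, list(
      overlap_mode = "exact", overlap_region_type = list("L1HS")))))),
    containing = c(base, list(variant_sets = list(mkset(nConstrained, list(
      overlap_mode = "containing", overlap_region_type = list("ALR"))))))
  )
  paths <- character(0)
  for (nm in names(cfgs)) {
    p <- file.path(dir, paste0("case_", nm, ".yaml"))
    yaml::write_yaml(cfgs[[nm]], p)
    paths[nm] <- p
  }
  paths
}
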