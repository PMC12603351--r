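# YAML simulation configuration: parsing, validation, defaults.
#
# Top-level keys: reference (FASTA path, required), overlap_regions and
# blacklist_regions (lists of BED paths), min_intersv_dist,
# allow_cross_haplotype_overlap, homozygous_prob (or homozygous_only: true),
# random_seed, max_placement_attempts, variant_sets (list of categories).
# Category keys: type (registry name or grammar expression) or vcf (path of
# fixed SVs), number, length_ranges (list of [min,max] per length-bearing
# symbol, or a mapping keyed by symbol; entries may be derivation strings
# "k*length(X)"), overlap_mode, overlap_region_type, homozygous_prob,
# interchromosomal, insertion_source, copy_number.
# All paths are resolved relative to the configuration file's directory.

configError <- function(msg) svError(msg, "svforgeConfigError")

.VALID_MODES <- c("partial", "exact", "contained", "containing", "terminal",
                  "whole_chromosome", "blacklist")

resolvePath <- function(path, baseDir) {
  if (is.null(path) || is.na(path)) return(NA_character_)
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(baseDir, path)
}

asRangeOrDerivation <- function(x, where) {
  if (is.character(x) && length(x) == 1L) return(x)
  v <- suppressWarnings(as.numeric(unlist(x)))
  if (length(v) == 1L) v <- c(v, v)
  if (length(v) != 2L || any(is.na(v)))
    configError(sprintf("%s: length range must be [min,max] or a derivation string", where))
  v
}

parseCategory <- function(raw, idx, baseDir, defaultHomozygousProb = 0.5) {
  where <- sprintf("variant_sets[%d]", idx)
  if (!is.null(raw$vcf)) {
    cat <- new("SVCategory", type = "vcf_import", rule = parseRule("A→A"),
               distances = list(), constraints = list(), count = 1L,
               homozygousProb = 0.5, interchromosomal = FALSE,
               insertionSource = "random", copyRange = c(1L, 1L),
               vcfPath = resolvePath(raw$vcf, baseDir))
    return(cat)
  }
  if (is.null(raw$type))
    configError(sprintf("%s: missing required field 'type'", where))
  typeStr <- as.character(raw$type)
  entry <- tryCatch(lookupType(typeStr), error = function(e) e)
  if (inherits(entry, "error")) {
    rule <- tryCatch(parseRule(typeStr), error = function(e) e)
    if (inherits(rule, "error"))
      configError(sprintf(
        "%s: '%s' is neither a registry name (%s) nor a parseable expression (%s)",
        where, typeStr, conditionMessage(entry), conditionMessage(rule)))
    special <- NA_character_
    interDefault <- FALSE
  } else {
    rule <- entry$rule
    special <- entry$special
    interDefault <- entry$interchromosomal
  }
  if (is.null(raw$number))
    configError(sprintf("%s: missing required field 'number'", where))
  count <- suppressWarnings(as.integer(raw$number))
  if (is.na(count) || count < 1L)
    configError(sprintf("%s: 'number' must be a positive integer", where))

  inter <- if (!is.null(raw$interchromosomal)) isTRUE(raw$interchromosomal)
           else interDefault
  syms <- lengthBearingSymbols(rule, interchromosomal = inter)
  if (!is.na(special) && special %in% c("SNP"))
    syms <- "A"

  lr <- raw$length_ranges
  distances <- list()
  if (!is.null(lr)) {
    if (!is.null(names(lr)) && all(nzchar(names(lr)))) {
      for (nm in names(lr))
        distances[[nm]] <- asRangeOrDerivation(lr[[nm]],
                                               sprintf("%s symbol %s", where, nm))
    } else {
      if (length(lr) > length(syms))
        configError(sprintf(
          "%s: %d length_ranges given but rule has %d length-bearing symbols (%s)",
          where, length(lr), length(syms), paste(syms, collapse = ",")))
      for (k in seq_along(lr))
        distances[[syms[k]]] <- asRangeOrDerivation(lr[[k]],
                                                    sprintf("%s entry %d", where, k))
    }
  }
  if (!is.na(special) && special == "SNP" && is.null(distances[["A"]]))
    distances[["A"]] <- c(1, 1)

  constraints <- list()
  if (!is.null(raw$overlap_mode)) {
    mode <- as.character(raw$overlap_mode)
    if (!mode %in% .VALID_MODES)
      configError(sprintf("%s: unknown overlap_mode '%s' (valid: %s)",
                          where, mode, paste(.VALID_MODES, collapse = ", ")))
    labels <- as.character(unlist(raw$overlap_region_type %||% character(0)))
    constraints[[1]] <- list(mode = mode, labels = labels)
  }
  hz <- raw$homozygous_prob
  if (is.null(hz) && isTRUE(raw$homozygous_only)) hz <- 1
  copyRange <- if (!is.null(raw$copy_number)) {
    v <- as.integer(unlist(raw$copy_number))
    if (length(v) == 1L) c(v, v) else v[1:2]
  } else c(1L, 1L)

  new("SVCategory", type = typeStr, rule = rule, distances = distances,
      constraints = constraints, count = count,
      homozygousProb = if (is.null(hz)) defaultHomozygousProb
                       else as.numeric(hz),
      interchromosomal = inter,
      insertionSource = {
        src <- raw$insertion_source %||% "random"
        if (identical(src, "random")) "random" else resolvePath(src, baseDir)
      },
      copyRange = copyRange, vcfPath = NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

categorySpecial <- function(category) {
  entry <- .SV_REGISTRY[[category@type]]
  if (is.null(entry)) NA_character_ else entry$special
}

#' Validate an SV category
#'
#' Checks a parsed category for simulability without raising: every symbol
#' of the rule (source letters, dispersions, novel insertions) must have a
#' distance entry or derivation, derivations must reference defined symbols
#' without cycles, ranges must satisfy 0 < min <= max, and constraints must
#' have ROI labels available when they need them.
#'
#' @param category an [SVCategory-class].
#' @param params optional [SimulationParams-class]; when given, constraints
#'   referencing ROI labels are checked against the declared ROI files.
#' @return a character vector of diagnostics; empty when the category is
#'   simulable.
#' @export
validateCategory <- function(category, params = NULL) {
  diags <- character(0)
  if (!is.na(category@vcfPath)) {
    if (!file.exists(category@vcfPath))
      diags <- c(diags, sprintf("missing-file: VCF '%s' does not exist",
                                category@vcfPath))
    return(diags)
  }
  special <- categorySpecial(category)
  syms <- lengthBearingSymbols(category@rule, category@interchromosomal)
  if (!is.na(special) && special == "SNP") syms <- "A"
  for (s in syms) {
    if (is.null(category@distances[[s]]))
      diags <- c(diags, sprintf("missing-distance: missing distance for symbol %s", s))
  }
  deps <- list()
  for (nm in names(category@distances)) {
    d <- category@distances[[nm]]
    if (is.character(d)) {
      m <- regmatches(d, regexec(
        "^\\s*([0-9]*\\.?[0-9]+)\\s*\\*\\s*length\\(\\s*(_?[A-Z0-9]+)\\s*\\)\\s*$", d))[[1]]
      if (length(m) != 3L) {
        diags <- c(diags, sprintf(
          "bad-derivation: cannot parse derivation '%s' for symbol %s", d, nm))
        next
      }
      ref <- m[3]
      if (!ref %in% syms)
        diags <- c(diags, sprintf(
          "unknown-symbol: derivation for %s references undefined symbol %s", nm, ref))
      deps[[nm]] <- ref
    } else if (is.numeric(d)) {
      if (length(d) != 2L || any(is.na(d)) || d[1] <= 0 || d[1] > d[2])
        diags <- c(diags, sprintf(
          "bad-range: range for symbol %s must satisfy 0 < min <= max", nm))
    }
  }
  # cycle detection over derivation dependencies
  for (start in names(deps)) {
    seen <- start
    cur <- deps[[start]]
    while (!is.null(cur) && !is.na(cur)) {
      if (cur %in% seen) {
        diags <- c(diags, sprintf(
          "derivation-cycle: cycle in length derivations involving %s",
          paste(c(seen, cur), collapse = " -> ")))
        break
      }
      seen <- c(seen, cur)
      cur <- deps[[cur]]
    }
  }
  for (cc in category@constraints) {
    if (!cc$mode %in% .VALID_MODES)
      diags <- c(diags, sprintf("bad-mode: unknown constraint mode '%s'", cc$mode))
    needsRoi <- cc$mode %in% c("partial", "exact", "contained", "containing",
                               "blacklist")
    if (needsRoi && !is.null(params) &&
        length(params@roiFiles) == 0 && length(params@blacklistFiles) == 0)
      diags <- c(diags, sprintf(
        "missing-roi: constraint '%s' requires ROI files but none are declared",
        cc$mode))
  }
  if (!is.na(special) && special %in% c("TR_EXPANSION", "TR_CONTRACTION") &&
      !is.null(params) && length(params@roiFiles) == 0)
    diags <- c(diags, "missing-roi: tandem repeat events require an ROI file of repeat loci")
  if (length(category@rule@anchorSymbols)) {
    idx <- which(category@rule@source$anchor & !category@rule@source$dispersion)
    if (length(idx) && any(diff(idx) > 1) &&
        !all(category@rule@source$anchor[min(idx):max(idx)]))
      diags <- c(diags, "bad-anchor: anchored symbols must be contiguous")
  }
  diags
}

#' Load and validate a simulation configuration
#'
#' Parses the YAML configuration into global parameters and a list of
#' validated SV categories. Rule expressions are parsed eagerly so grammar
#' errors surface at load time; defaults are filled for omitted optional
#' fields. Identical file bytes always produce an identical configuration.
#'
#' @param path YAML configuration file.
#' @return a list with elements \code{params} (a
#'   [SimulationParams-class]) and \code{categories} (list of
#'   [SVCategory-class]).
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("reference: ref.fa", "variant_sets:", "  - type: DEL",
#'              "    number: 5", "    length_ranges: [[100, 200]]"), cfg)
#' loadConfig(cfg)$categories[[1]]
#' @export
loadConfig <- function(path) {
  if (!file.exists(path))
    configError(sprintf("configuration file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  baseDir <- dirname(normalizePath(path))
  if (is.null(raw$reference))
    configError("missing required top-level field 'reference'")
  params <- new("SimulationParams",
    referencePath = resolvePath(as.character(raw$reference), baseDir),
    roiFiles = vapply(as.list(unlist(raw$overlap_regions)),
                      resolvePath, "", baseDir = baseDir),
    blacklistFiles = vapply(as.list(unlist(raw$blacklist_regions)),
                            resolvePath, "", baseDir = baseDir),
    minInterSVDist = as.numeric(raw$min_intersv_dist %||% 0),
    allowCrossHapOverlap = isTRUE(raw$allow_cross_haplotype_overlap),
    homozygousProb = as.numeric(
      raw$homozygous_prob %||% (if (isTRUE(raw$homozygous_only)) 1 else 0.5)),
    randomSeed = if (is.null(raw$random_seed)) NA_integer_
                 else as.integer(raw$random_seed),
    maxPlacementAttempts = as.integer(raw$max_placement_attempts %||% 100L))
  if (params@minInterSVDist < 0)
    configError("min_intersv_dist must be non-negative")
  if (params@maxPlacementAttempts < 1L)
    configError("max_placement_attempts must be a positive integer")
  sets <- raw$variant_sets %||% list()
  categories <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    cat <- parseCategory(sets[[i]], i, baseDir, params@homozygousProb)
    validObject(cat)
    diags <- validateCategory(cat, params)
    if (length(diags))
      configError(sprintf("variant_sets[%d] (%s): %s", i, cat@type,
                          paste(diags, collapse = "; ")))
    categories[[i]] <- cat
  }
  list(params = params, categories = categories)
}
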