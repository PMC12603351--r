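# Top-level orchestration: configuration -> placed SVs -> diploid genome ->
# truthset files.

readBedRois <- function(paths) {
  grs <- list()
  for (p in paths) {
    gr <- rtracklayer::import(p, format = "BED")
    lab <- if (!is.null(S4Vectors::mcols(gr)$name) &&
               all(!is.na(S4Vectors::mcols(gr)$name)))
      S4Vectors::mcols(gr)$name
    else tools::file_path_sans_ext(basename(p))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(label = lab)
    grs[[length(grs) + 1L]] <- gr
  }
  if (!length(grs)) return(GenomicRanges::GRanges(label = character(0)))
  suppressWarnings(do.call(c, grs))
}

readReference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Run a full simulation
#'
#' Loads the YAML configuration, places all SVs, builds both synthetic
#' haplotypes, and writes the output set: \code{hapA.fa}, \code{hapB.fa},
#' \code{sim.vcf}, \code{hapA.paf}, \code{hapB.paf} and \code{stats.tsv}
#' under \code{outputDir}. Identical configuration bytes and seed give
#' byte-identical outputs.
#'
#' @param configPath YAML configuration file (see [loadConfig()]).
#' @param outputDir output directory (created if needed).
#' @param seed integer seed; overrides the config's \code{random_seed}.
#' @return a [SimulationResult-class].
#' @examples
#' \dontrun{
#' res <- simulateGenome("sim.yaml", "out", seed = 7)
#' placedSVs(res)[[1]]
#' }
#' @export
simulateGenome <- function(configPath, outputDir, seed = NULL) {
  cfg <- loadConfig(configPath)
  params <- cfg$params
  if (is.null(seed)) seed <- params@randomSeed
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
  reference <- readReference(params@referencePath)
  rois <- readBedRois(params@roiFiles)
  blacklist <- readBedRois(params@blacklistFiles)
  svs <- placeAll(cfg$categories, reference, rois, params, blacklist)
  hapA <- buildHaplotype(reference, svs, 0L)
  hapB <- buildHaplotype(reference, svs, 1L)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    hapA_fasta = file.path(outputDir, "hapA.fa"),
    hapB_fasta = file.path(outputDir, "hapB.fa"),
    vcf = file.path(outputDir, "sim.vcf"),
    hapA_paf = file.path(outputDir, "hapA.paf"),
    hapB_paf = file.path(outputDir, "hapB.paf"),
    stats = file.path(outputDir, "stats.tsv"))
  Biostrings::writeXStringSet(hapA$sequences, paths[["hapA_fasta"]], width = 60)
  Biostrings::writeXStringSet(hapB$sequences, paths[["hapB_fasta"]], width = 60)
  writeVcfTruthset(svs, reference, paths[["vcf"]])
  writePaf(hapA$assembly, paths[["hapA_paf"]])
  writePaf(hapB$assembly, paths[["hapB_paf"]])
  writeStats(svs, list(hapA$assembly, hapB$assembly), paths[["stats"]])
  new("SimulationResult", svs = svs,
      assemblies = list(hapA$assembly, hapB$assembly),
      sequences = list(hapA$sequences, hapB$sequences),
      params = params, paths = paths)
}
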