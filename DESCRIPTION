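Package: svforge
Title: Grammar-Based Structural Variant Simulation with Context-Aware
    Placement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates structural variants (SVs) on a reference genome and
    emits a synthetic diploid genome together with a machine-readable
    truthset. SV types are described by a small rearrangement grammar that
    maps reference intervals to alternative allele structures, so both a
    built-in library of 26 predefined SV classes and arbitrary custom
    rearrangements can be simulated. Placement of each SV is controlled by
    breakend distance ranges and by context constraints against annotated
    regions of interest (exact, partial, contained, containing, terminal,
    whole-chromosome and blacklist modes), with a minimum inter-SV distance
    and a greedy most-restrictive-first placement order. Outputs are a pair
    of haplotype FASTA files, a linked multi-record VCF truthset annotated
    with the grammar of each event, a pair of PAF liftover files mapping
    haplotype coordinates back to the reference, and a summary statistics
    table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
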