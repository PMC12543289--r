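Package: ripscan
Title: Compartment-Wise k-mer Screens for Repeat-Induced Point Mutation Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative screen for repeat-induced point mutation (RIP)-like
    signatures in fungal genome assemblies. Segments a genome into coding,
    non-coding and repeat compartments, counts 2-, 3- and 4-mers per
    compartment, computes non-coding and repeat enrichment ratios, and
    classifies genomes by recent, trace or absent RIP-like activity.
    Companion metrics include GC-content segmentation, gene-density
    compartmentalization ("two-speed" genomes), repeat sequence-identity
    binning from tabular self-alignments, pangenome orthogroup categories,
    orthogroup microsynteny ratios and phylogenetically independent
    contrasts. A synthetic-genome generator with context-specific C-to-T
    mutagenesis (CpA/TpG) and repeat-linker-repeat cross simulation makes
    the whole pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    ape,
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
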