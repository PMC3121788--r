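Package: nhoskit
Title: Quantifying the Stability of the Nuclear Higher-Order Structure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for nucleoid-based assays of the nuclear
    higher-order structure (NHOS): the genome-wide pattern of supercoiled
    DNA loops anchored to the nuclear matrix (NM). Provides a Monte-Carlo
    model of NM-anchored loop ensembles under limited DNase I digestion
    with an analytic oracle, digestion-kinetics analysis (local slopes,
    plateau, topological-zone schemes), positional mapping of gene
    amplicons relative to the NM from PCR positivity patterns, DNA-halo
    based loop-size estimation with group statistics, and the two
    competing loop-rearrangement models (MAR substitution versus MAR
    extension) used to interpret age-dependent NHOS stabilization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
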