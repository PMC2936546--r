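Package: kdchip
Title: Knockdown-Controlled ChIP-seq Analysis of Inducible Transcription
    Factor Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for inducible transcription-factor ChIP-seq
    with an RNAi knockdown control. Reconciles peaks from two callers and
    classifies each as knockdown-sensitive (genuine binding) or
    knockdown-resistant (false positive); builds a position-specific weight
    matrix for the heat-shock element (HSE), scans genomes with exact
    dynamic-programming p-values and assigns motifs to peak summits;
    computes k-mer mappability tracks to define the factor-free motif set;
    annotates motifs against gene models; and profiles tiling-array
    chromatin tracks around bound versus free motifs with Fisher exact
    association tests and k-means clustering. A synthetic-data generator
    with complete ground-truth bookkeeping makes every stage testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
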