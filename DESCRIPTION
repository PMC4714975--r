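Package: ighrep
Title: Immunoglobulin Heavy-Chain Repertoire Sequencing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for barcoded paired-end IgH
    amplicon sequencing: demultiplexing, quality trimming and perfect-overlap
    read merging; V(D)J segment assignment by Smith-Waterman local alignment
    against a germline reference with CDR3 boundary migration, junction
    reconstruction and somatic hypermutation calling; artifact removal
    (related-read collapsing, singleton removal and a Poisson model of
    barcode cross-contamination); repertoire statistics (D50 diversity,
    pairwise CDR3 peptide sharing, normalized VH usage, N-insertion
    profiles, convergent-recombination entropy, mutation and isotype
    summaries); and nested CDR3 treemap visualization. A seeded synthetic
    repertoire and sequencing-run simulator provides ground-truth data for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
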