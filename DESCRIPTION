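Package: numtscape
Title: Discovery and Characterization of Nuclear Mitochondrial DNA Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide discovery of nuclear copies of
    mitochondrial DNA (NUMTs). Provides an in-house seed-and-extend nucleotide
    local-alignment engine with Karlin-Altschul E-value statistics, NUMT
    calling with genome-level summary statistics, grouping of NUMTs into
    post-insertion duplication families, detection of split NUMT pairs and
    classification of the interposed sequence, genic-context classification
    from GFF3 annotation, and screening of EST sets for chimeric transcripts
    that carry expressed NUMTs. A synthetic-genome module plants NUMT
    insertions with tunable divergence into simulated nuclear genomes and
    records a machine-readable truth ledger, so every stage can be validated
    without external assemblies. Supports both linear (multi-chromosome, with
    inverted terminal repeats) and circular mitochondrial genome topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
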