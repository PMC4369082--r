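Package: ishop
Title: Insertion-Sequence Annotation and Local-Hopping Spatial Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates insertion-sequence (IS) content in bacterial genomes and
    tests its spatial organisation. Builds a named repeat library (de novo
    seed-and-extend discovery merged with a reference IS catalogue), locates
    repeat footprints by thresholded local-alignment search, iteratively
    decomposes footprints into attributed IS elements, classifies repeats from
    protein-similarity evidence, and computes three spatial statistics: a
    binomial cluster probability, a regression of pairwise nucleotide
    divergence on genomic separation (the "local hopping" signature), and
    pseudogene-proximity enrichment with Wilcoxon rank-sum testing. A forward
    simulator of transposition histories with a replayable event log provides
    planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
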