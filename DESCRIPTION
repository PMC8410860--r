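Package: synsplit
Title: Gene-Cluster Split Detection and Comparative Genomic Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects rearrangement-driven splits of gene clusters from
    orthologue gene-order tables (synteny breakpoint calling, interposed-block
    measurement), maps cancer-gene density along chromosomes, computes
    co-expression matrices with stencil smoothing and leading-singular-vector
    compartment scores, cross-species expression-divergence statistics,
    region-versus-flank rank tests with eta-squared and Cohen's d effect
    sizes, and maximum-likelihood phylogenetic signal (Pagel's lambda), with a
    synthetic-data generator that plants known rearrangements, expression
    structure, signal shifts and Brownian traits for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    limma,
    igraph,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
biocViews: ComparativeGenomics, Phylogenetics, GeneExpression, Software
RoxygenNote: 7.3.3
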