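Package: apaviz
Title: Visualizing Alternative Polyadenylation Dynamics from Bulk and
    Single-Cell Poly(A)-Site Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for representing, annotating, quantifying and
    visualizing alternative polyadenylation (APA) from poly(A)-site
    count matrices at bulk or single-cell resolution. Provides a
    unified container coupling site-by-observation counts with site
    and observation metadata, genome-annotation-based assignment of
    poly(A) sites to genomic regions, the RUD (Relative Usage of
    Distal poly(A) site) usage index, rank-sum detection of genes
    with differential APA usage between cell groups, 2D embeddings
    of APA profiles, genome-browser-like track figures, and a
    synthetic-data generator with planted APA shifts for testing
    the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    uwot,
    rlang,
    ggplot2,
    patchwork,
    optparse
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
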