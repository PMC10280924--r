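Package: cernets
Title: Competing Endogenous RNA Network Inference from circRNA, miRNA and
    mRNA Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring circRNA-miRNA-mRNA competing endogenous RNA
    (ceRNA) networks from matched expression profiles. Covers genomic
    classification of back-splice junctions against a reference annotation
    with summary statistics (category proportions, N50 and length summaries,
    per-chromosome and per-sample counts), library-size normalization
    (RPM/CPM/FPKM) with threshold-based differential-expression screening,
    directional Pearson correlation filtering with exact t-distribution
    p-values, deterministic seed-and-extend prediction of miRNA response
    elements, hypergeometric shared-miRNA ceRNA scoring, evidence
    intersection, direction-coherent network assembly with
    Cytoscape-compatible export, and term over-representation analysis.
    Includes a negative-binomial synthetic-data generator with planted
    ground truth for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    BiocGenerics,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
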