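Package: adarindex
Title: Hotspot-Panel Quantification of A-to-I RNA Editing with Downstream
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Oncotranscriptomics", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rapid quantification of ADAR-mediated A-to-I RNA editing from
    aligned RNA-seq reads using a curated panel of 24 frequently edited exonic
    hotspot sites in 20 genes. Computes a coverage-weighted editing index
    (pooled G/(A+G) ratio) and a mean editing index (arithmetic mean of
    per-site rates over sufficiently covered sites), with optional exclusion
    of panel sites carrying germline A/G (T/C) polymorphisms detected in
    matched whole-exome sequencing. Also provides the downstream analysis
    machinery used with these indices: pathway activation levels from
    activator/repressor-annotated pathway databases, expression-based
    microsatellite-instability scores, tumor mutational burden, a
    retroelement insertional-signature score, and a Spearman
    correlation / Benjamini-Hochberg / set-intersection / permutation
    association framework, plus seed-deterministic synthetic data generators
    for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    methods,
    withr,
    Rsamtools,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
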