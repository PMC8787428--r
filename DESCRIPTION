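Package: phosflow
Title: Downstream Phosphoproteomics Analysis Pipeline
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated downstream analysis of mass-spectrometry phosphoproteomics
    data, from a phosphosite intensity table to biological interpretation.
    Parses MaxQuant 'Phospho (STY)Sites' tables and generic site tables,
    performs missingness filtering, median or quantile normalization and
    low-rank matrix-completion imputation, data-overview clustering and PCA,
    differential analysis with t, Wilcoxon, reproducibility-optimized
    (ROTS-style) and rank product statistics plus multi-group ANOVA/Tukey,
    cross-species phosphosite coordinate mapping via global pairwise alignment,
    kinase activity inference from position weight matrices with permutation
    swing scores, protein-level over-representation and site-level signed
    signature enrichment with GCT v1.3 I/O, and interaction-network hub
    permutation tests. Includes a synthetic-data generator for every input
    format and a config-driven pipeline reproducing a standard output folder
    layout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    limma,
    igraph,
    fgsea,
    yaml,
    ggplot2,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
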