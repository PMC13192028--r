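Package: mtlineage
Title: Single-Cell Mitochondrial DNA Lineage Tracing and Clonal Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing B cell clones with single-cell mitochondrial
    DNA (mtDNA) mutations. Calls high-confidence mtDNA variants from per-cell
    per-strand base counts with cell-count, variance-to-mean-ratio and
    strand-concordance filters; computes per-cell heteroplasmy matrices and
    normalized mutation burdens; assigns cells to mtDNA-defined clonotypes
    and quantifies their stability under downsampling; detects mean- and
    distribution-level heteroplasmy shifts between paired samples
    (Wilcoxon and Kolmogorov-Smirnov screens with Benjamini-Hochberg
    correction, quantile-quantile curves); classifies compartment
    enrichment of variants; infers copy-number changes from chromatin
    fragments in overlapping genome bins against a reference population;
    builds neighbor-joining clone trees; and scores concordance between
    mtDNA clones and B cell receptor clonotypes. A ground-truthed
    synthetic-data generator emulating clonal populations with
    beta-binomial heteroplasmy dispersion makes the whole pipeline
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    ape,
    igraph,
    jsonlite,
    mclust,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
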