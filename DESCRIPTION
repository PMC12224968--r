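Package: sccorpus
Title: Staged Curation of Single-Cell Count Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for turning heterogeneous single-cell RNA-seq count
    matrices into a curated, analysis- and model-ready corpus: a staged
    quality-control cascade with full attrition accounting, pseudo-bulk
    aggregation and FPKM conversion, expression-based sex inference from
    X/Y chromosome ratios, identification of stable-expression genes
    (zero-rate and coefficient-of-variation ranking) and organ-specific
    genes, clustering-based gene-set evaluation, and deterministic
    rank/median encoding for transcriptome foundation models. Includes a
    synthetic-corpus generator with planted ground truth so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    cluster,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
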