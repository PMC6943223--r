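Package: difnet
Title: Differential Expression and Differential Co-Expression Network
    Analysis for Two-Condition RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for nominating condition-specific regulatory
    programs from a two-condition replicated RNA-seq count matrix:
    negative-binomial differential-expression screening with median-of-ratios
    normalization and an exact conditional test, direction-split Fisher
    gene-set enrichment, typed interaction-network construction from
    KEGG-style relation tables, and differential co-expression hub detection
    via per-condition degree and k-core differences (DifDegree/DifKcore).
    Includes a synthetic-data generator that plants differentially expressed
    genes, enriched gene sets, and condition-specific co-expression modules
    with known ground truth, so every stage is verifiable offline.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
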