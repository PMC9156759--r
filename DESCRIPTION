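Package: nichescore
Title: Lineage-Traced Single-Cell Analysis of the Cardiac Vascular Niche
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable, tested building blocks for lineage-traced single-cell
    RNA-seq studies of the cardiac vascular niche: reporter-transcript purity
    filtering on top of standard cell-level quality control, binned-control
    module scoring for extracellular-matrix and other gene signatures,
    meta-cell construction by high-resolution graph clustering with
    score-gene and score-TF-activity correlation, permutation testing of
    cluster composition shifts between conditions, consensus ligand-receptor
    database construction with cluster-pair permutation interaction tests,
    and threshold-gated marker/differential-expression detection. A synthetic
    count-data generator plants every effect the pipeline is designed to
    detect, so each stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
biocViews: SingleCell, Transcriptomics, QualityControl, GeneExpression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
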