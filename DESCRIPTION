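Package: immunoConcord
Title: Cross-Platform Concordance of Targeted Immune Panel and RNA-Seq
    Expression for Tumor Immune Microenvironment Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare targeted hybridization-based immune gene
    expression panels (nCounter-style, with endogenous, housekeeping,
    negative-control and positive-control probes) against bulk RNA
    sequencing on paired samples. Implements negative-control
    detection-limit thresholding, geNorm housekeeping stability ranking
    and selection, housekeeping geometric-mean normalization, gene-length
    corrected TMM (geTMM) normalization of RNA-seq counts, cross-platform
    gene matching through HGNC symbols, per-sample and per-gene
    concordance statistics with expression binning, detection
    cross-tabulation, and marker-gene immune cell scoring including a
    fixed-signature scorer. A seeded synthetic paired-cohort generator
    with known ground truth (planted stable housekeeping genes,
    infiltration-driven marker co-expression, expression-dependent noise
    and platform-specific dropout) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, Normalization, QualityControl, Transcriptomics,
    ImmunoOncology
RoxygenNote: 7.3.3
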