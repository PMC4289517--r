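Package: metabodrift
Title: Simulation, QC-RLSC Drift Correction and Consensus Feature
    Selection for Multi-Batch Metabolomics Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for large multi-batch chromatography-mass-spectrometry
    metabolomics studies that rely on pooled quality-control (QC) samples.
    Simulates raw peak-area studies with injection-order drift, between-batch
    sensitivity steps, pooled-QC technical noise, planted covariate effects
    and detection-limit missingness; corrects drift by quality-control-based
    robust LOESS signal correction (QC-RLSC) with cubic-spline interpolation;
    integrates batches and applies relative-standard-deviation, presence and
    biological-information filters; and provides the downstream statistics
    used in population metabolic phenotyping: mean imputation and autoscaling,
    rank-based univariate screens, two-way ANOVA with Tukey HSD, correlation
    heatmap ordering, bootstrap consensus feature selection with Borda-count
    aggregation and forward-selection remodeling, and empirical sample-size
    assessment of classifier accuracy and ranking consistency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    car,
    randomForest,
    e1071,
    mixOmics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pheatmap
Config/testthat/edition: 3
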