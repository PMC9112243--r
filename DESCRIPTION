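Package: matcare
Title: Maternal-Care Phenotyping Pipeline: Pup Retrieval, Ultrasonic
    Vocalizations, Dendritic Morphometry, VTA Single-Unit and Marker
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tested analysis chain for maternal-immune-activation (Poly I:C)
    experiments in mouse dams: behavioral scoring of the pup retrieval assay
    (cumulative retrieval, latency, relative failure index, windowed rearing
    and sniff counts), ultrasonic-vocalization call metrics and six-way call
    classification from frequency contours, dendritic morphometry from SWC
    reconstructions (Sholl profiles at 20-micron shells, cumulative length,
    branch points, spine typing), single-unit spike-train analysis (firing
    rate, full action-potential width, narrow/wide/fast unit classification,
    burst detection, epoch-aligned firing-rate change), marker-fraction
    quantification for c-Fos histochemistry, cluster-level expression
    dot-plot summaries, and the accompanying statistical layer (exact
    Mann-Whitney, Welch t, exact Spearman, Type-II two-way ANOVA, split-plot
    mixed ANOVA, Grubbs outlier screening). A synthetic-data module
    generates every input with known ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    SummarizedExperiment,
    SingleCellExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
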