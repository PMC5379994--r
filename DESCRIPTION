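Package: SpeckleQuant
Title: High-Throughput 3D Quantification of Nuclear Foci and Nuclear
    Accumulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An automated image-analysis pipeline for counting and measuring
    intranuclear foci (such as paraspeckles) in multi-channel 3D confocal
    stacks. Detects cell bodies, nuclei and nuclear foci by intensity
    thresholding, connected components and seeded 3D watershed, links the
    three object classes hierarchically, applies edge-nucleus and
    transfection-gating filters, and computes per-cell nuclear-to-cytoplasmic
    intensity ratios (F_n/c) together with per-focus volume and intensity
    features. A statistical layer estimates group geometric means and
    geometric-mean ratios on the log scale, odds ratios for foci positivity,
    generalized estimating equations for per-focus outcomes clustered within
    cells, Bonferroni-adjusted significance thresholds, per-cell correlations
    and PCA group summaries. A synthetic-stack generator with voxel-level
    ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Software
RoxygenNote: 7.3.3
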