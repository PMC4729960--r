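Package: spatialmap
Title: Spatial Proteomics Mapping from Isobaric-Tag Fractionation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete analysis pipeline for LOPIT-style spatial proteomics
    experiments. Peptide-spectrum-match (PSM) level TMT reporter tables are
    filtered with a missing-value rule, aggregated to protein groups by the
    median, row-normalized to relative abundances, and replicate experiments
    are fused by row intersection into a higher-plex profile matrix.
    Unlabelled proteins are screened for novel phenotype clusters with a
    semi-supervised Gaussian novelty-detection loop, then classified to
    subcellular compartments with a class-weighted radial-kernel support
    vector machine tuned by repeated stratified nested cross-validation, with
    per-class score thresholds calibrated against independent annotation to a
    target false discovery rate. Quantitative-performance metrics
    (enrichment ratios, distances to organelle median profiles, rank-sum
    comparisons, replicate concordance), PCA map rendering with marker and
    protein-set overlays, and a parametric simulator of fractionation
    profiles with noise, missingness, mixed localization and reporter-ion
    interference complete the toolkit.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    e1071,
    mclust,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
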