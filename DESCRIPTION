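Package: cargoHCS
Title: Arrayed High-Content CRISPR Screen Analysis of Dynein Cargo Localisation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of arrayed CRISPR/Cas9 high-content
    imaging screens that read out minus-end-directed (dynein) cargo
    trafficking. Provides a synthetic screen generator with planted gene
    effects (384-well plate layouts, per-cell nuclear morphology and
    radial spot distributions, rendered fluorescence fields), image
    analysis (nucleus and cytoplasm segmentation, viability gating,
    difference-of-Gaussians spot detection, perinuclear ring compartments
    and localisation ratios, MTOC and micronucleus counting), robust-Z
    plate normalisation with robust Z-prime assay-window QC and LDA
    composite endpoints, threshold-based hit calling with prefilters and
    multi-cargo categorisation, and phenotypic fingerprinting (variability
    and redundancy feature filters, min-max scaling, hierarchical
    clustering with correlation distance, UMAP embedding, and cluster
    recovery diagnostics).
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
    EBImage,
    data.table,
    jsonlite,
    yaml,
    uwot,
    matrixStats
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS,
    ape,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
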