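Package: SpotShapley
Title: Data-Shapley Valuation of Training Slides for Spatial
    Transcriptomics Inference from Histology
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools to study how slide preparation and imaging quality
    affect models that infer Visium spot-level gene expression from
    tissue morphology. Provides a seeded synthetic-cohort generator
    (hexagonal Visium spot grids, spatially structured negative-binomial
    counts over latent tissue programs, paired serial sections, and
    protocol-dependent image quality), spot-centered patch extraction
    and superresolution inference grids, pluggable per-gene predictors
    with a deterministic hand-crafted-feature backend, a four-part
    evaluation suite (per-gene AUC/Spearman with spot bootstrap,
    k-NN cluster recovery on aligned embeddings, Mann-Whitney
    differential-expression localization), and slide-level data-Shapley
    valuation (exact and Monte Carlo) compared against per-slide assay
    costs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Spatial, Transcriptomics, GeneExpressionWorkflow
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'spot-geometry.R'
    'synthetic-cohort.R'
    'expression-models.R'
    'evaluation.R'
    'io.R'
    'valuation.R'
    'experiment.R'
    'utils.R'
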