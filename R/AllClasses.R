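#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

# ---------------------------------------------------------------------------
# Spot geometry
# ---------------------------------------------------------------------------

#' SpotGrid: a Visium-style spot lattice
#'
#' Holds barcoded spot centers on a hexagonal-offset lattice together with
#' the physical geometry that produced them. Array coordinates are 0-based
#' lattice indices; pixel coordinates follow the 0-based, row-major,
#' pixel-center convention and are derived from physical micron positions by
#' division with `resolutionUmPerPx`.
#'
#' @slot barcode unique spot identifiers.
#' @slot arrayRow,arrayCol integer lattice coordinates (0-based).
#' @slot pxlRow,pxlCol pixel coordinates of spot centers.
#' @slot spotDiameterUm spot diameter in microns (Visium: 55).
#' @slot pitchUm center-to-center distance in microns (Visium: 100).
#' @slot resolutionUmPerPx image resolution in microns per pixel.
#' @exportClass SpotGrid
setClass("SpotGrid",
  representation(
    barcode = "character",
    arrayRow = "integer",
    arrayCol = "integer",
    pxlRow = "numeric",
    pxlCol = "numeric",
    spotDiameterUm = "numeric",
    pitchUm = "numeric",
    resolutionUmPerPx = "numeric"
  )
)

setValidity("SpotGrid", function(object) {
  n <- length(object@barcode)
  msg <- character()
  if (anyDuplicated(object@barcode)) msg <- c(msg, "barcodes must be unique")
  lens <- c(length(object@arrayRow), length(object@arrayCol),
            length(object@pxlRow), length(object@pxlCol))
  if (any(lens != n)) msg <- c(msg, "coordinate slots must match barcode length")
  if (n > 0 && (any(object@pxlRow < 0) || any(object@pxlCol < 0))) {
    msg <- c(msg, "pixel coordinates must be nonnegative")
  }
  if (object@spotDiameterUm <= 0 || object@pitchUm <= 0 ||
      object@resolutionUmPerPx <= 0) {
    msg <- c(msg, "geometry parameters must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' PatchSpec: patch extraction geometry
#'
#' @slot patchPx side length of square patches in pixels.
#' @slot stridePx increment between window origins for superresolution
#'   inference.
#' @slot magnification magnification label; `"40x"` corresponds to
#'   0.25 um/px and `"20x"` to 0.5 um/px.
#' @exportClass PatchSpec
setClass("PatchSpec",
  representation(patchPx = "integer", stridePx = "integer",
                 magnification = "character"),
  prototype(patchPx = 512L, stridePx = 128L, magnification = "40x")
)

setValidity("PatchSpec", function(object) {
  msg <- character()
  if (object@patchPx <= 0L) msg <- c(msg, "patchPx must be positive")
  if (object@stridePx < 1L || object@stridePx > object@patchPx) {
    msg <- c(msg, "stridePx must lie in [1, patchPx]")
  }
  if (!object@magnification %in% c("20x", "40x")) {
    msg <- c(msg, "magnification must be '20x' or '40x'")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Synthetic cohort
# ---------------------------------------------------------------------------

#' ProtocolProfile: image-quality regime of a slide-preparation protocol
#'
#' Encodes the contrast between a traditional workflow (manual staining,
#' low-resolution scanning) and an enhanced one (automated staining,
#' high-resolution clinical-grade scanning) as a small set of rendering
#' parameters used by the synthetic patch generator.
#'
#' @slot name `"traditional"` or `"enhanced"`.
#' @slot resolutionUmPerPx microns per rendered pixel.
#' @slot stainVariability scale of the per-slide random channel shift.
#' @slot pixelNoiseSd scale of additive rendering noise.
#' @slot signalGain fraction in (0, 1] of the latent signal encoded into
#'   pixel statistics.
#' @slot artifactRate per-spot probability of an occluding artifact block.
#' @exportClass ProtocolProfile
setClass("ProtocolProfile",
  representation(
    name = "character",
    resolutionUmPerPx = "numeric",
    stainVariability = "numeric",
    pixelNoiseSd = "numeric",
    signalGain = "numeric",
    artifactRate = "numeric"
  )
)

setValidity("ProtocolProfile", function(object) {
  msg <- character()
  if (!object@name %in% c("traditional", "enhanced")) {
    msg <- c(msg, "name must be 'traditional' or 'enhanced'")
  }
  if (object@resolutionUmPerPx <= 0) msg <- c(msg, "resolutionUmPerPx must be > 0")
  if (object@stainVariability < 0) msg <- c(msg, "stainVariability must be >= 0")
  if (object@pixelNoiseSd < 0) msg <- c(msg, "pixelNoiseSd must be >= 0")
  if (object@signalGain <= 0 || object@signalGain > 1) {
    msg <- c(msg, "signalGain must lie in (0, 1]")
  }
  if (object@artifactRate < 0 || object@artifactRate > 1) {
    msg <- c(msg, "artifactRate must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' TissueField: latent tissue structure behind a synthetic slide
#'
#' @slot region per-spot region label in \{tumor, interface, distal\}.
#' @slot loadings spots x P matrix of latent program activities.
#' @slot geneWeights P x G matrix mapping programs to genes.
#' @exportClass TissueField
setClass("TissueField",
  representation(region = "character", loadings = "matrix",
                 geneWeights = "matrix")
)

setValidity("TissueField", function(object) {
  msg <- character()
  if (length(object@region) != nrow(object@loadings)) {
    msg <- c(msg, "one region label per spot is required")
  }
  if (!all(object@region %in% c("tumor", "interface", "distal"))) {
    msg <- c(msg, "region labels must be tumor/interface/distal")
  }
  if (ncol(object@loadings) != nrow(object@geneWeights)) {
    msg <- c(msg, "loadings and geneWeights disagree on program count")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticImageSource: procedural patch renderer for a synthetic slide
#'
#' Patches are rendered on demand from the latent tissue field through the
#' protocol's encoding; nothing is rasterized up front.
#'
#' @slot field the [TissueField-class] being imaged.
#' @slot profile the [ProtocolProfile-class] governing image quality.
#' @slot stainShift per-channel additive stain shift of this slide.
#' @slot seed base seed; per-spot render seeds derive from it.
#' @slot nChannels number of image channels.
#' @exportClass SyntheticImageSource
setClass("SyntheticImageSource",
  representation(field = "TissueField", profile = "ProtocolProfile",
                 stainShift = "numeric", seed = "integer",
                 nChannels = "integer")
)

#' RasterImageSource: an in-memory raster image
#'
#' @slot image h x w x channels array with values in [0, 1].
#' @exportClass RasterImageSource
setClass("RasterImageSource", representation(image = "array"))

setClassUnion("ImageSourceOrNULL",
              c("SyntheticImageSource", "RasterImageSource", "NULL"))
setClassUnion("TissueFieldOrNULL", c("TissueField", "NULL"))

#' Slide: one capture area with expression, geometry and provenance
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with genes as rows
#' and spots as columns (`counts` assay). `colData` carries per-spot region
#' and patient annotations; geometry lives in the [SpotGrid-class] slot and
#' morphology in the image source.
#'
#' @slot spotGrid the slide's [SpotGrid-class].
#' @slot protocol the [ProtocolProfile-class] used to image the slide.
#' @slot imageSource patch source (procedural or raster), or NULL.
#' @slot field the generating [TissueField-class] for synthetic slides.
#' @slot slideId slide identifier.
#' @slot role `"train"` or `"validation"`.
#' @exportClass Slide
setClass("Slide",
  contains = "SummarizedExperiment",
  representation(
    spotGrid = "SpotGrid",
    protocol = "ProtocolProfile",
    imageSource = "ImageSourceOrNULL",
    field = "TissueFieldOrNULL",
    slideId = "character",
    role = "character"
  )
)

setValidity("Slide", function(object) {
  msg <- character()
  if (ncol(object) != length(object@spotGrid@barcode)) {
    msg <- c(msg, "spot grid size must equal the number of columns")
  } else if (!identical(colnames(object), object@spotGrid@barcode)) {
    msg <- c(msg, "column names must equal the grid barcodes, in order")
  }
  if (length(msg)) msg else TRUE
})

#' Cohort: a set of slides plus the design that produced them
#'
#' @slot slides named list of [Slide-class] objects.
#' @slot design data.frame describing capture areas, protocols, roles and
#'   patients (one row per capture area).
#' @slot config the generating configuration list.
#' @exportClass Cohort
setClass("Cohort",
  representation(slides = "list", design = "data.frame", config = "list")
)

# ---------------------------------------------------------------------------
# Models
# ---------------------------------------------------------------------------

#' GeneTargets: binary and continuous prediction targets
#'
#' @slot geneIds gene identifiers.
#' @slot continuous spots x G matrix of log1p-transformed counts.
#' @slot binary spots x G 0/1 matrix from per-gene median dichotomization
#'   (strictly-greater-than-median rule; ties at the median are class 0).
#' @exportClass GeneTargets
setClass("GeneTargets",
  representation(geneIds = "character", continuous = "matrix",
                 binary = "matrix")
)

setValidity("GeneTargets", function(object) {
  msg <- character()
  if (!identical(dim(object@continuous), dim(object@binary))) {
    msg <- c(msg, "continuous and binary targets must share dimensions")
  }
  if (ncol(object@continuous) != length(object@geneIds)) {
    msg <- c(msg, "one gene id per target column is required")
  }
  if (length(msg)) msg else TRUE
})

#' GeneModelSet: per-gene predictors over patch features
#'
#' Records everything needed for exact re-inference: the featurizer
#' identity, the patch spec, the training slide ids, and per-gene
#' coefficient vectors for the continuous (ridge, mean-squared error on
#' log counts) and binary (ridge-penalized logistic) heads.
#'
#' @slot geneIds gene identifiers.
#' @slot contCoefs (p+1) x G coefficient matrix, intercept first.
#' @slot binCoefs (p+1) x G coefficient matrix for the logistic head;
#'   untrainable genes carry NA columns.
#' @slot excludedGenes genes whose binary head was untrainable (single
#'   class), excluded from macro binary metrics.
#' @slot featurizer featurizer identifier.
#' @slot patchSpec the [PatchSpec-class] patches were taken under.
#' @slot trainSlideIds slides the models were fit on.
#' @slot lambda selected ridge penalties, named by head.
#' @slot trainFitted fitted continuous values and binary scores on the
#'   training spots, for re-inference checks.
#' @slot seed training seed.
#' @exportClass GeneModelSet
setClass("GeneModelSet",
  representation(
    geneIds = "character",
    contCoefs = "matrix",
    binCoefs = "matrix",
    excludedGenes = "character",
    featurizer = "character",
    patchSpec = "PatchSpec",
    trainSlideIds = "character",
    lambda = "numeric",
    trainFitted = "list",
    seed = "integer"
  )
)

# ---------------------------------------------------------------------------
# Evaluation
# ---------------------------------------------------------------------------

#' EvalReport: the four-part evaluation of one model set on one slide
#'
#' @slot perGeneAuc,perGeneSpearman named per-gene metric vectors.
#' @slot macro list with mean/median macro values and their bootstrap 95%
#'   confidence intervals for both metrics.
#' @slot recovery named vector of k-NN cluster recovery proportions per k.
#' @slot deShift list with the median percentage change in Mann-Whitney U
#'   localization statistics and its bootstrap CI.
#' @slot nBootstrap bootstrap replicate count used.
#' @slot excludedGenes named character vector of excluded genes (names) and
#'   reasons (values).
#' @slot trainedOn,evaluatedOn labels for the comparison design.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(
    perGeneAuc = "numeric",
    perGeneSpearman = "numeric",
    macro = "list",
    recovery = "numeric",
    deShift = "list",
    nBootstrap = "integer",
    excludedGenes = "character",
    trainedOn = "character",
    evaluatedOn = "character"
  )
)

# ---------------------------------------------------------------------------
# Valuation
# ---------------------------------------------------------------------------

#' ValueFunction: memoized coalition value V(S) for slide subsets
#'
#' `V(S)` is the validation-slide macro AUC of models trained on subset S;
#' the empty coalition takes the chance-level value `vEmpty`.
#'
#' @slot slideIds the training-slide player set.
#' @slot fn function taking a character vector of slide ids, returning V.
#' @slot vEmpty value of the empty coalition (default 0.5, chance AUC).
#' @slot memo environment caching subset values by sorted-id key.
#' @slot meta provenance list (validation slide, metric, predictor spec).
#' @exportClass ValueFunction
setClass("ValueFunction",
  representation(slideIds = "character", fn = "function", vEmpty = "numeric",
                 memo = "environment", meta = "list")
)

#' ShapleyEstimate: per-slide data-Shapley values
#'
#' @slot phi named per-slide Shapley values.
#' @slot se Monte Carlo standard errors (0 for the exact method).
#' @slot nPermutations permutations used (NA for exact).
#' @slot converged convergence flag.
#' @slot method `"exact"` or `"monte_carlo"`.
#' @slot vEmpty,vFull coalition values of the empty and full sets.
#' @exportClass ShapleyEstimate
setClass("ShapleyEstimate",
  representation(phi = "numeric", se = "numeric", nPermutations = "integer",
                 converged = "logical", method = "character",
                 vEmpty = "numeric", vFull = "numeric")
)

setValidity("ShapleyEstimate", function(object) {
  msg <- character()
  if (length(object@phi) != length(object@se)) {
    msg <- c(msg, "phi and se must have equal length")
  }
  if (any(object@se < 0)) msg <- c(msg, "standard errors must be nonnegative")
  if (!object@method %in% c("exact", "monte_carlo")) {
    msg <- c(msg, "method must be 'exact' or 'monte_carlo'")
  }
  if (length(msg)) msg else TRUE
})

#' CostModel: per-slide assay cost decomposition
#'
#' Slide cost = base(protocol) + perSpot * detected spots + labor(protocol)
#' + sequencing(protocol). Defaults are synthetic placeholders chosen so
#' that a traditional capture area (manual staining, one patient) costs
#' more than an enhanced one (automated staining amortized over two
#' patients); every cost-dependent output labels the model used.
#'
#' @slot baseCost named numeric, base reagent cost per protocol.
#' @slot perSpot cost per detected spot (sequencing depth scales with
#'   spot count).
#' @slot labor named numeric, labor cost per protocol.
#' @slot sequencing named numeric, fixed sequencing cost per protocol.
#' @slot label free-text label identifying the cost model.
#' @exportClass CostModel
setClass("CostModel",
  representation(baseCost = "numeric", perSpot = "numeric",
                 labor = "numeric", sequencing = "numeric",
                 label = "character")
)

setValidity("CostModel", function(object) {
  msg <- character()
  vals <- c(object@baseCost, object@perSpot, object@labor, object@sequencing)
  if (any(vals < 0)) msg <- c(msg, "all cost components must be >= 0")
  for (s in c("baseCost", "labor", "sequencing")) {
    if (!all(c("traditional", "enhanced") %in% names(slot(object, s)))) {
      msg <- c(msg, sprintf("'%s' must be named for both protocols", s))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ValuationResult: per-slide Shapley values, costs and group comparisons
#'
#' @slot table per-slide data.frame with slide id, protocol, validation
#'   slide, phi, Monte Carlo SE, cost, and phi/cost ratio.
#' @slot estimates list of [ShapleyEstimate-class], one per validation
#'   slide.
#' @slot costModel the [CostModel-class] used.
#' @slot comparisons data.frame of Mann-Whitney group comparisons (U,
#'   rank-biserial r, two-sided p) between protocols.
#' @exportClass ValuationResult
setClass("ValuationResult",
  representation(table = "data.frame", estimates = "list",
                 costModel = "CostModel", comparisons = "data.frame")
)
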