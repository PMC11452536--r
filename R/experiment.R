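#' @include AllClasses.R AllGenerics.R synthetic-cohort.R expression-models.R
#' @include evaluation.R valuation.R io.R
NULL

#' Experiment configuration
#'
#' Bundles every setting of a full comparison run; fully serializable, and
#' re-running from a saved configuration reproduces all outputs.
#'
#' @param cohort a [cohortConfig()] list.
#' @param predictor a [predictorSpec()] list.
#' @param nBoot bootstrap replicates for evaluation CIs.
#' @param kNN neighbor counts for cluster recovery.
#' @param kClusters ground-truth cluster count.
#' @param topN genes in the localization-shift analysis.
#' @param topK spatially variable genes retained for modeling (default:
#'   all cohort genes).
#' @param valuation logical; run the Shapley/cost stage.
#' @param nPermutations Monte Carlo permutations (used when the training
#'   slide count exceeds the exact-method guard).
#' @param vEmpty empty-coalition value.
#' @param costModel a [CostModel-class].
#' @param seed master seed.
#' @return a named configuration list.
#' @export
experimentConfig <- function(cohort = cohortConfig(),
                             predictor = predictorSpec(),
                             nBoot = 200L, kNN = c(3L, 5L),
                             kClusters = 5L, topN = 200L, topK = NULL,
                             valuation = TRUE, nPermutations = 200L,
                             vEmpty = 0.5, costModel = defaultCostModel(),
                             seed = 1L) {
  list(cohort = cohort, predictor = predictor, nBoot = as.integer(nBoot),
       kNN = as.integer(kNN), kClusters = as.integer(kClusters),
       topN = as.integer(topN), topK = topK, valuation = valuation,
       nPermutations = as.integer(nPermutations), vEmpty = vEmpty,
       costModel = costModel, seed = as.integer(seed))
}

#' Run the full comparison experiment
#'
#' Executes the study design end to end on a synthetic cohort: generates
#' the cohort, selects spatially variable genes on the validation
#' sections, trains models on each training regime (traditional-only,
#' enhanced-only, both), evaluates every regime on both held-out serial
#' sections (six metric rows), and — unless disabled — values each
#' training slide by data Shapley against each validation slide and
#' compares protocols on cost, value and value-to-cost ratio. Partial
#' stage failures are recorded and the bundle marks incomplete stages.
#'
#' @param config an [experimentConfig()] list.
#' @param outDir optional output directory for [writeReport()] files.
#' @return list with `cohort`, `genes`, `models`, `reports` (named
#'   `regime@validation`), `valuation`, `failures`, and `files`.
#' @export
runExperiment <- function(config = experimentConfig(), outDir = NULL) {
  cfg <- config
  cfg$cohort$seed <- .childSeed(cfg$seed, 1L)
  failures <- character(0)
  cohort <- generateCohort(cfg$cohort)
  train <- cohortSlides(cohort, "train")
  vals <- cohortSlides(cohort, "validation")
  design <- cohortDesign(cohort)
  protoOf <- stats::setNames(design$protocol, design$slide_id)

  # gene universe: spatially variable genes on the validation sections
  topK <- cfg$topK %||% cfg$cohort$genes
  genes <- rankSpatiallyVariable(vals[[1]], topK = topK)

  regimes <- list(
    traditional = train[protoOf[names(train)] == "traditional"],
    enhanced = train[protoOf[names(train)] == "enhanced"],
    both = train)
  regimes <- regimes[vapply(regimes, length, integer(1)) > 0]

  featCache <- lapply(train, featurizeSlide,
                      spec = patchSpec(cfg$predictor$patchPx,
                                       stridePx = cfg$predictor$patchPx))
  valFeat <- lapply(vals, featurizeSlide,
                    spec = patchSpec(cfg$predictor$patchPx,
                                     stridePx = cfg$predictor$patchPx))

  models <- list()
  reports <- list()
  for (rg in names(regimes)) {
    fit <- try(trainGeneModels(regimes[[rg]], geneIds = genes,
                               spec = cfg$predictor,
                               seed = .childSeed(cfg$seed, 10L),
                               features = featCache[names(regimes[[rg]])]),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      failures <- c(failures, sprintf("train:%s", rg))
      next
    }
    models[[rg]] <- fit
    for (vid in names(vals)) {
      key <- paste0(rg, "@", protoOf[[vid]])
      rpt <- try(evaluateModels(fit, vals[[vid]], nBoot = cfg$nBoot,
                                kNN = cfg$kNN, kClusters = cfg$kClusters,
                                topN = cfg$topN,
                                seed = .childSeed(cfg$seed, 20L),
                                features = valFeat[[vid]]),
                 silent = TRUE)
      if (inherits(rpt, "try-error")) {
        failures <- c(failures, sprintf("evaluate:%s", key))
      } else {
        rpt@trainedOn <- rg
        rpt@evaluatedOn <- protoOf[[vid]]
        reports[[key]] <- rpt
      }
    }
  }

  valuation <- NULL
  if (isTRUE(cfg$valuation)) {
    method <- if (length(train) <= 10L) "exact" else "monte_carlo"
    valuation <- try(valuateCohort(cohort, spec = cfg$predictor,
                                   costModel = cfg$costModel,
                                   method = method,
                                   nPermutations = cfg$nPermutations,
                                   seed = .childSeed(cfg$seed, 30L),
                                   vEmpty = cfg$vEmpty),
                     silent = TRUE)
    if (inherits(valuation, "try-error")) {
      failures <- c(failures, "valuation")
      valuation <- NULL
    }
  }

  files <- character(0)
  if (!is.null(outDir)) {
    files <- writeReport(reports, valuation, dir = outDir)
  }
  list(cohort = cohort, genes = genes, models = models, reports = reports,
       valuation = valuation, failures = failures, files = files,
       config = cfg)
}
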