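#' @include AllClasses.R AllGenerics.R expression-models.R
NULL

# ---------------------------------------------------------------------------
# Core metrics
# ---------------------------------------------------------------------------

#' Rank-based AUC
#'
#' Area under the ROC curve computed from average ranks with midrank tie
#' handling, equal to P(score1 > score0) + 0.5 P(tie) and to
#' U / (n1 * n0) for the corresponding Mann-Whitney statistic.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores numeric scores.
#' @return AUC in [0, 1], or NA (with a warning) for single-class labels.
#' @examples
#' aucScore(c(0, 0, 1, 1), c(.1, .2, .8, .9))  # 1
#' @export
aucScore <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("single-class labels: AUC undefined, returning NA")
    return(NA_real_)
  }
  r <- .midrank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (midranks under ties).
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in [-1, 1]; NA when either input has zero rank
#'   variance.
#' @export
spearmanScore <- function(x, y) {
  stopifnot(length(x) == length(y))
  rx <- .midrank(x); ry <- .midrank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Mann-Whitney U test
#'
#' `U` counts pairs where x exceeds y plus half the ties, computed via
#' midranks. The two-sided p-value is exact (null permutation
#' distribution) when `min(n1, n2) <= exactMax` and the data are tie-free,
#' and otherwise uses the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric samples.
#' @param exactMax largest group-size minimum for which the exact null is
#'   used (default 8).
#' @return list with `U` (of x over y), `p` (two-sided), and `exact` flag.
#' @examples
#' mannWhitneyU(c(4, 5, 6), c(1, 2, 3))$U  # 9
#' @export
mannWhitneyU <- function(x, y, exactMax = 8L) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  all <- c(x, y)
  r <- .midrank(all)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(all) > 0L
  if (!ties && min(n1, n2) <= exactMax) {
    # exact two-sided p from the Wilcoxon null distribution
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        1 - stats::pwilcox(U - 1, n1, n2)))
    return(list(U = U, p = p, exact = TRUE))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  tieTab <- table(all)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tieTab^3 - tieTab) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, exact = FALSE))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = 2 * stats::pnorm(-abs(z)), exact = FALSE)
}

# ---------------------------------------------------------------------------
# Macro metrics with spot bootstrap
# ---------------------------------------------------------------------------

.perGeneMetric <- function(metric, truth, pred) {
  vapply(seq_len(ncol(truth)), function(g) {
    if (metric == "auc") {
      lab <- truth[, g]
      if (length(unique(lab)) < 2L) return(NA_real_)
      suppressWarnings(aucScore(lab, pred[, g]))
    } else {
      spearmanScore(truth[, g], pred[, g])
    }
  }, numeric(1))
}

#' Macro-averaged metric with spot-bootstrap confidence interval
#'
#' Computes the per-gene metric, macro-averages it over genes (both the
#' mean and, as also reported in the study design, the median), and
#' derives 95% confidence intervals from a non-parametric bootstrap over
#' spots: spots are resampled with replacement, the macro value is
#' recomputed per replicate, and the 2.5/97.5 percentiles are reported.
#' Genes degenerate in a replicate (single-class labels or zero rank
#' variance) are skipped in that replicate.
#'
#' @param metric `"auc"` or `"spearman"`.
#' @param truth spots x G matrix: 0/1 labels for AUC, continuous values
#'   for Spearman.
#' @param pred spots x G prediction matrix.
#' @param nBoot bootstrap replicate count (>= 1; the study uses 1000).
#' @param seed integer seed.
#' @return list with `perGene`, `macroMean`, `macroMedian`, `ciMean`,
#'   `ciMedian` (2-vectors), and `nBoot`.
#' @export
macroWithBootstrap <- function(metric = c("auc", "spearman"), truth, pred,
                               nBoot = 1000L, seed = 1L) {
  metric <- match.arg(metric)
  nBoot <- .assertCount(nBoot, "nBoot")
  stopifnot(identical(dim(truth), dim(pred)))
  perGene <- .perGeneMetric(metric, truth, pred)
  names(perGene) <- colnames(truth)
  n <- nrow(truth)
  reps <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      ix <- sample.int(n, n, replace = TRUE)
      v <- .perGeneMetric(metric, truth[ix, , drop = FALSE],
                          pred[ix, , drop = FALSE])
      c(mean(v, na.rm = TRUE), stats::median(v, na.rm = TRUE))
    }, numeric(2))
  })
  ci <- function(v) unname(stats::quantile(v, c(0.025, 0.975), na.rm = TRUE))
  list(perGene = perGene,
       macroMean = mean(perGene, na.rm = TRUE),
       macroMedian = stats::median(perGene, na.rm = TRUE),
       ciMean = ci(reps[1, ]), ciMedian = ci(reps[2, ]),
       nBoot = nBoot)
}

# ---------------------------------------------------------------------------
# Clustering fidelity
# ---------------------------------------------------------------------------

.logNormalize <- function(expr) {
  # count-like (nonnegative) input: library-size normalize and log1p;
  # input with negative entries is treated as already transformed
  if (any(expr < 0)) return(expr)
  libs <- rowSums(expr)
  libs[libs == 0] <- 1
  log1p(expr / libs * stats::median(libs))
}

#' Ground-truth expression clusters
#'
#' k-means (seeded, 10 restarts) on the top principal components (default
#' 20) of log-normalized expression. The clustering algorithm is a design
#' choice of this package; `k` is configurable.
#'
#' @param expr spots x G expression matrix (counts or continuous values).
#' @param kClusters number of clusters.
#' @param seed integer seed.
#' @param nPCs number of principal components.
#' @return integer cluster label per spot.
#' @export
clusterGroundTruth <- function(expr, kClusters = 5L, seed = 1L, nPCs = 20L) {
  kClusters <- .assertCount(kClusters, "kClusters")
  emb <- .pcaEmbed(.logNormalize(expr), nPCs)$scores
  if (kClusters == 1L) return(rep(1L, nrow(emb)))
  .withSeed(seed, stats::kmeans(emb, centers = kClusters,
                                nstart = 10L, iter.max = 50L)$cluster)
}

.pcaEmbed <- function(X, nPCs) {
  nPCs <- min(nPCs, ncol(X), nrow(X) - 1L)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = nPCs)
  list(scores = pc$x, rotation = pc$rotation, center = pc$center)
}

# default joint-embedding backend: principal-component basis fit on truth,
# applied to both matrices (deterministic and alignment-free)
.pcaBackend <- function(truthExpr, predExpr, nPCs = 20L) {
  fit <- .pcaEmbed(truthExpr, nPCs)
  project <- function(M) sweep(M, 2, fit$center) %*% fit$rotation
  list(truth = fit$scores, pred = project(predExpr))
}

#' k-NN cluster recovery of predicted expression
#'
#' Embeds ground-truth and predicted spots in one space (default backend:
#' principal-component basis fit on truth, applied to both; any function
#' `(truthExpr, predExpr) -> list(truth=, pred=)`, e.g. an aligned-UMAP
#' wrapper, can be plugged in). A k-NN classifier over the truth
#' embeddings and their cluster labels then assigns each predicted spot a
#' cluster; recovery is the fraction matching the spot's own truth
#' cluster. Votes are inverse-distance weighted, so a predicted spot
#' coinciding exactly with its truth spot recovers that spot's label.
#'
#' @param truthExpr,predExpr spots x G matrices, rows paired one-to-one.
#' @param truthClusters cluster label per truth spot.
#' @param kNN neighbor count (e.g. 3 or 5).
#' @param embedBackend embedding function, default PCA-on-truth.
#' @return recovery proportion in [0, 1].
#' @export
knnClusterRecovery <- function(truthExpr, predExpr, truthClusters,
                               kNN = 3L, embedBackend = .pcaBackend) {
  kNN <- .assertCount(kNN, "kNN")
  n <- nrow(truthExpr)
  stopifnot(nrow(predExpr) == n, length(truthClusters) == n)
  if (kNN > n) stop("kNN exceeds the number of spots", call. = FALSE)
  emb <- embedBackend(truthExpr, predExpr)
  assigned <- integer(n)
  labs <- as.integer(factor(truthClusters))
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(emb$truth) - emb$pred[i, ])^2))
    nb <- order(d)[seq_len(kNN)]
    w <- 1 / (d[nb] + 1e-12)
    votes <- tapply(w, labs[nb], sum)
    assigned[i] <- as.integer(names(votes)[which.max(votes)])
  }
  mean(assigned == labs)
}

# ---------------------------------------------------------------------------
# Differential-expression localization
# ---------------------------------------------------------------------------

#' Localization shift of differential expression at the tumor interface
#'
#' For each of the `topN` genes best predicted by Spearman correlation,
#' the Mann-Whitney U statistic contrasting interface spots against all
#' other regions (treating expression as continuous) is computed on the
#' true and on the predicted expression; the per-gene percentage change
#' `100 * (U_pred - U_truth) / U_truth` is summarized as its median over
#' genes with a spot-bootstrap 95% CI. Genes with `U_truth = 0` are
#' excluded with a recorded reason.
#'
#' @param truth,pred spots x G continuous expression matrices.
#' @param regions per-spot labels including `"interface"` and at least one
#'   other level.
#' @param perGeneSpearman named per-gene Spearman values ranking the genes.
#' @param topN number of top genes to examine (the study uses 200).
#' @param nBoot bootstrap replicates for the CI.
#' @param seed integer seed.
#' @return list with `medianPct`, `ci`, per-gene `pct`, `genes`, and
#'   `excluded`.
#' @export
deLocalizationShift <- function(truth, pred, regions, perGeneSpearman,
                                topN = 200L, nBoot = 1000L, seed = 1L) {
  stopifnot(identical(dim(truth), dim(pred)))
  if (!"interface" %in% regions || length(unique(regions)) < 2L) {
    stop("regions must include 'interface' and at least one other label",
         call. = FALSE)
  }
  genes <- names(sort(perGeneSpearman, decreasing = TRUE))
  genes <- genes[seq_len(min(topN, length(genes)))]
  inIface <- regions == "interface"
  uOf <- function(M, g, sel1, sel2) {
    v <- M[, g]
    r <- .midrank(c(v[sel1], v[sel2]))
    n1 <- sum(sel1)
    sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  }
  pct <- numeric(0); kept <- character(0); excluded <- character(0)
  for (g in genes) {
    uT <- uOf(truth, g, inIface, !inIface)
    if (uT == 0) { excluded <- c(excluded, g); next }
    uP <- uOf(pred, g, inIface, !inIface)
    pct <- c(pct, 100 * (uP - uT) / uT)
    kept <- c(kept, g)
  }
  names(pct) <- kept
  med <- stats::median(pct)
  reps <- .withSeed(seed, {
    n <- nrow(truth)
    vapply(seq_len(nBoot), function(b) {
      ix <- sample.int(n, n, replace = TRUE)
      i1 <- inIface[ix]
      if (!any(i1) || all(i1)) return(NA_real_)
      p <- vapply(kept, function(g) {
        uT <- uOf(truth[ix, , drop = FALSE], g, i1, !i1)
        if (uT == 0) return(NA_real_)
        uP <- uOf(pred[ix, , drop = FALSE], g, i1, !i1)
        100 * (uP - uT) / uT
      }, numeric(1))
      stats::median(p, na.rm = TRUE)
    }, numeric(1))
  })
  ci <- unname(stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE))
  list(medianPct = med, ci = ci, pct = pct, genes = kept,
       excluded = excluded)
}

# ---------------------------------------------------------------------------
# Report assembly
# ---------------------------------------------------------------------------

#' Evaluate a model set on a validation slide
#'
#' Runs the four evaluation procedures — per-gene AUC and Spearman with
#' macro averages and spot-bootstrap CIs, k-NN cluster recovery of
#' predicted expression against ground-truth clusters, and the
#' differential-expression localization shift — and assembles an
#' [EvalReport-class].
#'
#' @param models a [GeneModelSet-class].
#' @param slide the validation [Slide-class].
#' @param nBoot bootstrap replicates (study default 1000).
#' @param kNN neighbor counts for cluster recovery.
#' @param kClusters ground-truth cluster count.
#' @param topN genes examined in the localization shift.
#' @param seed integer seed.
#' @param features optional precomputed features of `slide`.
#' @return an [EvalReport-class].
#' @export
evaluateModels <- function(models, slide, nBoot = 1000L, kNN = c(3L, 5L),
                           kClusters = 5L, topN = 200L, seed = 1L,
                           features = NULL) {
  pred <- predictExpression(models, slide, features = features)
  truth <- makeTargets(slide, models@geneIds)
  okBin <- setdiff(models@geneIds, models@excludedGenes)

  aucRes <- macroWithBootstrap("auc",
                               truth@binary[, okBin, drop = FALSE],
                               pred$binaryScore[, okBin, drop = FALSE],
                               nBoot = nBoot, seed = .childSeed(seed, 1L))
  rhoRes <- macroWithBootstrap("spearman", truth@continuous,
                               pred$continuous,
                               nBoot = nBoot, seed = .childSeed(seed, 2L))
  truthClusters <- clusterGroundTruth(truth@continuous, kClusters,
                                      seed = .childSeed(seed, 3L))
  recovery <- vapply(kNN, function(k) {
    knnClusterRecovery(truth@continuous, pred$continuous, truthClusters, k)
  }, numeric(1))
  names(recovery) <- paste0("k", kNN)
  deShift <- deLocalizationShift(truth@continuous, pred$continuous,
                                 regions(slide), rhoRes$perGene,
                                 topN = topN, nBoot = nBoot,
                                 seed = .childSeed(seed, 4L))
  excluded <- c(stats::setNames(rep("single-class labels",
                                    length(models@excludedGenes)),
                                models@excludedGenes),
                stats::setNames(rep("zero truth U at interface",
                                    length(deShift$excluded)),
                                deShift$excluded))
  new("EvalReport",
      perGeneAuc = aucRes$perGene, perGeneSpearman = rhoRes$perGene,
      macro = list(auc = aucRes[c("macroMean", "macroMedian",
                                  "ciMean", "ciMedian")],
                   spearman = rhoRes[c("macroMean", "macroMedian",
                                       "ciMean", "ciMedian")]),
      recovery = recovery,
      deShift = deShift[c("medianPct", "ci")],
      nBootstrap = as.integer(nBoot), excludedGenes = excluded,
      trainedOn = paste(models@trainSlideIds, collapse = ","),
      evaluatedOn = slideId(slide))
}

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: trained on [%s], evaluated on '%s'\n",
              object@trainedOn, object@evaluatedOn))
  a <- object@macro$auc; s <- object@macro$spearman
  cat(sprintf("  macro AUC      mean %.3f [%.3f, %.3f]  median %.3f\n",
              a$macroMean, a$ciMean[1], a$ciMean[2], a$macroMedian))
  cat(sprintf("  macro Spearman mean %.3f [%.3f, %.3f]  median %.3f\n",
              s$macroMean, s$ciMean[1], s$ciMean[2], s$macroMedian))
  cat(sprintf("  recovery: %s\n",
              paste(sprintf("%s=%.3f", names(object@recovery),
                            object@recovery), collapse = ", ")))
  cat(sprintf("  DE localization shift: %.2f%% [%.2f, %.2f]\n",
              object@deShift$medianPct, object@deShift$ci[1],
              object@deShift$ci[2]))
})
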