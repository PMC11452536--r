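#' @include AllClasses.R AllGenerics.R spot-geometry.R synthetic-cohort.R
NULL

# ---------------------------------------------------------------------------
# Spatially variable gene ranking (Moran's I)
# ---------------------------------------------------------------------------

# spatial neighbors for Moran's I: the hexagonal adjacency (each interior
# spot's six nearest neighbors, fewer at the border); distance-tie-free
# and therefore well-defined, unlike a strict k-NN cutoff on a lattice
.moranNeighbors <- function(grid) spotNeighbors(grid)

#' Moran's I under row-standardized k-NN weights
#'
#' Spatial autocorrelation of a per-spot value: with row-standardized
#' weights `I = sum_i z_i * mean(z over neighbors of i) / sum_i z_i^2`,
#' where z are centered values. Zero-variance input returns 0 by
#' convention.
#'
#' @param values numeric per-spot vector.
#' @param neighbors list of neighbor index vectors (row-standardized
#'   weights are implied), e.g. from the grid's 6 nearest neighbors.
#' @return Moran's I.
#' @export
moranI <- function(values, neighbors) {
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) return(0)
  num <- 0
  for (i in seq_along(z)) {
    nb <- neighbors[[i]]
    if (length(nb)) num <- num + z[i] * mean(z[nb])
  }
  num / denom
}

#' Rank genes by spatial variability
#'
#' Genes are ranked by Moran's I of their log1p-transformed counts under
#' row-standardized nearest-neighbor spatial weights (the hexagonal
#' adjacency: each interior spot's six nearest neighbors, which on the
#' Visium lattice is the k = 6 neighborhood without distance ties).
#' Ties break by gene id; zero-variance genes
#' take I = 0 and rank last. This is the package's spatially-variable-gene
#' selector (recorded as `"moran"` in its output attributes).
#'
#' @param counts spots x G count matrix (or a [Slide-class]).
#' @param grid the [SpotGrid-class] (ignored when `counts` is a Slide).
#' @param topK how many genes to return.
#' @return character vector of `topK` gene ids, most spatially variable
#'   first, with attributes `moranI` (named, full ranking) and `selector`.
#' @export
rankSpatiallyVariable <- function(counts, grid = NULL, topK = NULL) {
  if (is(counts, "Slide")) {
    grid <- spotGrid(counts)
    counts <- t(assay(counts, "counts"))
  }
  if (nrow(counts) < 2L) stop("at least 2 spots are required", call. = FALSE)
  G <- ncol(counts)
  geneIds <- colnames(counts) %||% sprintf("gene%03d", seq_len(G))
  if (is.null(topK)) topK <- G
  if (topK > G) {
    stop(sprintf("topK (%d) exceeds the number of genes (%d)", topK, G),
         call. = FALSE)
  }
  nbrs <- .moranNeighbors(grid)
  lg <- log1p(counts)
  zeroVar <- apply(lg, 2, function(x) stats::var(x) == 0)
  I <- vapply(seq_len(G), function(g) {
    if (zeroVar[g]) 0 else moranI(lg[, g], nbrs)
  }, numeric(1))
  names(I) <- geneIds
  ord <- order(zeroVar, -I, geneIds)
  out <- geneIds[ord][seq_len(topK)]
  attr(out, "moranI") <- I[ord]
  attr(out, "selector") <- "moran"
  out
}

# ---------------------------------------------------------------------------
# Targets
# ---------------------------------------------------------------------------

#' Build binary and continuous prediction targets
#'
#' Continuous targets are `log(count + 1)`; binary targets are 1 where the
#' continuous value strictly exceeds the gene's median continuous value
#' (ties at the median are class 0).
#'
#' @param counts spots x G count matrix (or a [Slide-class]).
#' @param geneIds genes to keep, in order (default: all columns).
#' @return a [GeneTargets-class].
#' @examples
#' tg <- makeTargets(matrix(0:3, 4, 1, dimnames = list(NULL, "g1")))
#' tg@continuous[, 1]   # 0, log 2, log 3, log 4
#' tg@binary[, 1]       # 0 0 1 1
#' @export
makeTargets <- function(counts, geneIds = NULL) {
  if (is(counts, "Slide")) counts <- t(assay(counts, "counts"))
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("gene%03d", seq_len(ncol(counts)))
  }
  if (is.null(geneIds)) geneIds <- colnames(counts)
  counts <- counts[, geneIds, drop = FALSE]
  cont <- log1p(counts)
  med <- apply(cont, 2, stats::median)
  bin <- (cont > rep(med, each = nrow(cont))) * 1L
  new("GeneTargets", geneIds = geneIds, continuous = cont, binary = bin)
}

# ---------------------------------------------------------------------------
# Featurizer (reference backend)
# ---------------------------------------------------------------------------

.FEATURIZER_ID <- "channel-stats-v1"

#' Summary-statistic features of one patch
#'
#' The deterministic reference featurizer: per channel, the mean, standard
#' deviation and 25/50/75% quantiles of pixel values inside the circular
#' capture mask. A deep featurizer can replace this behind the same
#' interface (feature vector per patch).
#'
#' @param patch h x w x channels array.
#' @param maskDiameterPx capture-zone diameter in pixels (defaults to the
#'   full patch width).
#' @return named numeric feature vector (5 per channel).
#' @export
featurizePatch <- function(patch, maskDiameterPx = dim(patch)[1]) {
  if (length(dim(patch)) == 2L) patch <- array(patch, c(dim(patch), 1L))
  mask <- spotCaptureMask(dim(patch)[1], min(maskDiameterPx, dim(patch)[1]))
  C <- dim(patch)[3]
  out <- numeric(5L * C)
  for (ch in seq_len(C)) {
    v <- patch[, , ch][mask]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    out[(ch - 1L) * 5L + 1:5] <-
      c(mean(v), if (length(v) > 1L) stats::sd(v) else 0, q)
  }
  names(out) <- paste0(rep(paste0("ch", seq_len(C)), each = 5L), "_",
                       c("mean", "sd", "q25", "q50", "q75"))
  out
}

# mask diameter used for a slide: the spot capture zone at the slide's
# rendering resolution, capped at the patch size
.slideMaskDiameterPx <- function(slide, patchPx) {
  g <- spotGrid(slide)
  min(patchPx, g@spotDiameterUm / g@resolutionUmPerPx)
}

#' Featurize every spot of a slide
#'
#' @param slide a [Slide-class] with an image source.
#' @param spec a [PatchSpec-class].
#' @return spots x features matrix in grid order.
#' @export
featurizeSlide <- function(slide, spec) {
  p <- spec@patchPx
  maskPx <- .slideMaskDiameterPx(slide, p)
  n <- nSpots(slide)
  first <- featurizePatch(spotPatch(slide, 1L, p), maskPx)
  X <- matrix(0, n, length(first),
              dimnames = list(colnames(slide), names(first)))
  X[1L, ] <- first
  for (i in seq.int(2L, length.out = n - 1L)) {
    X[i, ] <- featurizePatch(spotPatch(slide, i, p), maskPx)
  }
  X
}

# ---------------------------------------------------------------------------
# Heads
# ---------------------------------------------------------------------------

# ridge solution from sufficient statistics; intercept (first column)
# unpenalized; penalty scales with n so duplicated data leave the fit
# unchanged
.ridgeSolve <- function(XtX, Xty, n, lambda) {
  p <- nrow(XtX)
  pen <- diag(c(0, rep(lambda * n, p - 1L)), p)
  solve(XtX + pen, Xty)
}

# ridge-penalized logistic regression via IRLS
.logisticRidge <- function(X, y, lambda, maxIter = 25L, tol = 1e-8) {
  p <- ncol(X)
  n <- nrow(X)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  pen <- diag(c(0, rep(lambda * n, p - 1L)), p)
  for (iter in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / w
    Xw <- X * w
    betaNew <- tryCatch(solve(crossprod(Xw, X) + pen, crossprod(Xw, z)),
                        error = function(e) NULL)
    if (is.null(betaNew)) return(NULL)
    betaNew <- drop(betaNew)
    if (max(abs(betaNew - beta)) < tol) { beta <- betaNew; break }
    beta <- betaNew
  }
  beta
}

#' Predictor specification for the reference backend
#'
#' @param patchPx patch side length used for featurization (default 32 px
#'   at the synthetic rendering resolutions).
#' @param lambdaGrid ridge penalties searched on the internal validation
#'   split.
#' @param valFraction fraction of training spots held out (stratified by
#'   slide) to select the penalty.
#' @param heads which heads to train.
#' @return a predictor-spec list.
#' @export
predictorSpec <- function(patchPx = 32L,
                          lambdaGrid = 10^c(-4, -3, -2, -1),
                          valFraction = 0.1,
                          heads = c("continuous", "binary")) {
  list(patchPx = as.integer(patchPx), lambdaGrid = lambdaGrid,
       valFraction = valFraction, heads = heads,
       featurizer = .FEATURIZER_ID)
}

#' Train per-gene expression predictors
#'
#' For each gene, fits a continuous head by ridge regression minimizing
#' mean squared error on log1p counts and a binary head by ridge-penalized
#' logistic regression on median-dichotomized targets, over features from
#' the reference featurizer. An internal validation split (default 10% of
#' spots, stratified by slide, seeded) selects the shared ridge penalty
#' from a small fixed grid; the final fit uses all training spots. Genes
#' whose dichotomized labels are single-class are flagged untrainable for
#' the binary head and excluded from macro binary metrics.
#'
#' @param trainSlides list of [Slide-class] objects.
#' @param geneIds genes to model (default: all genes of the first slide).
#' @param spec a [predictorSpec()] list.
#' @param seed integer seed (validation split).
#' @param features optional precomputed named list of per-slide feature
#'   matrices (from [featurizeSlide()]), to avoid re-rendering.
#' @return a [GeneModelSet-class].
#' @export
trainGeneModels <- function(trainSlides, geneIds = NULL,
                            spec = predictorSpec(), seed = 1L,
                            features = NULL) {
  stopifnot(length(trainSlides) >= 1L)
  if (is.null(names(trainSlides))) {
    names(trainSlides) <- vapply(trainSlides, slideId, character(1))
  }
  if (is.null(geneIds)) geneIds <- rownames(trainSlides[[1]])
  pspec <- patchSpec(spec$patchPx, stridePx = spec$patchPx)
  if (is.null(features)) {
    features <- lapply(trainSlides, featurizeSlide, spec = pspec)
  }
  X <- do.call(rbind, features[names(trainSlides)])
  slideOf <- rep(names(trainSlides),
                 vapply(trainSlides, nSpots, integer(1)))
  counts <- do.call(rbind, lapply(trainSlides,
                                  function(s) t(assay(s, "counts"))))
  targets <- makeTargets(counts, geneIds)
  if (nrow(X) < 2L) stop("at least 2 training spots are required",
                         call. = FALSE)
  Xi <- cbind(`(Intercept)` = 1, X)
  n <- nrow(Xi); p <- ncol(Xi); G <- length(geneIds)

  # internal validation split, stratified by slide
  valIdx <- .withSeed(.childSeed(seed, 11L), {
    unlist(lapply(split(seq_len(n), slideOf), function(ix) {
      nv <- max(1L, round(spec$valFraction * length(ix)))
      if (nv >= length(ix)) integer(0) else sample(ix, nv)
    }), use.names = FALSE)
  })
  trIdx <- setdiff(seq_len(n), valIdx)
  if (!length(valIdx)) { trIdx <- seq_len(n); valIdx <- seq_len(n) }

  # continuous head: penalty by validation MSE averaged over genes
  XtXtr <- crossprod(Xi[trIdx, , drop = FALSE])
  XtYtr <- crossprod(Xi[trIdx, , drop = FALSE],
                     targets@continuous[trIdx, , drop = FALSE])
  valMse <- vapply(spec$lambdaGrid, function(l) {
    B <- .ridgeSolve(XtXtr, XtYtr, length(trIdx), l)
    mean((Xi[valIdx, , drop = FALSE] %*% B -
            targets@continuous[valIdx, , drop = FALSE])^2)
  }, numeric(1))
  lamCont <- spec$lambdaGrid[which.min(valMse)]
  contCoefs <- .ridgeSolve(crossprod(Xi), crossprod(Xi, targets@continuous),
                           n, lamCont)
  colnames(contCoefs) <- geneIds

  # binary head: penalty by validation deviance averaged over trainable genes
  binCoefs <- matrix(NA_real_, p, G, dimnames = list(colnames(Xi), geneIds))
  excluded <- character(0)
  lamBin <- NA_real_
  if ("binary" %in% spec$heads) {
    trainable <- which(apply(targets@binary, 2,
                             function(y) length(unique(y)) == 2L))
    excluded <- setdiff(geneIds, geneIds[trainable])
    if (length(trainable)) {
      probe <- trainable[seq_len(min(5L, length(trainable)))]
      valDev <- vapply(spec$lambdaGrid, function(l) {
        dev <- 0
        for (g in probe) {
          b <- .logisticRidge(Xi[trIdx, , drop = FALSE],
                              targets@binary[trIdx, g], l)
          if (is.null(b)) return(Inf)
          mu <- stats::plogis(drop(Xi[valIdx, , drop = FALSE] %*% b))
          y <- targets@binary[valIdx, g]
          dev <- dev - mean(y * log(pmax(mu, 1e-12)) +
                              (1 - y) * log(pmax(1 - mu, 1e-12)))
        }
        dev
      }, numeric(1))
      lamBin <- spec$lambdaGrid[which.min(valDev)]
      for (g in trainable) {
        b <- .logisticRidge(Xi, targets@binary[, g], lamBin)
        if (is.null(b)) {
          excluded <- c(excluded, geneIds[g])
        } else {
          binCoefs[, g] <- b
        }
      }
    }
  }

  fitted <- list(continuous = Xi %*% contCoefs,
                 binaryScore = stats::plogis(Xi %*% binCoefs))
  new("GeneModelSet", geneIds = geneIds, contCoefs = contCoefs,
      binCoefs = binCoefs, excludedGenes = unique(excluded),
      featurizer = spec$featurizer, patchSpec = pspec,
      trainSlideIds = names(trainSlides),
      lambda = c(continuous = lamCont, binary = lamBin),
      trainFitted = fitted, seed = as.integer(seed))
}

setMethod("show", "GeneModelSet", function(object) {
  cat(sprintf(paste0("GeneModelSet: %d genes (%d binary-untrainable), ",
                     "featurizer '%s', trained on %s\n"),
              length(object@geneIds), length(object@excludedGenes),
              object@featurizer,
              paste(object@trainSlideIds, collapse = ", ")))
})

#' Predict spot-level expression on a slide
#'
#' Applies the featurizer and both heads at every spot; output rows follow
#' the slide's grid order.
#'
#' @param models a [GeneModelSet-class].
#' @param slide a [Slide-class].
#' @param features optional precomputed feature matrix for the slide.
#' @return list with `continuous` (spots x G predicted log1p expression)
#'   and `binaryScore` (spots x G probabilities; NA columns for
#'   untrainable genes).
#' @export
predictExpression <- function(models, slide, features = NULL) {
  if (is.null(features)) features <- featurizeSlide(slide, models@patchSpec)
  Xi <- cbind(`(Intercept)` = 1, features)
  list(continuous = Xi %*% models@contCoefs,
       binaryScore = stats::plogis(Xi %*% models@binCoefs))
}

#' Superresolution inference over an image
#'
#' Predicts expression at every sliding-window position of the image (no
#' expression input is consumed), yielding denser-than-spot inference maps
#' when the stride is below the spot pitch.
#'
#' @param models a [GeneModelSet-class].
#' @param image h x w x channels array or [RasterImageSource-class].
#' @param spec a [PatchSpec-class]; `stridePx` controls map density.
#' @param genes genes to predict (default: all modeled genes).
#' @param maskDiameterPx featurization mask diameter (default: full patch).
#' @return list with `positions` (from [superresolutionPositions()]) and
#'   `continuous` (positions x genes prediction matrix).
#' @export
superresolve <- function(models, image, spec, genes = NULL,
                         maskDiameterPx = spec@patchPx) {
  if (is(image, "RasterImageSource")) image <- image@image
  if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
  if (is.null(genes)) genes <- models@geneIds
  pos <- superresolutionPositions(dim(image)[1], dim(image)[2], spec)
  p <- spec@patchPx
  X <- matrix(0, nrow(pos),
              length(featurizePatch(array(0, c(2, 2, dim(image)[3])))))
  for (i in seq_len(nrow(pos))) {
    sl <- .sliceWindow(image, pos$row[i], pos$col[i], p, pad = "none")
    X[i, ] <- featurizePatch(sl$patch, maskDiameterPx)
  }
  Xi <- cbind(1, X)
  list(positions = pos,
       continuous = Xi %*% models@contCoefs[, genes, drop = FALSE])
}
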