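#' @include AllClasses.R AllGenerics.R spot-geometry.R
NULL

.N_CHANNELS <- 6L      # rendered image channels (redundant stain basis)
.ENCODE_SCALE <- 0.08  # channel-mean shift per unit loading at gain 1

#' Protocol profiles for the two slide-preparation regimes
#'
#' Defaults encode the study's quality contrast: the enhanced protocol
#' (automated staining, high-resolution scanning) has strictly lower pixel
#' noise and stain variability and strictly higher signal gain than the
#' traditional one (manual staining, low-resolution scanning), plus a far
#' lower artifact rate. Rendering resolutions are desk-scale: patches stay
#' small while preserving the relative 2x resolution advantage of the
#' enhanced protocol.
#'
#' @param name `"traditional"` or `"enhanced"`.
#' @param resolutionUmPerPx,stainVariability,pixelNoiseSd,signalGain,artifactRate
#'   overrides for individual quality parameters.
#' @return a [ProtocolProfile-class].
#' @examples
#' protocolProfile("enhanced")
#' @export
protocolProfile <- function(name = c("traditional", "enhanced"),
                            resolutionUmPerPx = NULL,
                            stainVariability = NULL,
                            pixelNoiseSd = NULL,
                            signalGain = NULL,
                            artifactRate = NULL) {
  name <- match.arg(name)
  def <- if (name == "traditional") {
    list(res = 4, stain = 0.08, noise = 0.15, gain = 0.55, artifact = 0.12)
  } else {
    list(res = 2, stain = 0.02, noise = 0.05, gain = 0.90, artifact = 0.02)
  }
  new("ProtocolProfile", name = name,
      resolutionUmPerPx = resolutionUmPerPx %||% def$res,
      stainVariability = stainVariability %||% def$stain,
      pixelNoiseSd = pixelNoiseSd %||% def$noise,
      signalGain = signalGain %||% def$gain,
      artifactRate = artifactRate %||% def$artifact)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "ProtocolProfile", function(object) {
  cat(sprintf(paste0("ProtocolProfile '%s': %.3g um/px, noise sd %.3g, ",
                     "stain var %.3g, gain %.3g, artifact rate %.3g\n"),
              object@name, object@resolutionUmPerPx, object@pixelNoiseSd,
              object@stainVariability, object@signalGain,
              object@artifactRate))
})

#' Channel-mixing basis of a protocol
#'
#' Each protocol maps latent program activities into image channels
#' through its own fixed orthonormal basis, derived deterministically from
#' the protocol name. This models protocol-specific stain/color response:
#' predictors calibrated to one protocol's basis transfer imperfectly to
#' the other.
#'
#' @param profile a [ProtocolProfile-class].
#' @param nPrograms number of latent programs P.
#' @param nChannels number of image channels.
#' @return nChannels x nPrograms matrix with orthonormal columns.
#' @export
channelMixing <- function(profile, nPrograms, nChannels = .N_CHANNELS) {
  if (nChannels < nPrograms) {
    stop("nChannels must be at least the number of programs", call. = FALSE)
  }
  .withSeed(.stringSeed(paste0("stain-basis-", profile@name)), {
    m <- matrix(stats::rnorm(nChannels * nPrograms), nChannels, nPrograms)
    qr.Q(qr(m))
  })
}

#' Deterministic pixel encoding of program loadings
#'
#' The noise-free channel mean of a spot's patch: 0.5 plus the loading
#' vector pushed through the protocol's channel-mixing basis, scaled by the
#' signal gain, clamped to [0.02, 0.98].
#'
#' @param loadings numeric vector of length P, or spots x P matrix.
#' @param profile a [ProtocolProfile-class].
#' @param nChannels number of image channels.
#' @return per-channel means (vector, or spots x channels matrix).
#' @export
encodeLoadings <- function(loadings, profile, nChannels = .N_CHANNELS) {
  vec <- is.null(dim(loadings))
  L <- if (vec) matrix(loadings, nrow = 1) else loadings
  A <- channelMixing(profile, ncol(L), nChannels)
  enc <- 0.5 + .ENCODE_SCALE * profile@signalGain * (L %*% t(A))
  enc <- pmin(pmax(enc, 0.02), 0.98)
  if (vec) drop(enc) else enc
}

#' Decode channel means back to program loadings
#'
#' Least-squares inversion of [encodeLoadings()]; used for signal-recovery
#' diagnostics on synthetic data.
#'
#' @param channelMeans vector or spots x channels matrix of channel means.
#' @param profile the rendering [ProtocolProfile-class].
#' @param nPrograms number of latent programs P.
#' @return loading estimates (same leading shape as the input).
#' @export
decodeLoadings <- function(channelMeans, profile, nPrograms) {
  vec <- is.null(dim(channelMeans))
  M <- if (vec) matrix(channelMeans, nrow = 1) else channelMeans
  A <- channelMixing(profile, nPrograms, ncol(M))
  est <- ((M - 0.5) %*% A) / (.ENCODE_SCALE * profile@signalGain)
  if (vec) drop(est) else est
}

# region-specific additive offsets: program p elevates region (p mod 3)
.regionOffsets <- function(P, effect = 1.2) {
  regions <- c("tumor", "interface", "distal")
  off <- matrix(0, 3, P, dimnames = list(regions, NULL))
  for (p in seq_len(P)) off[((p - 1L) %% 3L) + 1L, p] <- effect
  off
}

#' Generate the latent tissue field of a synthetic slide
#'
#' Tumor regions are connected blobs grown from random focus spots;
#' interface spots are the non-tumor spots within one pitch of a tumor
#' spot; the remainder is distal. Latent program loadings are smoothed
#' random fields (spatially autocorrelated) plus region-specific offsets,
#' and a P x G program-to-gene weight matrix links programs to genes.
#'
#' @param grid a [SpotGrid-class].
#' @param nTumorFoci number of tumor seed spots (>= 1).
#' @param P number of latent programs (default 4).
#' @param seed integer seed.
#' @param G number of genes (default 50); ignored when `geneWeights` is
#'   supplied.
#' @param geneWeights optional P x G weight matrix shared across slides of
#'   one cohort.
#' @param tumorFrac target fraction of spots labeled tumor.
#' @param regionEffect loading offset distinguishing regions.
#' @return a [TissueField-class].
#' @export
generateTissueField <- function(grid, nTumorFoci = 2L, P = 4L, seed = 1L,
                                G = 50L, geneWeights = NULL,
                                tumorFrac = 0.18, regionEffect = 1.2) {
  n <- nSpots(grid)
  if (n < 1L) stop("grid must contain at least one spot", call. = FALSE)
  nTumorFoci <- .assertCount(nTumorFoci, "nTumorFoci")
  P <- .assertCount(P, "P")
  if (n < nTumorFoci) {
    stop(sprintf("grid of %d spots cannot host %d disjoint tumor foci",
                 n, nTumorFoci), call. = FALSE)
  }
  nbrs <- spotNeighbors(grid)
  .withSeed(seed, {
    # --- tumor blobs grown from foci ---------------------------------
    minSep <- 3 * grid@pitchUm
    xy <- spotCoordsUm(grid)
    foci <- integer(0)
    cand <- sample.int(n)
    for (i in cand) {
      if (!length(foci) ||
          all(sqrt((xy[foci, 1] - xy[i, 1])^2 +
                   (xy[foci, 2] - xy[i, 2])^2) >= minSep)) {
        foci <- c(foci, i)
      }
      if (length(foci) == nTumorFoci) break
    }
    if (length(foci) < nTumorFoci) {
      stop(sprintf("grid too small to host %d disjoint tumor foci",
                   nTumorFoci), call. = FALSE)
    }
    tumor <- logical(n)
    tumor[foci] <- TRUE
    target <- max(nTumorFoci, round(tumorFrac * n))
    frontier <- foci
    while (sum(tumor) < target && length(frontier)) {
      grow <- unique(unlist(nbrs[frontier], use.names = FALSE))
      grow <- grow[!tumor[grow]]
      if (!length(grow)) break
      take <- sample(grow, min(length(grow), target - sum(tumor)))
      tumor[take] <- TRUE
      frontier <- take
    }
    # fill holes: non-tumor spots whose every neighbor is tumor
    repeat {
      hole <- which(!tumor & vapply(nbrs, function(v) {
        length(v) > 0 && all(tumor[v])
      }, logical(1)))
      if (!length(hole)) break
      tumor[hole] <- TRUE
    }
    region <- rep("distal", n)
    region[tumor] <- "tumor"
    touching <- which(!tumor & vapply(nbrs, function(v) any(tumor[v]),
                                      logical(1)))
    region[touching] <- "interface"

    # --- smoothed random program loadings ----------------------------
    L <- matrix(stats::rnorm(n * P), n, P)
    for (iter in 1:3) {
      Lsm <- L
      for (i in seq_len(n)) {
        if (length(nbrs[[i]])) {
          Lsm[i, ] <- 0.5 * L[i, ] +
            0.5 * colMeans(L[nbrs[[i]], , drop = FALSE])
        }
      }
      L <- Lsm
    }
    sds <- apply(L, 2, stats::sd)
    for (p in seq_len(P)) {
      if (is.finite(sds[p]) && sds[p] > 0) {
        L[, p] <- (L[, p] - mean(L[, p])) / sds[p]
      }
    }
    off <- .regionOffsets(P, regionEffect)
    L <- L + off[region, , drop = FALSE]

    # --- program-to-gene weights -------------------------------------
    if (is.null(geneWeights)) {
      geneWeights <- generateGeneWeights(P, G, seed = .childSeed(seed, 17L))
    }
    new("TissueField", region = region, loadings = unname(L),
        geneWeights = geneWeights)
  })
}

#' Program-to-gene weight matrix
#'
#' Each gene loads mainly on one program (cycled assignment, random sign)
#' with small dense background weights, giving regionally localized
#' expression for most genes.
#'
#' @param P,G program and gene counts.
#' @param seed integer seed.
#' @return P x G matrix.
#' @export
generateGeneWeights <- function(P, G, seed = 1L) {
  .withSeed(seed, {
    W <- matrix(stats::rnorm(P * G, sd = 0.1), P, G)
    main <- ((seq_len(G) - 1L) %% P) + 1L
    for (g in seq_len(G)) {
      W[main[g], g] <- W[main[g], g] +
        sample(c(-1, 1), 1) * stats::runif(1, 0.8, 1.2)
    }
    W
  })
}

#' @rdname regions
setMethod("regions", "TissueField", function(x) x@region)

setMethod("show", "TissueField", function(object) {
  tab <- table(factor(object@region, c("tumor", "interface", "distal")))
  cat(sprintf("TissueField: %d spots (%s), %d programs, %d genes\n",
              length(object@region),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              ncol(object@loadings), ncol(object@geneWeights)))
})

#' Simulate spatially structured negative-binomial counts
#'
#' The log-mean of gene g at spot s is an offset plus
#' `(loadings %*% geneWeights)[s, g]`; the offset is a single per-slide
#' scalar chosen so that the average spot's total count equals the mean
#' library size. Counts are drawn from a negative binomial with that mean
#' and size (theta) `nbDispersion` (variance `mu + mu^2 / theta`, so
#' large values approach Poisson). Per-spot totals vary with tissue
#' content, as in real spot data.
#'
#' @param field a [TissueField-class].
#' @param librarySizeMean expected total counts per spot.
#' @param nbDispersion NB size (theta) parameter, > 0.
#' @param seed integer seed.
#' @return spots x G integer count matrix.
#' @export
simulateExpression <- function(field, librarySizeMean = 10000,
                               nbDispersion = 10, seed = 1L) {
  .assertScalarPositive(librarySizeMean, "librarySizeMean")
  .assertScalarPositive(nbDispersion, "nbDispersion")
  eta <- field@loadings %*% field@geneWeights
  if (!all(is.finite(eta))) {
    stop("non-finite expression means; check loadings and weights",
         call. = FALSE)
  }
  ex <- exp(eta)
  mu <- librarySizeMean * ex / mean(rowSums(ex))
  .withSeed(seed, {
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = nbDispersion),
                     nrow(mu), ncol(mu))
    storage.mode(counts) <- "integer"
    counts
  })
}

#' Render one spot-centered synthetic patch
#'
#' Channel means are the deterministic encoding of the spot's program
#' loadings ([encodeLoadings()]); on top of that the renderer adds a
#' patch-level DC noise component (sd `pixelNoiseSd / 2`), i.i.d. pixel
#' noise (sd `pixelNoiseSd`), and the slide's per-channel stain shift;
#' with probability `artifactRate` a constant-value block occludes part of
#' the patch. Values are clamped to [0, 1].
#'
#' @param field a [TissueField-class].
#' @param spotIndex spot index in grid order.
#' @param profile a [ProtocolProfile-class].
#' @param patchPx patch side length in pixels (> 0).
#' @param seed integer seed (per spot).
#' @param stainShift per-channel additive shift of the slide (default 0).
#' @param nChannels number of channels.
#' @return patchPx x patchPx x nChannels array.
#' @export
renderPatch <- function(field, spotIndex, profile, patchPx, seed = 1L,
                        stainShift = NULL, nChannels = .N_CHANNELS) {
  patchPx <- .assertCount(patchPx, "patchPx")
  means <- encodeLoadings(field@loadings[spotIndex, ], profile, nChannels)
  if (is.null(stainShift)) stainShift <- numeric(nChannels)
  .withSeed(seed, {
    hasArtifact <- stats::runif(1) < profile@artifactRate
    dc <- stats::rnorm(nChannels, sd = profile@pixelNoiseSd / 2)
    patch <- array(stats::rnorm(patchPx * patchPx * nChannels,
                                sd = profile@pixelNoiseSd),
                   dim = c(patchPx, patchPx, nChannels))
    for (ch in seq_len(nChannels)) {
      patch[, , ch] <- patch[, , ch] + means[ch] + dc[ch] + stainShift[ch]
    }
    if (hasArtifact) {
      side <- max(1L, as.integer(round(0.4 * patchPx)))
      r0 <- sample.int(patchPx - side + 1L, 1L)
      c0 <- sample.int(patchPx - side + 1L, 1L)
      patch[r0:(r0 + side - 1L), c0:(c0 + side - 1L), ] <- 0.2
    }
    pmin(pmax(patch, 0), 1)
  })
}

#' @rdname spotPatch
setMethod("spotPatch", "SyntheticImageSource",
  function(x, spotIndex, patchPx) {
    renderPatch(x@field, spotIndex, x@profile, patchPx,
                seed = .childSeed(x@seed, spotIndex),
                stainShift = x@stainShift, nChannels = x@nChannels)
  })

#' @rdname spotPatch
setMethod("spotPatch", "Slide", function(x, spotIndex, patchPx) {
  src <- x@imageSource
  if (is.null(src)) stop("slide has no image source", call. = FALSE)
  if (is(src, "RasterImageSource")) {
    g <- x@spotGrid
    p <- as.integer(patchPx)
    sl <- .sliceWindow(src@image,
                       as.integer(round(g@pxlRow[spotIndex] - p / 2)),
                       as.integer(round(g@pxlCol[spotIndex] - p / 2)),
                       p, pad = "reflect")
    sl$patch
  } else {
    spotPatch(src, spotIndex, patchPx)
  }
})

#' Subset a SpotGrid by spot index
#' @param x a [SpotGrid-class].
#' @param i spot indices.
#' @param j,...,drop unused, present for generic compatibility.
#' @return the subset [SpotGrid-class].
#' @export
setMethod("[", "SpotGrid", function(x, i, j, ..., drop = FALSE) {
  initialize(x, barcode = x@barcode[i], arrayRow = x@arrayRow[i],
             arrayCol = x@arrayCol[i], pxlRow = x@pxlRow[i],
             pxlCol = x@pxlCol[i])
})

#' Generate one complete synthetic slide
#'
#' Builds the spot grid, grows one tissue field per patient, simulates
#' counts, and attaches a procedural image source carrying the slide's
#' stain shift. With `nPatients = 2` the capture area is split at the
#' vertical midline (left/right), each half receiving an independent
#' tissue field over the shared program-to-gene weights.
#'
#' @param gridSpec list with `captureMm` and optionally `spotDiameterUm`,
#'   `pitchUm`.
#' @param fieldParams list with `nTumorFoci`, `P`, `G`, optionally
#'   `geneWeights`, `tumorFrac`, `regionEffect`.
#' @param profile a [ProtocolProfile-class].
#' @param exprParams list with `librarySizeMean`, `nbDispersion`.
#' @param seed integer seed.
#' @param slideId slide identifier.
#' @param nPatients 1 or 2 tissue sections on the capture area.
#' @param patientIds patient identifiers (length `nPatients`).
#' @param role `"train"` or `"validation"`.
#' @return a [Slide-class].
#' @export
generateSlide <- function(gridSpec, fieldParams, profile, exprParams,
                          seed = 1L, slideId = "slide", nPatients = 1L,
                          patientIds = NULL, role = "train") {
  nPatients <- .assertCount(nPatients, "nPatients")
  stopifnot(nPatients <= 2L)
  if (is.null(patientIds)) patientIds <- paste0(slideId, "_p", seq_len(nPatients))
  grid <- buildSpotGrid(gridSpec$captureMm,
                        spotDiameterUm = gridSpec$spotDiameterUm %||% 55,
                        pitchUm = gridSpec$pitchUm %||% 100,
                        resolutionUmPerPx = profile@resolutionUmPerPx,
                        barcodePrefix = slideId)
  fp <- fieldParams
  W <- fp$geneWeights %||%
    generateGeneWeights(fp$P %||% 4L, fp$G %||% 50L,
                        seed = .childSeed(seed, 17L))
  n <- nSpots(grid)
  if (nPatients == 1L) {
    halves <- list(seq_len(n))
  } else {
    xUm <- spotCoordsUm(grid)[, "x"]
    mid <- gridSpec$captureMm * 1000 / 2
    halves <- list(which(xUm < mid), which(xUm >= mid))
  }
  region <- character(n)
  loadings <- NULL
  patient <- character(n)
  for (h in seq_along(halves)) {
    idx <- halves[[h]]
    f <- generateTissueField(grid[idx], nTumorFoci = fp$nTumorFoci %||% 2L,
                             P = fp$P %||% 4L,
                             seed = .childSeed(seed, 100L + h),
                             geneWeights = W,
                             tumorFrac = fp$tumorFrac %||% 0.18,
                             regionEffect = fp$regionEffect %||% 1.2)
    region[idx] <- f@region
    if (is.null(loadings)) {
      loadings <- matrix(0, n, ncol(f@loadings))
    }
    loadings[idx, ] <- f@loadings
    patient[idx] <- patientIds[h]
  }
  field <- new("TissueField", region = region, loadings = loadings,
               geneWeights = W)
  counts <- simulateExpression(field,
                               librarySizeMean = exprParams$librarySizeMean %||% 10000,
                               nbDispersion = exprParams$nbDispersion %||% 10,
                               seed = .childSeed(seed, 200L))
  stainShift <- .withSeed(.childSeed(seed, 300L),
                          stats::rnorm(.N_CHANNELS,
                                       sd = profile@stainVariability))
  src <- new("SyntheticImageSource", field = field, profile = profile,
             stainShift = stainShift, seed = .childSeed(seed, 400L),
             nChannels = .N_CHANNELS)
  geneIds <- sprintf("gene%03d", seq_len(ncol(counts)))
  se <- SummarizedExperiment(
    assays = list(counts = t(counts)),
    rowData = S4Vectors::DataFrame(gene_id = geneIds, row.names = geneIds),
    colData = S4Vectors::DataFrame(region = region, patient = patient,
                                   row.names = grid@barcode))
  new("Slide", se, spotGrid = grid, protocol = profile, imageSource = src,
      field = field, slideId = slideId, role = role)
}

#' Generate a held-out serial-section pair
#'
#' Two slides over one shared tissue field, emulating consecutive slices
#' of one block profiled under both protocols: the first is rendered with
#' the traditional profile, the second with the enhanced profile, and the
#' second's loadings are perturbed by `jitter` to model inter-section
#' drift. With `jitter = 0` both slides share identical count-generating
#' means.
#'
#' @param fieldParams,exprParams as in [generateSlide()].
#' @param jitter sd of the loading perturbation of the second section.
#' @param seed integer seed.
#' @param gridSpec list with `captureMm` etc.
#' @param profiles list with `traditional` and `enhanced`
#'   [ProtocolProfile-class] objects.
#' @param patientId shared patient identifier.
#' @return named list with slides `traditional` and `enhanced`.
#' @export
generateSerialPair <- function(fieldParams, exprParams, jitter = 0.05,
                               seed = 1L,
                               gridSpec = list(captureMm = 2.8),
                               profiles = list(
                                 traditional = protocolProfile("traditional"),
                                 enhanced = protocolProfile("enhanced")),
                               patientId = "serial_patient") {
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  fp <- fieldParams
  W <- fp$geneWeights %||%
    generateGeneWeights(fp$P %||% 4L, fp$G %||% 50L,
                        seed = .childSeed(seed, 17L))
  mkSlide <- function(profile, slideId, field, exprSeed, srcSeed) {
    grid <- buildSpotGrid(gridSpec$captureMm,
                          spotDiameterUm = gridSpec$spotDiameterUm %||% 55,
                          pitchUm = gridSpec$pitchUm %||% 100,
                          resolutionUmPerPx = profile@resolutionUmPerPx,
                          barcodePrefix = slideId)
    counts <- simulateExpression(field,
                                 librarySizeMean = exprParams$librarySizeMean %||% 10000,
                                 nbDispersion = exprParams$nbDispersion %||% 10,
                                 seed = exprSeed)
    stainShift <- .withSeed(.childSeed(srcSeed, 3L),
                            stats::rnorm(.N_CHANNELS,
                                         sd = profile@stainVariability))
    src <- new("SyntheticImageSource", field = field, profile = profile,
               stainShift = stainShift, seed = srcSeed,
               nChannels = .N_CHANNELS)
    geneIds <- sprintf("gene%03d", seq_len(ncol(counts)))
    se <- SummarizedExperiment(
      assays = list(counts = t(counts)),
      rowData = S4Vectors::DataFrame(gene_id = geneIds, row.names = geneIds),
      colData = S4Vectors::DataFrame(region = field@region,
                                     patient = patientId,
                                     row.names = grid@barcode))
    new("Slide", se, spotGrid = grid, protocol = profile, imageSource = src,
        field = field, slideId = slideId, role = "validation")
  }
  # field built on the traditional-resolution grid; the lattice (and hence
  # adjacency) is resolution-invariant, so it is shared by both sections
  baseGrid <- buildSpotGrid(gridSpec$captureMm,
                            spotDiameterUm = gridSpec$spotDiameterUm %||% 55,
                            pitchUm = gridSpec$pitchUm %||% 100,
                            resolutionUmPerPx =
                              profiles$traditional@resolutionUmPerPx)
  field1 <- generateTissueField(baseGrid, nTumorFoci = fp$nTumorFoci %||% 2L,
                                P = fp$P %||% 4L,
                                seed = .childSeed(seed, 101L),
                                geneWeights = W,
                                tumorFrac = fp$tumorFrac %||% 0.18,
                                regionEffect = fp$regionEffect %||% 1.2)
  field2 <- field1
  if (jitter > 0) {
    pert <- .withSeed(.childSeed(seed, 102L),
                      matrix(stats::rnorm(length(field1@loadings),
                                          sd = jitter),
                             nrow(field1@loadings)))
    field2@loadings <- field1@loadings + pert
  }
  list(traditional = mkSlide(profiles$traditional, "val_traditional",
                             field1, .childSeed(seed, 201L),
                             .childSeed(seed, 301L)),
       enhanced = mkSlide(profiles$enhanced, "val_enhanced",
                          field2, .childSeed(seed, 202L),
                          .childSeed(seed, 302L)))
}

#' Cohort configuration
#'
#' Desk-scale defaults mirroring the study design: 4 traditional training
#' slides (one patient each, single-patient capture areas) and 4 enhanced
#' training slides (two patients each, capture areas scaled by sqrt(2) to
#' hold two sections at equal per-patient area), plus one held-out serial
#' pair (traditional + enhanced) from a single patient.
#'
#' @param nTrainingSlidesPerProtocol training slides per protocol.
#' @param genes gene count G (>= 2).
#' @param captureMm single-patient capture-area side in mm.
#' @param librarySizeMean expected counts per spot.
#' @param nbDispersion NB size (theta) parameter.
#' @param serialPairJitter inter-serial-section loading drift sd.
#' @param seed master seed; all sub-seeds derive from it.
#' @param P latent program count.
#' @param nTumorFoci tumor foci per tissue section.
#' @param profiles list of the two [ProtocolProfile-class] objects.
#' @return a named list (the cohort configuration).
#' @export
cohortConfig <- function(nTrainingSlidesPerProtocol = 4L, genes = 50L,
                         captureMm = 2.8, librarySizeMean = 10000,
                         nbDispersion = 10, serialPairJitter = 0.05,
                         seed = 1L, P = 4L, nTumorFoci = 2L,
                         profiles = list(
                           traditional = protocolProfile("traditional"),
                           enhanced = protocolProfile("enhanced"))) {
  if (genes < 2L) stop("at least 2 genes are required", call. = FALSE)
  .assertScalarPositive(captureMm, "captureMm")
  .assertScalarPositive(librarySizeMean, "librarySizeMean")
  .assertScalarPositive(nbDispersion, "nbDispersion")
  if (serialPairJitter < 0) stop("serialPairJitter must be >= 0", call. = FALSE)
  list(nTrainingSlidesPerProtocol = as.integer(nTrainingSlidesPerProtocol),
       genes = as.integer(genes), captureMm = captureMm,
       librarySizeMean = librarySizeMean, nbDispersion = nbDispersion,
       serialPairJitter = serialPairJitter, seed = as.integer(seed),
       P = as.integer(P), nTumorFoci = as.integer(nTumorFoci),
       profiles = profiles)
}

#' Generate a seeded synthetic cohort
#'
#' Reproduces the study's cohort design at desk scale: traditional
#' training slides host one patient on a single-patient capture area,
#' enhanced training slides host two patients on a larger area, and two
#' serial sections from one extra patient are held out for validation
#' (one per protocol). All randomness derives deterministically from
#' `config$seed`.
#'
#' @param config a [cohortConfig()] list.
#' @return a [Cohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(seed = 7, genes = 10, captureMm = 1.2))
#' cohortDesign(coh)
#' @export
generateCohort <- function(config = cohortConfig()) {
  fp <- list(nTumorFoci = config$nTumorFoci, P = config$P, G = config$genes,
             geneWeights = generateGeneWeights(config$P, config$genes,
                                               seed = .childSeed(config$seed, 1L)))
  ep <- list(librarySizeMean = config$librarySizeMean,
             nbDispersion = config$nbDispersion)
  nT <- config$nTrainingSlidesPerProtocol
  slides <- list()
  design <- list()
  area <- 0L
  patient <- 0L
  for (i in seq_len(nT)) {
    area <- area + 1L; patient <- patient + 1L
    id <- sprintf("train_trad_%02d", i)
    slides[[id]] <- generateSlide(
      gridSpec = list(captureMm = config$captureMm), fieldParams = fp,
      profile = config$profiles$traditional, exprParams = ep,
      seed = .childSeed(config$seed, 1000L + i), slideId = id,
      nPatients = 1L, patientIds = sprintf("P%02d", patient))
    design[[length(design) + 1L]] <- data.frame(
      capture_area = area, slide_id = id, protocol = "traditional",
      role = "train", patients = sprintf("P%02d", patient),
      capture_mm = config$captureMm)
  }
  # held-out serial pair: capture areas 5 and 6
  pair <- generateSerialPair(fieldParams = fp, exprParams = ep,
                             jitter = config$serialPairJitter,
                             seed = .childSeed(config$seed, 5000L),
                             gridSpec = list(captureMm = config$captureMm),
                             profiles = config$profiles,
                             patientId = sprintf("P%02d", patient + 1L))
  patient <- patient + 1L
  for (nm in c("traditional", "enhanced")) {
    area <- area + 1L
    id <- slideId(pair[[nm]])
    slides[[id]] <- pair[[nm]]
    design[[length(design) + 1L]] <- data.frame(
      capture_area = area, slide_id = id, protocol = nm,
      role = "validation", patients = sprintf("P%02d", patient),
      capture_mm = config$captureMm)
  }
  for (i in seq_len(nT)) {
    area <- area + 1L
    id <- sprintf("train_enh_%02d", i)
    pids <- sprintf("P%02d", patient + c(1L, 2L)); patient <- patient + 2L
    slides[[id]] <- generateSlide(
      gridSpec = list(captureMm = config$captureMm * sqrt(2)),
      fieldParams = fp, profile = config$profiles$enhanced, exprParams = ep,
      seed = .childSeed(config$seed, 2000L + i), slideId = id,
      nPatients = 2L, patientIds = pids)
    design[[length(design) + 1L]] <- data.frame(
      capture_area = area, slide_id = id, protocol = "enhanced",
      role = "train", patients = paste(pids, collapse = ";"),
      capture_mm = config$captureMm * sqrt(2))
  }
  new("Cohort", slides = slides, design = do.call(rbind, design),
      config = config)
}

#' Cohort design table
#' @param cohort a [Cohort-class].
#' @return the design data.frame (one row per capture area).
#' @export
cohortDesign <- function(cohort) cohort@design

#' Slides of a cohort
#' @param cohort a [Cohort-class].
#' @param role optional filter, `"train"` or `"validation"`.
#' @return named list of [Slide-class] objects.
#' @export
cohortSlides <- function(cohort, role = NULL) {
  if (is.null(role)) return(cohort@slides)
  keep <- cohort@design$slide_id[cohort@design$role == role]
  cohort@slides[keep]
}

setMethod("show", "Cohort", function(object) {
  d <- object@design
  cat(sprintf("Cohort: %d capture areas (%d train, %d validation), %d genes\n",
              nrow(d), sum(d$role == "train"), sum(d$role == "validation"),
              object@config$genes))
})

#' @rdname nSpots
setMethod("nSpots", "Slide", function(x) ncol(x))
#' @rdname spotGrid
setMethod("spotGrid", "Slide", function(x) x@spotGrid)
#' @rdname protocol
setMethod("protocol", "Slide", function(x) x@protocol)
#' @rdname slideId
setMethod("slideId", "Slide", function(x) x@slideId)
#' @rdname regions
setMethod("regions", "Slide", function(x) colData(x)$region)

setMethod("show", "Slide", function(object) {
  cat(sprintf("Slide '%s' [%s, %s]: %d genes x %d spots\n",
              object@slideId, object@protocol@name, object@role,
              nrow(object), ncol(object)))
})
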