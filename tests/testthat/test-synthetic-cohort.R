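test_that("protocol profiles encode the quality contrast", {
  tr <- protocolProfile("traditional")
  en <- protocolProfile("enhanced")
  expect_lt(en@pixelNoiseSd, tr@pixelNoiseSd)
  expect_lt(en@stainVariability, tr@stainVariability)
  expect_gt(en@signalGain, tr@signalGain)
  expect_lt(en@resolutionUmPerPx, tr@resolutionUmPerPx)
  expect_error(protocolProfile("traditional", signalGain = 1.5), "signalGain")
})

test_that("tissue fields have coherent regions and positive spatial autocorrelation", {
  g <- smallGrid(1.6)  # a few hundred spots
  f <- generateTissueField(g, nTumorFoci = 2L, P = 4L, seed = 7L, G = 10L)
  expect_setequal(unique(f@region), c("tumor", "interface", "distal"))

  # exhaustive adjacency check: every interface spot touches tumor and
  # non-tumor; no tumor spot is labeled interface
  nbrs <- bruteNeighbors(g)
  tumor <- f@region == "tumor"
  for (i in which(f@region == "interface")) {
    expect_true(any(tumor[nbrs[[i]]]))
    expect_true(any(!tumor[nbrs[[i]]]))
  }
  # interface is exactly the non-tumor boundary of the tumor
  for (i in which(f@region == "distal")) {
    expect_false(any(tumor[nbrs[[i]]]))
  }

  # smoothed loadings are spatially autocorrelated
  for (p in seq_len(ncol(f@loadings))) {
    expect_gt(moranI(f@loadings[, p], nbrs), 0)
  }

  # determinism
  f2 <- generateTissueField(g, nTumorFoci = 2L, P = 4L, seed = 7L, G = 10L)
  expect_identical(f, f2)
})

test_that("degenerate grids are handled explicitly", {
  g1 <- buildSpotGrid(0.1)[1]  # one spot
  f <- generateTissueField(g1, nTumorFoci = 1L, seed = 1L, G = 3L)
  expect_identical(f@region, "tumor")
  expect_error(generateTissueField(g1, nTumorFoci = 2L, seed = 1L),
               "foci")
  g2 <- buildSpotGrid(0.1)    # two adjacent spots cannot host 2 separated foci
  expect_error(generateTissueField(g2, nTumorFoci = 2L, seed = 1L),
               "too small")
})

test_that("negative-binomial counts match the stated generative model", {
  g <- smallGrid(1.6)
  f <- generateTissueField(g, seed = 3L, G = 6L)
  f@geneWeights[] <- 0  # flat expression: every gene's mean = lib/G
  n <- nSpots(g)
  counts <- simulateExpression(f, librarySizeMean = 6000,
                               nbDispersion = 10, seed = 5L)
  mu <- 6000 / 6
  for (gi in seq_len(6)) {
    se <- sd(counts[, gi]) / sqrt(n)
    expect_lt(abs(mean(counts[, gi]) - mu), 3 * se)
  }

  # Poisson limit: huge dispersion (theta) drives variance/mean to 1
  cP <- simulateExpression(f, librarySizeMean = 6000, nbDispersion = 1e7,
                           seed = 5L)
  vmr <- apply(cP, 2, var) / apply(cP, 2, mean)
  expect_true(all(abs(vmr - 1) < 0.2))

  # determinism and error handling
  expect_identical(counts, simulateExpression(f, 6000, 10, seed = 5L))
  fBad <- f; fBad@loadings[1, 1] <- Inf
  expect_error(simulateExpression(fBad, 6000, 10, 1L), "non-finite")
})

test_that("NB marginals match analytic mean and variance at scale", {
  g <- buildSpotGrid(6.5)  # ~5000 spots
  f <- generateTissueField(g, seed = 2L, G = 4L)
  f@geneWeights[] <- 0
  theta <- 8
  mu <- 8000 / 4
  counts <- simulateExpression(f, librarySizeMean = 8000,
                               nbDispersion = theta, seed = 9L)
  n <- nrow(counts)
  varAn <- mu + mu^2 / theta
  for (gi in 1:4) {
    x <- counts[, gi]
    seMean <- sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - mu), 4 * seMean)
    # SE of the sample variance from the empirical fourth moment
    m4 <- mean((x - mean(x))^4)
    seVar <- sqrt((m4 - var(x)^2) / n)
    expect_lt(abs(var(x) - varAn), 4 * seVar)
  }
})

test_that("patch rendering follows the stated encoding and noise model", {
  g <- smallGrid(1.0)
  f <- generateTissueField(g, seed = 4L, G = 5L)
  clean <- noiselessProfile()

  # noise-free patches are exactly the deterministic encoding
  patch <- renderPatch(f, 3L, clean, patchPx = 8L, seed = 1L)
  enc <- encodeLoadings(f@loadings[3L, ], clean)
  expect_equal(apply(patch, 3, mean), enc, tolerance = 1e-12)
  expect_equal(apply(patch, 3, sd), rep(0, length(enc)))

  # identical loadings, same slide, no noise -> identical patches
  f2 <- f; f2@loadings[5L, ] <- f2@loadings[3L, ]
  expect_identical(renderPatch(f2, 3L, clean, 8L, seed = 1L),
                   renderPatch(f2, 5L, clean, 8L, seed = 99L))

  expect_error(renderPatch(f, 1L, clean, patchPx = 0L), "patchPx")

  # decoding error is smaller under the enhanced profile (200 spots)
  tr <- protocolProfile("traditional"); en <- protocolProfile("enhanced")
  idx <- seq_len(min(200L, nSpots(g)))
  madOf <- function(profile) {
    est <- t(vapply(idx, function(i) {
      p <- renderPatch(f, i, profile, 16L, seed = 1000L + i)
      decodeLoadings(apply(p, 3, mean), profile, ncol(f@loadings))
    }, numeric(ncol(f@loadings))))
    mean(abs(est - f@loadings[idx, ]))
  }
  expect_lt(madOf(en), madOf(tr))
})

test_that("loading recovery error grows with pixel noise", {
  g <- smallGrid(0.8)
  f <- generateTissueField(g, seed = 6L, G = 5L)
  noiseLevels <- c(0, 0.05, 0.15, 0.3, 0.6)
  err <- sapply(noiseLevels, function(ns) {
    prof <- protocolProfile("enhanced", pixelNoiseSd = ns,
                            stainVariability = 0, artifactRate = 0)
    mean(sapply(1:10, function(sd) {
      est <- t(vapply(seq_len(nSpots(g)), function(i) {
        p <- renderPatch(f, i, prof, 12L, seed = sd * 1000L + i)
        decodeLoadings(apply(p, 3, mean), prof, ncol(f@loadings))
      }, numeric(ncol(f@loadings))))
      mean(abs(est - f@loadings))
    }))
  })
  expect_true(all(diff(err) >= 0))
})

test_that("two-patient slides split the capture area at the midline", {
  s1 <- generateSlide(list(captureMm = 1.2), list(P = 4L, G = 6L),
                      protocolProfile("traditional"),
                      list(librarySizeMean = 4000), seed = 2L,
                      slideId = "one", nPatients = 1L)
  expect_equal(unique(colData(s1)$patient), "one_p1")

  s2 <- generateSlide(list(captureMm = 1.6), list(P = 4L, G = 6L),
                      protocolProfile("enhanced"),
                      list(librarySizeMean = 4000), seed = 2L,
                      slideId = "two", nPatients = 2L,
                      patientIds = c("A", "B"))
  xUm <- spotCoordsUm(spotGrid(s2))[, "x"]
  pat <- colData(s2)$patient
  expect_identical(unname(pat == "A"), unname(xUm < 800))
  expect_identical(unname(pat == "B"), unname(xUm >= 800))

  # byte-identical serialization under a fixed seed
  s2b <- generateSlide(list(captureMm = 1.6), list(P = 4L, G = 6L),
                       protocolProfile("enhanced"),
                       list(librarySizeMean = 4000), seed = 2L,
                       slideId = "two", nPatients = 2L,
                       patientIds = c("A", "B"))
  expect_identical(serialize(s2, NULL), serialize(s2b, NULL))
})

test_that("serial pairs share their expression-generating field", {
  fp <- list(P = 4L, G = 20L)
  ep <- list(librarySizeMean = 10000, nbDispersion = 10)
  pair <- generateSerialPair(fp, ep, jitter = 0, seed = 3L,
                             gridSpec = list(captureMm = 1.2))
  expect_identical(pair$traditional@field@loadings,
                   pair$enhanced@field@loadings)
  expect_equal(protocol(pair$traditional)@name, "traditional")
  expect_equal(protocol(pair$enhanced)@name, "enhanced")

  # with zero jitter, per-gene Spearman between count matrices is high
  cT <- t(assay(pair$traditional, "counts"))
  cE <- t(assay(pair$enhanced, "counts"))
  rho <- vapply(seq_len(ncol(cT)),
                function(gi) spearmanScore(cT[, gi], cE[, gi]), numeric(1))
  expect_gt(median(rho), 0.9)

  # increasing jitter decreases mean inter-section correlation
  meanRho <- function(j) {
    mean(sapply(1:10, function(sd) {
      p <- generateSerialPair(fp, ep, jitter = j, seed = sd,
                              gridSpec = list(captureMm = 0.8))
      a <- t(assay(p$traditional, "counts"))
      b <- t(assay(p$enhanced, "counts"))
      mean(vapply(seq_len(ncol(a)),
                  function(gi) spearmanScore(a[, gi], b[, gi]),
                  numeric(1)), na.rm = TRUE)
    }))
  }
  rhos <- vapply(c(0, 0.5, 1.5), meanRho, numeric(1))
  expect_true(all(diff(rhos) < 0))
})

test_that("cohorts mirror the study design deterministically", {
  cfg <- cohortConfig(seed = 5L, genes = 8L, captureMm = 1.0)
  coh <- generateCohort(cfg)
  d <- cohortDesign(coh)
  expect_equal(nrow(d), 10L)
  expect_equal(sum(d$role == "validation"), 2L)
  expect_equal(sum(d$protocol == "traditional" & d$role == "train"), 4L)
  # enhanced training areas carry two patients each
  enh <- d[d$protocol == "enhanced" & d$role == "train", ]
  expect_true(all(grepl(";", enh$patients)))

  # no training slides: only the serial pair remains
  coh0 <- generateCohort(cohortConfig(nTrainingSlidesPerProtocol = 0L,
                                      seed = 5L, genes = 8L,
                                      captureMm = 1.0))
  expect_equal(nrow(cohortDesign(coh0)), 2L)
  expect_setequal(cohortDesign(coh0)$role, "validation")

  # same seed: hash-equal serialization; different seed: same design,
  # different counts
  cohB <- generateCohort(cfg)
  expect_identical(serialize(coh, NULL), serialize(cohB, NULL))
  coh2 <- generateCohort(cohortConfig(seed = 6L, genes = 8L,
                                      captureMm = 1.0))
  expect_identical(cohortDesign(coh2)[c("capture_area", "protocol", "role")],
                   d[c("capture_area", "protocol", "role")])
  expect_false(identical(assay(cohortSlides(coh2)[[1]], "counts"),
                         assay(cohortSlides(coh)[[1]], "counts")))
})
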