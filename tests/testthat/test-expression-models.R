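test_that("Moran's I agrees with the double-sum oracle and ranks genes", {
  g <- smallGrid(1.2)  # < 200 spots
  n <- nSpots(g)
  set.seed(11)
  vals <- matrix(rnorm(n * 3), n, 3)
  xy <- spotCoordsUm(g)
  nbrs <- spotNeighbors(g)
  for (j in 1:3) {
    expect_equal(moranI(vals[, j], nbrs), bruteMoran(vals[, j], xy),
                 tolerance = 1e-10)
  }

  # a smooth spatial gradient outranks i.i.d. noise; a constant gene
  # ranks last with I = 0
  counts <- cbind(
    noise = rpois(n, 20),
    gradient = round(xy[, "x"] / 20),
    flat = rep(5L, n))
  ranked <- rankSpatiallyVariable(counts, g)
  expect_equal(ranked[1], "gradient")
  expect_equal(ranked[3], "flat")
  expect_equal(unname(attr(ranked, "moranI")["flat"]), 0)
  expect_equal(attr(ranked, "selector"), "moran")

  # permutation invariance with consistent coordinates
  perm <- sample(n)
  ranked2 <- rankSpatiallyVariable(counts[perm, ], g[perm])
  expect_identical(as.character(ranked2), as.character(ranked))

  expect_error(rankSpatiallyVariable(counts, g, topK = 10), "topK")
})

test_that("targets follow the offset-1 log and strict-median rules", {
  tg <- makeTargets(matrix(0:3, 4, 1, dimnames = list(NULL, "g1")))
  expect_equal(unname(tg@continuous[, 1]), log(1:4))
  expect_equal(unname(tg@binary[, 1]), c(0, 0, 1, 1))

  tgEq <- makeTargets(matrix(7L, 5, 2))
  expect_true(all(tgEq@binary == 0))  # ties at the median are class 0
  expect_true(all(tgEq@continuous == log(8)))
})

test_that("training is deterministic and reaches the noise-free ceiling", {
  prof <- noiselessProfile()
  W <- generateGeneWeights(4L, 10L, seed = 99L)  # one gene map, both slides
  mk <- function(id, seed) generateSlide(
    list(captureMm = 1.2), list(P = 4L, G = 10L, geneWeights = W), prof,
    list(librarySizeMean = 20000, nbDispersion = 50), seed = seed,
    slideId = id)
  s1 <- mk("a", 21L); s2 <- mk("b", 22L)

  m <- trainGeneModels(list(a = s1, b = s2), seed = 5L)
  m2 <- trainGeneModels(list(a = s1, b = s2), seed = 5L)
  expect_identical(m@contCoefs, m2@contCoefs)
  expect_identical(m@binCoefs, m2@binCoefs)

  # noise-free synthetic slides: per-gene training Spearman near ceiling
  truth <- makeTargets(rbind(t(assay(s1, "counts")), t(assay(s2, "counts"))))
  rho <- vapply(seq_along(m@geneIds), function(gi) {
    spearmanScore(truth@continuous[, gi], m@trainFitted$continuous[, gi])
  }, numeric(1))
  expect_gt(min(rho), 0.95)

  # binary and continuous heads rank spots concordantly
  for (gi in seq_along(m@geneIds)) {
    expect_gt(spearmanScore(m@trainFitted$continuous[, gi],
                            m@trainFitted$binaryScore[, gi]), 0)
  }
})

test_that("shuffled labels give chance-level held-out AUC", {
  prof <- protocolProfile("enhanced")
  s1 <- generateSlide(list(captureMm = 1.2), list(P = 4L, G = 10L), prof,
                      list(librarySizeMean = 8000), seed = 31L,
                      slideId = "tr")
  s2 <- generateSlide(list(captureMm = 1.2), list(P = 4L, G = 10L), prof,
                      list(librarySizeMean = 8000), seed = 32L,
                      slideId = "te")
  # break the morphology-expression link by permuting spots' counts
  set.seed(1)
  perm <- sample(ncol(s1))
  shuffled <- makeSlideFromCounts(t(assay(s1, "counts"))[perm, ],
                                  spotGrid(s1), region = regions(s1),
                                  profile = protocol(s1),
                                  imageSource = s1@imageSource,
                                  slideId = "shuffled")
  m <- trainGeneModels(list(tr = shuffled), seed = 5L)
  pred <- predictExpression(m, s2)
  truth <- makeTargets(s2, m@geneIds)
  auc <- vapply(seq_along(m@geneIds), function(gi) {
    suppressWarnings(aucScore(truth@binary[, gi], pred$binaryScore[, gi]))
  }, numeric(1))
  expect_lt(abs(mean(auc, na.rm = TRUE) - 0.5), 0.05)
})

test_that("prediction reproduces fitted values and handles constant images", {
  rs <- rasterSlide(nTiles = 4L, patchPx = 8L, seed = 3)
  m <- trainGeneModels(list(fixture = rs$slide), spec = predictorSpec(patchPx = 8L),
                       seed = 2L)
  pred <- predictExpression(m, rs$slide)
  expect_equal(pred$continuous, m@trainFitted$continuous,
               ignore_attr = TRUE)
  expect_equal(pred$binaryScore, m@trainFitted$binaryScore,
               ignore_attr = TRUE)

  # constant image: identical predictions at every spot
  const <- rs
  const$slide@imageSource <- new("RasterImageSource",
                                 image = array(0.5, dim(rs$image)))
  predC <- predictExpression(m, const$slide)
  expect_equal(apply(predC$continuous, 2, function(v) max(v) - min(v)),
               rep(0, ncol(predC$continuous)), ignore_attr = TRUE)
})

test_that("superresolution at stride = patch reproduces spot predictions", {
  rs <- rasterSlide(nTiles = 4L, patchPx = 8L, seed = 5)
  m <- trainGeneModels(list(fixture = rs$slide),
                       spec = predictorSpec(patchPx = 8L), seed = 2L)
  sr <- superresolve(m, rs$image, patchSpec(8L, 8L))
  expect_equal(nrow(sr$positions), 16L)
  predSpot <- predictExpression(m, rs$slide)
  # grid order is row-major over tiles, matching position order
  expect_equal(sr$continuous, predSpot$continuous, ignore_attr = TRUE)

  # halving the stride densifies the map per the formula
  sr2 <- superresolve(m, rs$image, patchSpec(8L, 4L))
  expect_equal(nrow(sr2$positions), 49L)
})

test_that("held-out correlation rises with signal gain", {
  gains <- c(0.3, 0.55, 0.8, 1)
  seeds <- 1:10
  W <- generateGeneWeights(4L, 8L, seed = 77L)
  meanRho <- sapply(gains, function(gn) {
    mean(sapply(seeds, function(sd) {
      prof <- protocolProfile("enhanced", signalGain = gn)
      fp <- list(P = 4L, G = 8L, geneWeights = W)
      tr <- generateSlide(list(captureMm = 1.0), fp,
                          prof, list(librarySizeMean = 8000),
                          seed = 100L + sd, slideId = "tr")
      te <- generateSlide(list(captureMm = 1.0), fp,
                          prof, list(librarySizeMean = 8000),
                          seed = 200L + sd, slideId = "te")
      m <- trainGeneModels(list(tr = tr),
                           spec = predictorSpec(heads = "continuous"),
                           seed = sd)
      pred <- predictExpression(m, te)
      truth <- makeTargets(te, m@geneIds)
      mean(vapply(seq_along(m@geneIds), function(gi) {
        spearmanScore(truth@continuous[, gi], pred$continuous[, gi])
      }, numeric(1)), na.rm = TRUE)
    }))
  })
  expect_true(all(diff(meanRho) > 0))
})
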