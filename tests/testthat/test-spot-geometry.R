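test_that("hexagonal grid matches the Visium lattice geometry", {
  g <- buildSpotGrid(6.5)
  expect_gte(nSpots(g), 4500)
  expect_lte(nSpots(g), 5000)

  # hand enumeration for a capture area of exactly one pitch: rows at
  # y = 0 and y = 100*sqrt(3)/2 < 100 each hold one spot (x = 0 even row,
  # x = 50 odd row)
  g1 <- buildSpotGrid(0.1)
  expect_equal(nSpots(g1), 2L)
  expect_equal(spotCoordsUm(g1)[, "x"], c(0, 50), ignore_attr = TRUE)

  # nearest-neighbor distances equal the pitch
  gs <- buildSpotGrid(0.8)
  xy <- spotCoordsUm(gs)
  d <- as.matrix(dist(xy)); diag(d) <- Inf
  expect_equal(min(d), 100, tolerance = 1e-9)

  expect_error(buildSpotGrid(0.05), "pitch")
  expect_error(buildSpotGrid(-1), "positive")
})

test_that("pixel coordinates scale with resolution; spot set does not", {
  g1 <- buildSpotGrid(1.4, resolutionUmPerPx = 1)
  g2 <- buildSpotGrid(1.4, resolutionUmPerPx = 2)
  expect_identical(g1@arrayRow, g2@arrayRow)
  expect_identical(g1@arrayCol, g2@arrayCol)
  expect_equal(g2@pxlRow, g1@pxlRow / 2)
  expect_equal(g2@pxlCol, g1@pxlCol / 2)
  expect_equal(nSpots(g1), nSpots(g2))
})

test_that("grid adjacency matches the exhaustive distance oracle", {
  g <- smallGrid(1.0)
  got <- spotNeighbors(g)
  want <- bruteNeighbors(g)
  for (i in seq_len(nSpots(g))) {
    expect_setequal(got[[i]], want[[i]])
  }
})

test_that("capture mask is circular, centered and rotation-symmetric", {
  m1 <- spotCaptureMask(5, 1)
  expect_equal(sum(m1), 1L)
  expect_true(m1[3, 3])

  m <- spotCaptureMask(130, 130)
  expect_lt(abs(sum(m) - pi * 65^2) / (pi * 65^2), 0.01)
  expect_identical(m, t(m)[, rev(seq_len(130))])  # 90-degree rotation
})

test_that("superresolution positions obey the stride formula", {
  pos <- superresolutionPositions(1024, 1024, patchSpec(512, 128))
  expect_equal(nrow(pos), 25L)
  expect_equal(pos$row[1], 0)
  expect_equal(max(pos$row) + 512, 1024)

  # stride = patch tiles without overlap
  pos2 <- superresolutionPositions(64, 96, patchSpec(32, 32))
  expect_equal(nrow(pos2), 2L * 3L)
  expect_equal(sort(unique(pos2$col)), c(0, 32, 64))

  expect_equal(nrow(superresolutionPositions(512, 512, patchSpec(512, 7))), 1L)
  expect_error(superresolutionPositions(100, 100, patchSpec(512, 128)),
               "smaller")

  # property: count per axis = floor((dim - patch)/stride) + 1
  set.seed(42)
  for (rep in 1:20) {
    p <- sample(4:32, 1); s <- sample(seq_len(p), 1)
    h <- p + sample(0:50, 1); w <- p + sample(0:50, 1)
    pos <- superresolutionPositions(h, w, patchSpec(p, s))
    expect_equal(nrow(pos),
                 (floor((h - p) / s) + 1) * (floor((w - p) / s) + 1))
  }
})

test_that("spot-centered patches equal a direct slicing oracle", {
  set.seed(7)
  img <- array(seq_len(20 * 24), c(20, 24, 1))  # unique pixel values
  grid <- new("SpotGrid", barcode = c("a", "b"),
              arrayRow = c(0L, 0L), arrayCol = c(0L, 1L),
              pxlRow = c(10, 6), pxlCol = c(12, 7),
              spotDiameterUm = 55, pitchUm = 100, resolutionUmPerPx = 1)
  res <- extractSpotPatches(img, grid, patchSpec(4, 4))
  # half-open window with top-left at center - p/2
  expect_equal(res$patches[[1]][, , 1], img[9:12, 11:14, 1])
  expect_equal(res$patches[[2]][, , 1], img[5:8, 6:9, 1])
  expect_false(any(res$padded))

  # constant image: all patches identical
  cimg <- array(0.3, c(20, 24, 2))
  resC <- extractSpotPatches(cimg, grid, patchSpec(4, 4))
  expect_identical(resC$patches[[1]], resC$patches[[2]])

  # border spot: per-spot error record without padding, flagged with it
  gridB <- new("SpotGrid", barcode = "edge", arrayRow = 0L, arrayCol = 0L,
               pxlRow = 1, pxlCol = 1, spotDiameterUm = 55, pitchUm = 100,
               resolutionUmPerPx = 1)
  resE <- extractSpotPatches(img, gridB, patchSpec(6, 6), pad = "none")
  expect_null(resE$patches[[1]])
  expect_match(resE$errors[1], "edge")
  resP <- extractSpotPatches(img, gridB, patchSpec(6, 6))
  expect_true(resP$padded[1])
  expect_equal(dim(resP$patches[[1]]), c(6L, 6L, 1L))
})

test_that("tiling patches reassemble the image exactly", {
  rs <- rasterSlide(nTiles = 3L, patchPx = 6L)
  res <- extractSpotPatches(rs$image, rs$grid, patchSpec(6, 6))
  rebuilt <- array(NA_real_, dim(rs$image))
  for (i in seq_len(nSpots(rs$grid))) {
    r0 <- rs$grid@pxlRow[i] - 3; c0 <- rs$grid@pxlCol[i] - 3
    rebuilt[r0 + 1:6, c0 + 1:6, ] <- res$patches[[i]]
  }
  expect_equal(rebuilt, rs$image)
})

test_that("tissue_positions round trip is exact", {
  g <- buildSpotGrid(0.9, resolutionUmPerPx = 3)  # non-integer pixels
  path <- tempfile(fileext = ".csv")
  writeTissuePositions(g, path)
  g2 <- readTissuePositions(path, spotDiameterUm = g@spotDiameterUm,
                            pitchUm = g@pitchUm,
                            resolutionUmPerPx = g@resolutionUmPerPx)
  expect_identical(g2@barcode, g@barcode)
  expect_identical(g2@arrayRow, g@arrayRow)
  expect_equal(g2@pxlRow, g@pxlRow)
  expect_equal(g2@pxlCol, g@pxlCol)
})
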