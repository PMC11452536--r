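# fixtures built in code; no stored data

suppressPackageStartupMessages(library(SummarizedExperiment))

# a noise-free protocol: deterministic rendering at full signal
noiselessProfile <- function(name = "traditional") {
  protocolProfile(name, pixelNoiseSd = 0, stainVariability = 0,
                  signalGain = 1, artifactRate = 0)
}

# small hexagonal grid (~170 spots at 1.2 mm)
smallGrid <- function(captureMm = 1.2, resolutionUmPerPx = 4) {
  buildSpotGrid(captureMm, resolutionUmPerPx = resolutionUmPerPx)
}

# assemble a Slide from an explicit spots x G count matrix
makeSlideFromCounts <- function(counts, grid,
                                region = rep("distal", nrow(counts)),
                                profile = protocolProfile("traditional"),
                                imageSource = NULL, field = NULL,
                                slideId = "fixture", role = "train") {
  geneIds <- colnames(counts)
  if (is.null(geneIds)) geneIds <- sprintf("gene%03d", seq_len(ncol(counts)))
  se <- SummarizedExperiment(
    assays = list(counts = t(unname(counts))),
    rowData = S4Vectors::DataFrame(gene_id = geneIds, row.names = geneIds),
    colData = S4Vectors::DataFrame(region = region,
                                   patient = "P1",
                                   row.names = grid@barcode))
  new("Slide", se, spotGrid = grid, protocol = profile,
      imageSource = imageSource, field = field, slideId = slideId,
      role = role)
}

# a Slide whose image source is a raster aligned with a tiling grid:
# nTiles x nTiles patches of side patchPx, spot centers at tile centers
rasterSlide <- function(nTiles = 4L, patchPx = 8L, nChannels = 1L,
                        counts = NULL, seed = 1) {
  side <- nTiles * patchPx
  set.seed(seed)
  img <- array(runif(side * side * nChannels), c(side, side, nChannels))
  centers <- (seq_len(nTiles) - 1L) * patchPx + patchPx / 2
  pos <- expand.grid(col = centers, row = centers)[, c("row", "col")]
  n <- nrow(pos)
  grid <- new("SpotGrid",
              barcode = sprintf("rs_%02d", seq_len(n)),
              arrayRow = as.integer(rep(seq_len(nTiles) - 1L,
                                        each = nTiles)),
              arrayCol = as.integer(rep(seq_len(nTiles) - 1L, nTiles)),
              pxlRow = pos$row, pxlCol = pos$col,
              spotDiameterUm = 55, pitchUm = 100,
              resolutionUmPerPx = 0.5)
  if (is.null(counts)) {
    counts <- matrix(rpois(n * 5, 20), n, 5,
                     dimnames = list(NULL, sprintf("gene%03d", 1:5)))
  }
  slide <- makeSlideFromCounts(counts, grid,
                               imageSource = new("RasterImageSource",
                                                 image = img))
  list(slide = slide, image = img, grid = grid, patchPx = patchPx)
}

# brute-force O(n^2) pair-counting AUC oracle
bruteAuc <- function(labels, scores) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# brute-force Mann-Whitney U oracle (x over y)
bruteU <- function(x, y) {
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot
}

# O(n^2) double-sum Moran's I oracle with row-standardized weights over
# the hexagonal adjacency (centers within 1.05 * pitch)
bruteMoran <- function(values, xy, pitchUm = 100, tol = 1.05) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    d[i] <- Inf
    nb <- which(d <= tol * pitchUm)
    if (length(nb)) {
      for (j in nb) num <- num + z[i] * z[j] / length(nb)
    }
  }
  num / sum(z^2)
}

# exhaustive neighbor oracle: indices within tol * pitch
bruteNeighbors <- function(grid, tol = 1.05) {
  xy <- spotCoordsUm(grid)
  n <- nrow(xy)
  lapply(seq_len(n), function(i) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    setdiff(which(d <= tol * grid@pitchUm), i)
  })
}

# deterministic synthetic value function over named players: values are
# reproducible functions of the subset identity
randomValueFunction <- function(ids, seed) {
  valueFunction(ids, function(subset) {
    key <- paste(sort(subset), collapse = "+")
    codes <- utf8ToInt(key)
    h <- seed
    for (k in codes) h <- (h * 31 + k) %% 1e6
    0.5 + (h / 1e6 - 0.5) * 0.4
  }, vEmpty = 0.5)
}
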