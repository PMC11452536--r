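#' @include AllClasses.R AllGenerics.R
NULL

#' Microns per pixel implied by a magnification label
#'
#' Fixed mappings used throughout: 40x corresponds to 0.25 um/px and 20x
#' to 0.5 um/px.
#'
#' @param magnification `"20x"` or `"40x"`.
#' @return microns per pixel.
#' @export
magnificationResolution <- function(magnification) {
  switch(match.arg(magnification, c("20x", "40x")),
         "20x" = 0.5, "40x" = 0.25)
}

#' Construct a PatchSpec
#'
#' @param patchPx patch side length in pixels (default 512, the sub-image
#'   size used for spot-centered crops at 40x).
#' @param stridePx window increment for superresolution inference
#'   (default 128 pixels, about 32 um at 40x).
#' @param magnification `"20x"` or `"40x"`.
#' @return a [PatchSpec-class].
#' @examples
#' patchSpec(512, 128, "40x")
#' @export
patchSpec <- function(patchPx = 512L, stridePx = 128L, magnification = "40x") {
  new("PatchSpec", patchPx = .assertCount(patchPx, "patchPx"),
      stridePx = .assertCount(stridePx, "stridePx"),
      magnification = match.arg(magnification, c("20x", "40x")))
}

#' Build a hexagonal-offset Visium spot grid
#'
#' Spots sit on a hexagonal-offset lattice: odd array rows are shifted half
#' a pitch to the right and rows are spaced `pitchUm * sqrt(3)/2` apart, so
#' nearest-neighbor center distances equal the pitch in all directions.
#' Centers with physical coordinates in the half-open square
#' `[0, captureMm)` are kept. Pixel coordinates are micron positions
#' divided by `resolutionUmPerPx`; changing the resolution rescales pixel
#' coordinates only and never changes the spot set.
#'
#' @param captureMm capture-area side length in millimeters (Visium: 6.5
#'   or 11).
#' @param spotDiameterUm spot diameter in microns (default 55).
#' @param pitchUm center-to-center distance in microns (default 100).
#' @param resolutionUmPerPx image resolution in microns per pixel.
#' @param barcodePrefix prefix for generated barcodes.
#' @return a [SpotGrid-class].
#' @examples
#' g <- buildSpotGrid(6.5)
#' nSpots(g)   # 4940 spots, consistent with "up to 5000"
#' @export
buildSpotGrid <- function(captureMm, spotDiameterUm = 55, pitchUm = 100,
                          resolutionUmPerPx = 0.5, barcodePrefix = "spot") {
  .assertScalarPositive(captureMm, "captureMm")
  .assertScalarPositive(spotDiameterUm, "spotDiameterUm")
  .assertScalarPositive(pitchUm, "pitchUm")
  .assertScalarPositive(resolutionUmPerPx, "resolutionUmPerPx")
  captureUm <- captureMm * 1000
  if (captureUm < pitchUm) {
    stop("capture area must be at least one pitch wide", call. = FALSE)
  }
  rowStep <- pitchUm * sqrt(3) / 2
  nRows <- floor((captureUm - 1e-9) / rowStep) + 1
  rows <- integer(0); cols <- integer(0)
  for (r in seq_len(nRows) - 1L) {
    offset <- if (r %% 2L == 1L) pitchUm / 2 else 0
    nCols <- floor((captureUm - offset - 1e-9) / pitchUm) + 1
    if (offset >= captureUm) next
    rows <- c(rows, rep.int(r, nCols))
    cols <- c(cols, seq_len(nCols) - 1L)
  }
  xUm <- cols * pitchUm + ifelse(rows %% 2L == 1L, pitchUm / 2, 0)
  yUm <- rows * rowStep
  new("SpotGrid",
      barcode = sprintf("%s_%03d_%03d", barcodePrefix, rows, cols),
      arrayRow = as.integer(rows), arrayCol = as.integer(cols),
      pxlRow = yUm / resolutionUmPerPx, pxlCol = xUm / resolutionUmPerPx,
      spotDiameterUm = spotDiameterUm, pitchUm = pitchUm,
      resolutionUmPerPx = resolutionUmPerPx)
}

#' @describeIn buildSpotGrid number of spots in a grid.
#' @param x a SpotGrid.
#' @export
setMethod("nSpots", "SpotGrid", function(x) length(x@barcode))

setMethod("show", "SpotGrid", function(object) {
  cat(sprintf("SpotGrid with %d spots (pitch %.0f um, spot %.0f um, %.3g um/px)\n",
              nSpots(object), object@pitchUm, object@spotDiameterUm,
              object@resolutionUmPerPx))
})

#' Coerce a SpotGrid to a data.frame in tissue_positions order
#'
#' @param x a SpotGrid.
#' @param row.names,optional,... passed for generic compatibility; unused.
#' @return data.frame with columns barcode, in_tissue, array_row,
#'   array_col, pxl_row, pxl_col.
#' @export
as.data.frame.SpotGrid <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(barcode = x@barcode, in_tissue = 1L,
             array_row = x@arrayRow, array_col = x@arrayCol,
             pxl_row = x@pxlRow, pxl_col = x@pxlCol,
             stringsAsFactors = FALSE)
}

#' Physical micron coordinates of spot centers
#' @param grid a SpotGrid.
#' @return two-column matrix (x, y) in microns.
#' @export
spotCoordsUm <- function(grid) {
  cbind(x = grid@pxlCol * grid@resolutionUmPerPx,
        y = grid@pxlRow * grid@resolutionUmPerPx)
}

#' Grid adjacency under the hexagonal lattice
#'
#' Two spots are neighbors when their center distance is at most
#' `tol * pitch` (default 1.05, capturing the six hexagonal neighbors).
#'
#' @param grid a SpotGrid.
#' @param tol multiple of the pitch defining adjacency.
#' @return list of integer neighbor-index vectors, one per spot.
#' @export
spotNeighbors <- function(grid, tol = 1.05) {
  xy <- spotCoordsUm(grid)
  n <- nrow(xy)
  cutoff <- grid@pitchUm * tol
  # bucket by array row: neighbors live in the same or adjacent rows
  byRow <- split(seq_len(n), grid@arrayRow)
  rowKeys <- as.integer(names(byRow))
  out <- vector("list", n)
  for (ri in seq_along(rowKeys)) {
    cand <- unlist(byRow[as.character(rowKeys[ri] + c(-1L, 0L, 1L))],
                   use.names = FALSE)
    for (i in byRow[[ri]]) {
      d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
      nb <- cand[d2 <= cutoff^2 & cand != i]
      out[[i]] <- nb
    }
  }
  out
}

#' Circular spot capture mask
#'
#' Boolean mask of the circular capture zone of a spot, centered in a
#' square patch (e.g. the 130-pixel-diameter zone of a 55 um spot at 20x).
#' Pixel centers at 0-based coordinates; a pixel is inside when its center
#' lies within `diameterPx / 2` of the patch center `(patchPx - 1) / 2`.
#'
#' @param patchPx patch side length in pixels.
#' @param diameterPx mask diameter in pixels.
#' @return patchPx x patchPx logical matrix.
#' @examples
#' sum(spotCaptureMask(130, 130)) / (pi * 65^2)  # ~1
#' @export
spotCaptureMask <- function(patchPx, diameterPx) {
  patchPx <- .assertCount(patchPx, "patchPx")
  .assertScalarPositive(diameterPx, "diameterPx")
  ctr <- (patchPx - 1) / 2
  idx <- seq_len(patchPx) - 1
  d2 <- outer((idx - ctr)^2, (idx - ctr)^2, "+")
  d2 <= (diameterPx / 2)^2
}

#' Superresolution window positions
#'
#' Top-left corners of every `patchPx`-sized window whose origin is a
#' multiple of `stridePx` and which fits inside the image; row-major
#' order. Per axis there are `floor((dim - patchPx)/stridePx) + 1`
#' positions.
#'
#' @param imageH,imageW image height and width in pixels.
#' @param spec a [PatchSpec-class].
#' @return data.frame with 0-based `row`, `col` window origins and the
#'   window centers `centerRow`, `centerCol`.
#' @examples
#' nrow(superresolutionPositions(1024, 1024, patchSpec(512, 128)))  # 25
#' @export
superresolutionPositions <- function(imageH, imageW, spec) {
  stopifnot(is(spec, "PatchSpec"))
  p <- spec@patchPx; s <- spec@stridePx
  if (imageH < p || imageW < p) {
    stop("image is smaller than the patch size", call. = FALSE)
  }
  rows <- seq.int(0L, by = s, length.out = floor((imageH - p) / s) + 1L)
  cols <- seq.int(0L, by = s, length.out = floor((imageW - p) / s) + 1L)
  pos <- expand.grid(col = cols, row = rows)[, c("row", "col")]
  pos$centerRow <- pos$row + p / 2
  pos$centerCol <- pos$col + p / 2
  rownames(pos) <- NULL
  pos
}

# slice one half-open window [r0, r0+p) x [c0, c0+p) out of an image array,
# optionally reflect-padding at the borders
.sliceWindow <- function(image, r0, c0, p, pad = c("reflect", "none")) {
  pad <- match.arg(pad)
  h <- dim(image)[1]; w <- dim(image)[2]
  rIdx <- seq.int(r0 + 1L, length.out = p)
  cIdx <- seq.int(c0 + 1L, length.out = p)
  padded <- any(rIdx < 1L) || any(rIdx > h) || any(cIdx < 1L) || any(cIdx > w)
  if (padded) {
    if (pad == "none") return(NULL)
    reflect <- function(i, n) {
      # reflect 1-based indices into [1, n] (edge-mirrored)
      j <- (i - 1L) %% (2L * n)
      j <- ifelse(j >= n, 2L * n - 1L - j, j)
      j + 1L
    }
    rIdx <- reflect(rIdx, h); cIdx <- reflect(cIdx, w)
  }
  list(patch = image[rIdx, cIdx, , drop = FALSE], padded = padded)
}

#' Extract spot-centered image patches
#'
#' One square patch per spot, centered at the spot's pixel coordinates,
#' using half-open windows `[c - p/2, c + p/2)` under the 0-based
#' pixel-center convention. Patch order matches grid order. Spots whose
#' window crosses the image border are reflect-padded by default and
#' flagged; with `pad = "none"` they yield a per-spot error record instead
#' of being dropped silently.
#'
#' @param image h x w x channels numeric array (a 2-d matrix is treated as
#'   one channel), or a [RasterImageSource-class].
#' @param grid a [SpotGrid-class].
#' @param spec a [PatchSpec-class].
#' @param pad `"reflect"` (default) or `"none"`.
#' @return list with `patches` (list of arrays, NULL where extraction
#'   failed), `padded` logical per spot, and `errors` character per spot
#'   (NA when extraction succeeded).
#' @export
extractSpotPatches <- function(image, grid, spec, pad = c("reflect", "none")) {
  pad <- match.arg(pad)
  if (is(image, "RasterImageSource")) image <- image@image
  if (length(dim(image)) == 2L) {
    image <- array(image, dim = c(dim(image), 1L))
  }
  p <- spec@patchPx
  n <- nSpots(grid)
  patches <- vector("list", n)
  padded <- logical(n)
  errors <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    r0 <- as.integer(round(grid@pxlRow[i] - p / 2))
    c0 <- as.integer(round(grid@pxlCol[i] - p / 2))
    sl <- .sliceWindow(image, r0, c0, p, pad)
    if (is.null(sl)) {
      errors[i] <- sprintf("spot %s: window [%d,%d)x[%d,%d) exceeds image bounds",
                           grid@barcode[i], r0, r0 + p, c0, c0 + p)
    } else {
      patches[[i]] <- sl$patch
      padded[i] <- sl$padded
    }
  }
  list(patches = patches, padded = padded, errors = errors,
       padPolicy = pad)
}
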