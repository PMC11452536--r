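#' @include AllClasses.R AllGenerics.R synthetic-cohort.R
#' @importFrom Matrix readMM writeMM Matrix
#' @importFrom utils read.csv read.delim write.csv write.table
#' @importFrom jsonlite write_json read_json
NULL

#' Write a spot grid as a tissue_positions.csv
#'
#' Visium-dialect table with columns barcode, in_tissue, array_row,
#' array_col, pxl_row, pxl_col. Full double precision is kept so a
#' read-back reproduces the grid exactly.
#'
#' @param grid a [SpotGrid-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTissuePositions <- function(grid, path) {
  df <- as.data.frame(grid)
  df$pxl_row <- format(df$pxl_row, digits = 17, trim = TRUE,
                       scientific = FALSE)
  df$pxl_col <- format(df$pxl_col, digits = 17, trim = TRUE,
                       scientific = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tissue_positions.csv into a SpotGrid
#'
#' @param path file path.
#' @param spotDiameterUm,pitchUm,resolutionUmPerPx physical geometry not
#'   stored in the table.
#' @return a [SpotGrid-class] (in-tissue spots only).
#' @export
readTissuePositions <- function(path, spotDiameterUm = 55, pitchUm = 100,
                                resolutionUmPerPx = 0.5) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row", "pxl_col")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: missing columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  df <- df[df$in_tissue == 1L, , drop = FALSE]
  new("SpotGrid", barcode = as.character(df$barcode),
      arrayRow = as.integer(df$array_row),
      arrayCol = as.integer(df$array_col),
      pxlRow = as.numeric(df$pxl_row), pxlCol = as.numeric(df$pxl_col),
      spotDiameterUm = spotDiameterUm, pitchUm = pitchUm,
      resolutionUmPerPx = resolutionUmPerPx)
}

#' Write a slide as a Visium-style bundle
#'
#' Counts go to `matrix.mtx` (genes x spots, Matrix Market) with
#' `features.tsv` and `barcodes.tsv`; geometry to `tissue_positions.csv`;
#' per-spot region annotations to `regions.tsv` (barcode, region); and a
#' `manifest.json` records the slide id, protocol, role and geometry.
#'
#' @param slide a [Slide-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeVisiumBundle <- function(slide, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- assay(slide, "counts")
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  write.table(data.frame(id = rownames(slide), name = rownames(slide),
                         type = "Gene Expression"),
              file.path(dir, "features.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(data.frame(barcode = colnames(slide)),
              file.path(dir, "barcodes.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeTissuePositions(spotGrid(slide), file.path(dir, "tissue_positions.csv"))
  write.table(data.frame(barcode = colnames(slide),
                         region = regions(slide)),
              file.path(dir, "regions.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  g <- spotGrid(slide)
  jsonlite::write_json(
    list(slide_id = slide@slideId, protocol = protocol(slide)@name,
         role = slide@role, spot_diameter_um = g@spotDiameterUm,
         pitch_um = g@pitchUm, resolution_um_per_px = g@resolutionUmPerPx),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a Visium-style bundle into a Slide
#'
#' Parses the Matrix Market counts, features/barcodes TSVs,
#' tissue_positions.csv and, when present, regions.tsv and manifest.json.
#' Barcode agreement between the matrix and the positions table is
#' validated; mismatches are reported by barcode. The returned slide has
#' no image source.
#'
#' @param dir bundle directory.
#' @return a [Slide-class].
#' @export
readVisiumBundle <- function(dir) {
  mtxPath <- file.path(dir, "matrix.mtx")
  counts <- tryCatch(as.matrix(Matrix::readMM(mtxPath)),
                     error = function(e) {
                       stop(sprintf("%s: malformed Matrix Market file (%s)",
                                    mtxPath, conditionMessage(e)),
                            call. = FALSE)
                     })
  if (ncol(counts) == 0L) {
    stop(sprintf("%s: empty slide (0 spots)", dir), call. = FALSE)
  }
  feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  barcodes <- read.delim(file.path(dir, "barcodes.tsv"), header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  if (nrow(feats) != nrow(counts) || length(barcodes) != ncol(counts)) {
    stop(sprintf("%s: matrix is %d x %d but features/barcodes give %d x %d",
                 dir, nrow(counts), ncol(counts), nrow(feats),
                 length(barcodes)), call. = FALSE)
  }
  dimnames(counts) <- list(feats[[1]], barcodes)
  manifest <- if (file.exists(file.path(dir, "manifest.json"))) {
    jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  } else list()
  grid <- readTissuePositions(
    file.path(dir, "tissue_positions.csv"),
    spotDiameterUm = manifest$spot_diameter_um %||% 55,
    pitchUm = manifest$pitch_um %||% 100,
    resolutionUmPerPx = manifest$resolution_um_per_px %||% 0.5)
  missing <- setdiff(barcodes, grid@barcode)
  if (length(missing)) {
    stop(sprintf("%s: positions file is missing barcodes: %s", dir,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  grid <- grid[match(barcodes, grid@barcode)]
  region <- rep(NA_character_, length(barcodes))
  regPath <- file.path(dir, "regions.tsv")
  if (file.exists(regPath)) {
    reg <- read.delim(regPath, stringsAsFactors = FALSE)
    region <- reg$region[match(barcodes, reg$barcode)]
  }
  storage.mode(counts) <- "integer"
  proto <- protocolProfile(manifest$protocol %||% "traditional")
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_id = feats[[1]],
                                   row.names = feats[[1]]),
    colData = S4Vectors::DataFrame(region = region,
                                   patient = NA_character_,
                                   row.names = barcodes))
  new("Slide", se, spotGrid = grid, protocol = proto, imageSource = NULL,
      field = NULL, slideId = manifest$slide_id %||% basename(dir),
      role = manifest$role %||% "train")
}

#' Write cohort manifest
#'
#' JSON listing of slides, protocols and roles of a cohort.
#'
#' @param cohort a [Cohort-class].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeCohortManifest <- function(cohort, path) {
  jsonlite::write_json(cohortDesign(cohort), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Report output
# ---------------------------------------------------------------------------

.fmtNum <- function(x) signif(x, 6)

#' Write evaluation and valuation reports to disk
#'
#' Emits tab-separated tables — a Table-3-shaped metric summary (one row
#' per training-regime x validation-slide combination), per-gene metrics,
#' and the per-slide valuation table with phi, SE, cost and ratio — plus a
#' JSON summary recomputable from the tables, and optional PNG heatmaps of
#' true vs predicted spatial expression. Floats are written at 6
#' significant digits.
#'
#' @param reports named list of [EvalReport-class] objects (names
#'   `regime@validation`).
#' @param valuation a [ValuationResult-class] or NULL.
#' @param dir output directory.
#' @param figures logical; also render spatial heatmap PNGs (requires a
#'   working png device).
#' @param figureData optional list with `slide`, `pred`, `genes` for the
#'   heatmaps.
#' @return character vector of written files, invisibly.
#' @export
writeReport <- function(reports, valuation = NULL, dir = ".",
                        figures = FALSE, figureData = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  metricRows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    a <- r@macro$auc; s <- r@macro$spearman
    data.frame(trained_on = r@trainedOn, evaluated_on = r@evaluatedOn,
               auc_median = .fmtNum(a$macroMedian),
               auc_mean = .fmtNum(a$macroMean),
               auc_ci_lo = .fmtNum(a$ciMean[1]),
               auc_ci_hi = .fmtNum(a$ciMean[2]),
               spearman_median = .fmtNum(s$macroMedian),
               spearman_mean = .fmtNum(s$macroMean),
               spearman_ci_lo = .fmtNum(s$ciMean[1]),
               spearman_ci_hi = .fmtNum(s$ciMean[2]),
               recovery_k3 = .fmtNum(r@recovery[["k3"]]),
               recovery_k5 = .fmtNum(r@recovery[["k5"]]),
               de_shift_pct = .fmtNum(r@deShift$medianPct),
               de_shift_lo = .fmtNum(r@deShift$ci[1]),
               de_shift_hi = .fmtNum(r@deShift$ci[2]),
               n_bootstrap = r@nBootstrap)
  })
  metricTab <- do.call(rbind, metricRows)
  f <- file.path(dir, "metrics.tsv")
  write.table(metricTab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  written <- c(written, f)

  perGene <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(trained_on = r@trainedOn, evaluated_on = r@evaluatedOn,
               gene = names(r@perGeneSpearman),
               auc = .fmtNum(r@perGeneAuc[names(r@perGeneSpearman)]),
               spearman = .fmtNum(r@perGeneSpearman), row.names = NULL)
  }))
  f <- file.path(dir, "per_gene_metrics.tsv")
  write.table(perGene, f, sep = "\t", row.names = FALSE, quote = FALSE)
  written <- c(written, f)

  summary <- list(metrics = metricTab)
  if (!is.null(valuation)) {
    vt <- valuation@table
    vt[c("phi", "se", "cost", "ratio")] <-
      lapply(vt[c("phi", "se", "cost", "ratio")], .fmtNum)
    f <- file.path(dir, "valuation.tsv")
    write.table(vt, f, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, f)
    f <- file.path(dir, "comparisons.tsv")
    write.table(valuation@comparisons, f, sep = "\t", row.names = FALSE,
                quote = FALSE)
    written <- c(written, f)
    summary$valuation <- vt
    summary$comparisons <- valuation@comparisons
    summary$cost_model <- valuation@costModel@label
  }
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = 8)
  written <- c(written, f)

  if (figures && !is.null(figureData)) {
    fig <- try(.writeSpatialHeatmaps(figureData, dir), silent = TRUE)
    if (!inherits(fig, "try-error")) written <- c(written, fig)
  }
  invisible(written)
}

# true-vs-predicted spatial heatmaps for a few genes
.writeSpatialHeatmaps <- function(figureData, dir) {
  slide <- figureData$slide
  pred <- figureData$pred
  genes <- figureData$genes
  g <- spotGrid(slide)
  truth <- makeTargets(slide, genes)@continuous
  path <- file.path(dir, "spatial_heatmaps.png")
  grDevices::png(path, width = 300 * length(genes), height = 600, res = 72)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(2, length(genes)), mar = c(1, 1, 2, 1))
  shade <- function(v) {
    v <- (v - min(v)) / max(1e-12, diff(range(v)))
    grDevices::rgb(v, 0.2, 1 - v)
  }
  for (gene in genes) {
    graphics::plot(g@pxlCol, -g@pxlRow, col = shade(truth[, gene]),
                   pch = 16, cex = 0.6, axes = FALSE,
                   main = paste(gene, "(truth)"), xlab = "", ylab = "")
  }
  for (gene in genes) {
    graphics::plot(g@pxlCol, -g@pxlRow, col = shade(pred[, gene]),
                   pch = 16, cex = 0.6, axes = FALSE,
                   main = paste(gene, "(predicted)"), xlab = "", ylab = "")
  }
  path
}
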