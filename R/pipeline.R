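# End-to-end pipeline stages (simulate -> measure -> compare) with JSON
# run manifests so that every output can be traced to its inputs and
# parameters. A thin command-line wrapper over these functions lives in
# inst/scripts/epimorph.R.

.writeManifest <- function(path, stage, config, extra = list()) {
    manifest <- c(list(
        tool = "epimorph",
        version = as.character(utils::packageVersion("epimorph")),
        stage = stage,
        config = config), extra)
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    invisible(path)
}

.logLine <- function(...) message(format(Sys.time(), "%H:%M:%S"), " ", ...)

#' Simulate a cohort and write its artifacts
#'
#' Generates a synthetic cohort and writes, per image, a label TIFF and a
#' GeoJSON of the vector truth, plus a ground-truth CSV and a JSON
#' manifest with the resolved design.
#'
#' @param design a [cohortDesign()].
#' @param outDir output directory (created if needed).
#' @param membranePx membrane width for the rasters (default 1).
#' @param writeRasters write label TIFFs (default `TRUE`).
#' @return the [SyntheticCohort-class], invisibly.
#' @export
runSimulate <- function(design, outDir, membranePx = 1L,
                        writeRasters = TRUE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cohort <- simulateCohort(design)
    imgs <- cohortImages(cohort)
    for (i in seq_len(nrow(imgs))) {
        sid <- imgs$sample_id[i]
        sheet <- cohortSheets(cohort)[[sid]]
        writePolygonsGeoJSON(sheet, file.path(outDir,
                                              paste0(sid, ".geojson")))
        if (writeRasters)
            writeLabelImage(rasterizeSheet(sheet, membranePx = membranePx),
                            file.path(outDir, paste0(sid, ".tif")))
        .logLine("simulated ", sid, ": ",
                 nrow(cellData(sheet)), " cells")
    }
    utils::write.csv(cohortTruth(cohort),
                     file.path(outDir, "ground_truth.csv"),
                     row.names = FALSE)
    dsn <- cohort@design
    dsn$baseConfig <- unclass(dsn$baseConfig)
    .writeManifest(file.path(outDir, "manifest.json"), "simulate", dsn,
                   list(images = nrow(imgs),
                        cells = nrow(cohortTruth(cohort))))
    invisible(cohort)
}

#' Measure every label image of a run
#'
#' End-to-end tessellation and morphometry over a set of label images:
#' polygon extraction, adjacency, border/damage exclusion, per-cell
#' metrics. The manifest records the segmented / border-excluded /
#' damage-excluded / analyzed counts per image.
#'
#' @param paths character vector of label image paths (TIFF/PNG).
#' @param outCsv path of the combined metrics CSV.
#' @param pixelSize physical pixel size (micrometres per pixel).
#' @param minSharedPx adjacency threshold, see [buildAdjacency()].
#' @param clamp clamp negative scores, see [polygonalityScore()].
#' @param metadata optional data.frame with `sample_id`, `mouse`,
#'   `genotype`, `age` columns to join onto the output.
#' @param manifest optional path of the JSON run manifest.
#' @return the combined metrics data.frame, invisibly.
#' @export
runMeasure <- function(paths, outCsv, pixelSize = 1, minSharedPx = 3L,
                       clamp = FALSE, metadata = NULL, manifest = NULL) {
    if (length(paths) == 0L) stop("no input images given")
    counts <- list(); all <- list()
    for (p in paths) {
        sid <- tools::file_path_sans_ext(basename(p))
        img <- readLabelImage(p, pixelSize = pixelSize)
        mosaic <- extractCellPolygons(img, sampleId = sid)
        graph <- buildAdjacency(img, minSharedPx = minSharedPx)
        mosaic <- setAdjacency(mosaic, graph)
        kept <- filterAnalysisSet(mosaic)
        m <- measureCells(kept, clamp = clamp)
        cd <- cellData(mosaic)
        counts[[sid]] <- list(
            sample_id = sid,
            segmented = nrow(cd),
            border_excluded = sum(cd$touches_border),
            damage_excluded = sum(cd$in_damaged_region &
                                  !cd$touches_border),
            analyzed = nrow(m))
        .logLine("measured ", sid, ": ", nrow(cd), " segmented, ",
                 nrow(m), " analyzed")
        all[[sid]] <- m
    }
    res <- do.call(rbind, c(all, list(make.row.names = FALSE)))
    if (!is.null(metadata))
        res <- merge(metadata, res, by = "sample_id", sort = FALSE)
    writeMetricsTable(res, outCsv)
    if (!is.null(manifest))
        .writeManifest(manifest, "measure",
                       list(pixelSize = pixelSize,
                            minSharedPx = minSharedPx, clamp = clamp,
                            inputs = as.list(unname(tools::md5sum(paths)))),
                       list(images = counts))
    invisible(res)
}

#' Compare groups from a metrics table
#'
#' Runs the per-age mean and variance comparison over the given metrics
#' and writes a results CSV (and JSON). Requires `genotype`, `mouse` and
#' (unless pooling) `age` columns.
#'
#' @param metricsCsv path(s) of metrics CSVs from [runMeasure()], or a
#'   data.frame.
#' @param outCsv results CSV path.
#' @param metrics metric columns to compare; defaults to the core
#'   morphology set present in the table.
#' @param outJson optional JSON results path.
#' @param ... passed to [compareGroups()].
#' @return the results data.frame, invisibly.
#' @export
runCompare <- function(metricsCsv, outCsv, metrics = NULL, outJson = NULL,
                       ...) {
    tab <- if (is.data.frame(metricsCsv)) metricsCsv
           else do.call(rbind, lapply(metricsCsv, readMetricsTable))
    need <- c("genotype", "mouse", "age")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("metrics table lacks required grouping columns: ",
             paste(miss, collapse = ", "))
    if (is.null(metrics))
        metrics <- intersect(c("area", "perimeter", "hexagonality_score",
                               "polygonality_score", "eccentricity",
                               "n_neighbors"), names(tab))
    res <- compareGroups(tab, metrics, ...)
    utils::write.csv(res, outCsv, row.names = FALSE)
    if (!is.null(outJson))
        jsonlite::write_json(res, outJson, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    invisible(res)
}
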