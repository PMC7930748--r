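# Per-cell morphometry and per-sample summaries.

#' Compute the full shape-metric table for a mosaic
#'
#' For every cell: area, perimeter, convex-hull area and perimeter,
#' solidity, Feret max/min diameters, moment-ellipse eccentricity and
#' aspect ratio, neighbor count (graph degree against all segmented
#' cells), and the polygonality and hexagonality regularity scores.
#'
#' @param mosaic a [CellMosaic-class] (typically already passed through
#'   [filterAnalysisSet()]).
#' @param graph an [AdjacencyGraph-class]; defaults to the graph stored in
#'   the mosaic. Every cell of the mosaic must be a node.
#' @param clamp clamp negative score sub-ratios at 0 (default `FALSE`;
#'   see [polygonalityScore()]).
#' @return data.frame with one row per cell, metadata columns first.
#' @export
measureCells <- function(mosaic, graph = adjacency(mosaic), clamp = FALSE) {
    stopifnot(is(mosaic, "CellMosaic"))
    if (is.null(graph)) stop("no adjacency graph supplied or stored")
    cells <- cellData(mosaic)
    polys <- cellPolygons(mosaic)
    deg <- neighborCounts(graph)
    missing <- setdiff(cells$cell_id, as.integer(names(deg)))
    if (length(missing))
        stop("cells absent from adjacency graph: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    n <- nrow(cells)
    num <- function() numeric(n)
    m <- data.frame(
        cell_id = cells$cell_id, sample_id = cells$sample_id,
        area = num(), perimeter = num(), hull_area = num(),
        hull_perimeter = num(), solidity = num(),
        feret_max = num(), feret_min = num(),
        eccentricity = num(), aspect_ratio = num(),
        n_neighbors = deg[as.character(cells$cell_id)]
    )
    for (i in seq_len(n)) {
        g <- basicGeometry(polys[[i]])
        f <- feretDiameters(polys[[i]])
        e <- ellipseDescriptors(polys[[i]])
        m$area[i] <- g$area; m$perimeter[i] <- g$perimeter
        m$hull_area[i] <- g$hull_area; m$hull_perimeter[i] <- g$hull_perimeter
        m$solidity[i] <- g$solidity
        m$feret_max[i] <- f$feret_max; m$feret_min[i] <- f$feret_min
        m$eccentricity[i] <- e$eccentricity; m$aspect_ratio[i] <- e$aspect_ratio
    }
    ps <- polygonalityScore(m$perimeter, m$area, m$hull_perimeter,
                            m$hull_area, m$n_neighbors, clamp = clamp)
    hs <- hexagonalityScore(m$perimeter, m$area, m$hull_perimeter,
                            m$hull_area, clamp = clamp)
    m$psr <- ps$psr; m$par <- ps$par
    m$polygonality_score <- ps$score
    m$score_reason <- ps$reason
    m$hsr <- hs$hsr; m$har <- hs$har
    m$hexagonality_score <- hs$score
    rownames(m) <- NULL
    m
}

.sampleMoments <- function(x) {
    x <- x[is.finite(x)]
    c(mean = mean(x), median = stats::median(x), sd = stats::sd(x),
      skewness = e1071::skewness(x, type = 1),
      kurtosis = e1071::kurtosis(x, type = 1))
}

#' Summarize one sample (image) of shape metrics
#'
#' Per-metric mean, median, SD (n-1 convention), skewness and excess
#' kurtosis (standardized third/fourth central moments), plus the
#' hexagonality SD — the within-image spread of the hexagonality score
#' used as a tissue-regularity readout.
#'
#' @param metrics data.frame from [measureCells()] (one sample).
#' @param metricCols metric columns to summarize; defaults to all numeric
#'   metric columns.
#' @return a list with `sample_id`, `n_cells`, `hexagonality_sd`, and a
#'   `stats` data.frame (metric x statistic).
#' @export
summarizeSample <- function(metrics, metricCols = NULL) {
    if (nrow(metrics) == 0L) stop("no cells to summarize")
    if (is.null(metricCols)) {
        metricCols <- setdiff(names(metrics)[vapply(metrics, is.numeric,
                                                    logical(1))],
                              c("cell_id", "n_neighbors"))
        metricCols <- c(metricCols, "n_neighbors")
    }
    stats <- t(vapply(metricCols,
                      function(cn) .sampleMoments(metrics[[cn]]),
                      numeric(5)))
    stats <- data.frame(metric = metricCols, stats, row.names = NULL)
    hexSd <- if ("hexagonality_score" %in% names(metrics))
        stats::sd(metrics$hexagonality_score[
            is.finite(metrics$hexagonality_score)]) else NA_real_
    list(sample_id = unique(metrics$sample_id)[1L],
         n_cells = nrow(metrics),
         hexagonality_sd = hexSd,
         stats = stats)
}

#' Write a shape-metric table to CSV
#'
#' Metadata columns (`mouse`, `genotype`, `age`, `sample_id`, `cell_id`)
#' come first, in a stable order; numeric values are written with enough
#' digits to round-trip losslessly.
#'
#' @param metrics data.frame of per-cell metrics.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMetricsTable <- function(metrics, path) {
    meta <- intersect(c("mouse", "genotype", "age", "sample_id", "cell_id"),
                      names(metrics))
    metrics <- metrics[, c(meta, setdiff(names(metrics), meta)), drop = FALSE]
    ok <- tryCatch({
        suppressWarnings(
            utils::write.csv(format(metrics, digits = 15, trim = TRUE,
                                    scientific = NA),
                             path, row.names = FALSE, quote = TRUE))
        TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("cannot write metrics table to ", path)
    invisible(path)
}

#' Read a shape-metric table written by [writeMetricsTable()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readMetricsTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE)
}
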