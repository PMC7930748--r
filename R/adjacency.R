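# Cell neighbor graph from a label raster. Two cells are neighbors when
# enough pixel pairs face each other across their common boundary:
# directly 4-adjacent, or separated by exactly one background (membrane)
# pixel — segmentation networks that draw 1-px cell borders leave exactly
# such a skeleton between every pair of touching cells.

#' Build the cell adjacency graph of a label image
#'
#' An edge (a, b) is recorded when labels a and b have at least
#' `minSharedPx` 4-connected pixel pairs across their boundary, counting
#' pairs that are directly adjacent or separated by exactly one
#' background/membrane pixel. The default of 3 suppresses corner-touch
#' artifacts. The shared boundary length per edge is the pair count times
#' the pixel size.
#'
#' @param img a [LabelImage-class].
#' @param minSharedPx minimum number of facing pixel pairs (default 3).
#' @return an [AdjacencyGraph-class].
#' @export
buildAdjacency <- function(img, minSharedPx = 3L) {
    stopifnot(is(img, "LabelImage"))
    if (minSharedPx < 1L) stop("minSharedPx must be >= 1")
    px <- labelPixels(img)
    nr <- nrow(px); nc <- ncol(px)

    pairs <- function(a, b) {
        keep <- a > 0L & b > 0L & a != b
        if (!any(keep)) return(NULL)
        cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
    }
    pp <- list()
    # directly adjacent, horizontal and vertical
    if (nc >= 2L) pp <- c(pp, list(pairs(px[, -nc], px[, -1L])))
    if (nr >= 2L) pp <- c(pp, list(pairs(px[-nr, ], px[-1L, ])))
    # one membrane pixel between
    if (nc >= 3L) {
        a <- px[, 1:(nc - 2L)]; m <- px[, 2:(nc - 1L)]; b <- px[, 3:nc]
        pp <- c(pp, list(pairs(ifelse(m == 0L, a, 0L), b)))
    }
    if (nr >= 3L) {
        a <- px[1:(nr - 2L), ]; m <- px[2:(nr - 1L), ]; b <- px[3:nr, ]
        pp <- c(pp, list(pairs(ifelse(m == 0L, a, 0L), b)))
    }
    pp <- do.call(rbind, pp)
    nodes <- sort(unique(px[px > 0L]))
    if (is.null(pp) || nrow(pp) == 0L) {
        edges <- data.frame(a = integer(0), b = integer(0), length = numeric(0))
        return(new("AdjacencyGraph", nodes = as.integer(nodes), edges = edges))
    }
    key <- paste(pp[, 1L], pp[, 2L])
    cnt <- table(key)
    keep <- cnt >= minSharedPx
    ab <- do.call(rbind, strsplit(names(cnt)[keep], " ", fixed = TRUE))
    if (is.null(ab)) ab <- matrix(integer(0), 0L, 2L)
    edges <- data.frame(
        a = as.integer(ab[, 1L]),
        b = as.integer(ab[, 2L]),
        length = as.numeric(cnt[keep]) * pixelSize(img)
    )
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
    new("AdjacencyGraph", nodes = as.integer(nodes), edges = edges)
}

#' Restrict cells to the analyzable set
#'
#' Drops cells that touch the image border (truncated geometry) or overlap
#' a damaged-region mask. Neighbor counts are unaffected: excluded cells
#' remain in the adjacency graph, so a retained cell's
#' \eqn{N_{neighbors}} still counts every segmented neighbor.
#'
#' @param mosaic a [CellMosaic-class].
#' @return a [CellMosaic-class] containing only retained cells (the graph,
#'   if present, is carried over unchanged).
#' @export
filterAnalysisSet <- function(mosaic) {
    stopifnot(is(mosaic, "CellMosaic"))
    cells <- cellData(mosaic)
    keep <- !cells$touches_border & !cells$in_damaged_region
    if (!any(keep))
        warning("no cells remain after border/damage exclusion")
    new("CellMosaic",
        polygons = cellPolygons(mosaic)[keep],
        cells = cells[keep, , drop = FALSE],
        graph = adjacency(mosaic),
        sampleId = mosaic@sampleId)
}

#' Attach an adjacency graph to a mosaic
#'
#' @param mosaic a [CellMosaic-class].
#' @param graph an [AdjacencyGraph-class].
#' @return the mosaic with the graph slot set.
#' @export
setAdjacency <- function(mosaic, graph) {
    stopifnot(is(mosaic, "CellMosaic"), is(graph, "AdjacencyGraph"))
    mosaic@graph <- graph
    mosaic
}
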