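#' Accessors for morphometry containers
#'
#' `labelPixels()` and `pixelSize()` read the raster and its physical
#' calibration from a [LabelImage-class]; `exclusionMask()` returns the
#' damaged-region mask (or `NULL`). `cellPolygons()` and `cellData()` read
#' the polygon list and per-cell metadata of a [CellMosaic-class];
#' `adjacency()` returns its [AdjacencyGraph-class]. `neighborCounts()`
#' returns the named degree vector of a graph, i.e. the
#' \eqn{N_{neighbors}} metric. `cohortImages()`, `cohortTruth()` and
#' `cohortSheets()` access a [SyntheticCohort-class].
#'
#' @param x the object.
#' @return the slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("labelPixels", function(x) standardGeneric("labelPixels"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("exclusionMask", function(x) standardGeneric("exclusionMask"))
#' @rdname accessors
#' @export
setGeneric("cellPolygons", function(x) standardGeneric("cellPolygons"))
#' @rdname accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("neighborCounts", function(x) standardGeneric("neighborCounts"))
#' @rdname accessors
#' @export
setGeneric("cohortImages", function(x) standardGeneric("cohortImages"))
#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
#' @rdname accessors
#' @export
setGeneric("cohortSheets", function(x) standardGeneric("cohortSheets"))

#' @rdname accessors
setMethod("labelPixels", "LabelImage", function(x) x@pixels)
#' @rdname accessors
setMethod("pixelSize", "LabelImage", function(x) x@pixelSize)
#' @rdname accessors
setMethod("exclusionMask", "LabelImage", function(x) x@exclusionMask)
#' @rdname accessors
setMethod("cellPolygons", "CellMosaic", function(x) x@polygons)
#' @rdname accessors
setMethod("cellData", "CellMosaic", function(x) x@cells)
#' @rdname accessors
setMethod("adjacency", "CellMosaic", function(x) x@graph)
#' @rdname accessors
setMethod("neighborCounts", "AdjacencyGraph", function(x) {
    deg <- stats::setNames(integer(length(x@nodes)), x@nodes)
    if (nrow(x@edges)) {
        tab <- table(factor(c(x@edges$a, x@edges$b), levels = x@nodes))
        deg[names(tab)] <- as.integer(tab)
    }
    deg
})
#' @rdname accessors
setMethod("cohortImages", "SyntheticCohort", function(x) x@images)
#' @rdname accessors
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)
#' @rdname accessors
setMethod("cohortSheets", "SyntheticCohort", function(x) x@sheets)
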