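#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Segmented label image
#'
#' An integer raster in which every cell's pixels carry a unique positive
#' label and background/membrane pixels are 0, together with the physical
#' pixel size and an optional mask of damaged regions to exclude from
#' analysis.
#'
#' @slot pixels integer matrix of non-negative labels (rows = y, columns = x).
#' @slot pixelSize physical side length of one pixel (micrometres per pixel).
#' @slot exclusionMask optional logical matrix of identical dimensions;
#'   `TRUE` marks damaged regions whose cells are excluded from analysis.
#'
#' @export
setClass("LabelImage",
    representation(
        pixels = "matrix",
        pixelSize = "numeric",
        exclusionMask = "matrixOrNULL"
    ),
    prototype(pixelSize = 1, exclusionMask = NULL)
)

setValidity("LabelImage", function(object) {
    msg <- character()
    px <- object@pixels
    if (!is.numeric(px) && !is.integer(px))
        msg <- c(msg, "pixels must be a numeric/integer matrix")
    if (length(px) == 0L)
        msg <- c(msg, "pixels must be non-empty")
    else {
        if (any(px < 0)) msg <- c(msg, "labels must be non-negative")
        if (any(px != round(px))) msg <- c(msg, "labels must be integers")
    }
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a single positive number")
    if (!is.null(object@exclusionMask)) {
        if (!identical(dim(object@exclusionMask), dim(px)))
            msg <- c(msg, "exclusionMask dimensions must match pixels")
        if (!is.logical(object@exclusionMask))
            msg <- c(msg, "exclusionMask must be logical")
    }
    if (length(msg)) msg else TRUE
})

#' Cell neighbor graph
#'
#' Undirected adjacency between cells that share a boundary, with the shared
#' boundary length per edge in physical units. Node degree is the
#' neighbor-count metric \eqn{N_{neighbors}} used by the polygonality score.
#'
#' @slot nodes integer vector of cell ids present in the tessellation.
#' @slot edges data.frame with columns `a`, `b` (cell id pair, a < b) and
#'   `length` (shared boundary length, micrometres).
#'
#' @export
setClass("AdjacencyGraph",
    representation(nodes = "integer", edges = "data.frame")
)

setValidity("AdjacencyGraph", function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("a", "b", "length") %in% names(e)))
        msg <- c(msg, "edges must have columns a, b, length")
    else if (nrow(e)) {
        if (any(e$a == e$b)) msg <- c(msg, "self-edges are not allowed")
        if (!all(e$a %in% object@nodes) || !all(e$b %in% object@nodes))
            msg <- c(msg, "edge endpoints must be nodes")
        key <- paste(pmin(e$a, e$b), pmax(e$a, e$b))
        if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
    }
    if (length(msg)) msg else TRUE
})

#' A set of cell polygons from one image
#'
#' Holds one simple polygon per cell (vertices in physical units,
#' counter-clockwise so the signed area is positive), per-cell metadata
#' (border contact, damaged-region overlap), and optionally the cell
#' neighbor graph.
#'
#' @slot polygons named list of 2-column numeric matrices (x, y vertices,
#'   open ring); names are cell ids.
#' @slot cells data.frame with one row per cell: `cell_id`, `sample_id`,
#'   `touches_border`, `in_damaged_region`.
#' @slot graph an [AdjacencyGraph-class] or `NULL`.
#' @slot sampleId identifier of the source image.
#'
#' @export
setClass("CellMosaic",
    representation(
        polygons = "list",
        cells = "data.frame",
        graph = "ANY",
        sampleId = "character"
    ),
    prototype(graph = NULL, sampleId = NA_character_)
)

setValidity("CellMosaic", function(object) {
    msg <- character()
    ids <- object@cells$cell_id
    if (length(object@polygons) != nrow(object@cells))
        msg <- c(msg, "one polygon per cell row required")
    if (!identical(as.integer(names(object@polygons)), as.integer(ids)))
        msg <- c(msg, "polygon names must equal cells$cell_id in order")
    bad <- vapply(object@polygons, function(p) {
        !is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L
    }, logical(1))
    if (any(bad)) msg <- c(msg, "polygons must be 2-column matrices with >= 3 vertices")
    if (!is.null(object@graph) && !is(object@graph, "AdjacencyGraph"))
        msg <- c(msg, "graph must be an AdjacencyGraph or NULL")
    if (length(msg)) msg else TRUE
})

#' Synthetic multi-mouse cohort of epithelial sheets
#'
#' The output of [simulateCohort()]: vector tessellations for every image in
#' a genotype x age x mouse design, image-level metadata, and the per-cell
#' ground truth recorded by the generator.
#'
#' @slot sheets named list of [CellMosaic-class] objects, one per image.
#' @slot images data.frame with one row per image: `sample_id`, `mouse`,
#'   `genotype`, `age`, plus the realized generator parameters.
#' @slot truth data.frame of per-cell ground truth (areas, perimeters,
#'   neighbor counts) straight from the vector geometry.
#' @slot design the [cohortDesign()] list that produced the cohort.
#'
#' @export
setClass("SyntheticCohort",
    representation(
        sheets = "list",
        images = "data.frame",
        truth = "data.frame",
        design = "list"
    )
)

setValidity("SyntheticCohort", function(object) {
    msg <- character()
    if (!all(c("sample_id", "mouse", "genotype", "age") %in% names(object@images)))
        msg <- c(msg, "images must have sample_id, mouse, genotype, age columns")
    if (length(object@sheets) != nrow(object@images))
        msg <- c(msg, "one sheet per image row required")
    if (!identical(names(object@sheets), as.character(object@images$sample_id)))
        msg <- c(msg, "sheet names must equal images$sample_id")
    if (length(msg)) msg else TRUE
})

setMethod("show", "LabelImage", function(object) {
    d <- dim(object@pixels)
    labs <- setdiff(unique(as.vector(object@pixels)), 0)
    cat(sprintf("LabelImage: %d x %d px, %d cells, %.4g um/px%s\n",
        d[1], d[2], length(labs), object@pixelSize,
        if (!is.null(object@exclusionMask)) ", with exclusion mask" else ""))
})

setMethod("show", "AdjacencyGraph", function(object) {
    cat(sprintf("AdjacencyGraph: %d cells, %d shared-boundary edges\n",
        length(object@nodes), nrow(object@edges)))
})

setMethod("show", "CellMosaic", function(object) {
    cat(sprintf("CellMosaic '%s': %d cells (%d border, %d in damaged regions)%s\n",
        object@sampleId, nrow(object@cells),
        sum(object@cells$touches_border),
        sum(object@cells$in_damaged_region),
        if (is.null(object@graph)) "" else ", with adjacency graph"))
})

setMethod("show", "SyntheticCohort", function(object) {
    cat(sprintf(
        "SyntheticCohort: %d images, %d mice, genotypes {%s}, ages {%s}, %d cells\n",
        nrow(object@images), length(unique(object@images$mouse)),
        paste(unique(object@images$genotype), collapse = ", "),
        paste(unique(object@images$age), collapse = ", "),
        nrow(object@truth)))
})
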