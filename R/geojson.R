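# Polygon exchange as GeoJSON FeatureCollections (one Polygon feature per
# cell, cell metadata in feature properties).

#' Write a mosaic's polygons as GeoJSON
#'
#' One `Polygon` feature per cell with `cell_id`, `sample_id`,
#' `touches_border` and `in_damaged_region` properties. Rings are closed
#' (first vertex repeated) as GeoJSON requires.
#'
#' @param mosaic a [CellMosaic-class].
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
writePolygonsGeoJSON <- function(mosaic, path) {
    stopifnot(is(mosaic, "CellMosaic"))
    cells <- cellData(mosaic)
    feats <- lapply(seq_len(nrow(cells)), function(i) {
        p <- cellPolygons(mosaic)[[i]]
        ring <- rbind(p, p[1L, , drop = FALSE])
        list(
            type = "Feature",
            properties = list(
                cell_id = cells$cell_id[i],
                sample_id = cells$sample_id[i],
                touches_border = cells$touches_border[i],
                in_damaged_region = cells$in_damaged_region[i]
            ),
            geometry = list(
                type = "Polygon",
                coordinates = list(lapply(seq_len(nrow(ring)),
                                          function(k) unname(ring[k, ])))
            )
        )
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read cell polygons from GeoJSON
#'
#' Inverse of [writePolygonsGeoJSON()]. Only the outer ring of each
#' Polygon feature is used; missing properties default to `FALSE` flags
#' and sequential ids.
#'
#' @param path `.geojson` path.
#' @param sampleId sample id to use when the file carries none.
#' @return a [CellMosaic-class] (no adjacency graph).
#' @export
readPolygonsGeoJSON <- function(path, sampleId = "") {
    if (!file.exists(path)) stop("file not found: ", path)
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!identical(gj$type, "FeatureCollection"))
        stop("not a GeoJSON FeatureCollection")
    feats <- gj$features
    if (length(feats) == 0L) stop("no features in ", path)
    polys <- vector("list", length(feats))
    ids <- integer(length(feats))
    sids <- character(length(feats))
    tb <- idr <- logical(length(feats))
    for (i in seq_along(feats)) {
        f <- feats[[i]]
        if (!identical(f$geometry$type, "Polygon"))
            stop("feature ", i, " is not a Polygon")
        ring <- f$geometry$coordinates[[1L]]
        m <- do.call(rbind, lapply(ring, function(v)
            c(as.numeric(v[[1L]]), as.numeric(v[[2L]]))))
        if (nrow(m) >= 2L && all(m[1L, ] == m[nrow(m), ]))
            m <- m[-nrow(m), , drop = FALSE]
        if (.shoelace(m) < 0) m <- m[nrow(m):1L, , drop = FALSE]
        colnames(m) <- c("x", "y")
        polys[[i]] <- m
        pr <- f$properties
        ids[i] <- if (!is.null(pr$cell_id)) as.integer(pr$cell_id) else i
        sids[i] <- if (!is.null(pr$sample_id)) as.character(pr$sample_id)
                   else sampleId
        tb[i] <- isTRUE(pr$touches_border)
        idr[i] <- isTRUE(pr$in_damaged_region)
    }
    names(polys) <- ids
    new("CellMosaic",
        polygons = polys,
        cells = data.frame(cell_id = ids, sample_id = sids,
                           touches_border = tb, in_damaged_region = idr),
        graph = NULL,
        sampleId = if (length(unique(sids)) == 1L) sids[1L] else sampleId)
}
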