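# Synthetic epithelial sheets: seeds on a triangular lattice, isotropic
# Gaussian jitter, optional dropout (enlarged cells), Voronoi tessellation
# clipped to the window, optional Lloyd (centroidal) relaxation. The
# unperturbed lattice tessellates into regular hexagons, i.e. the
# honeycomb limit of a healthy epithelium; jitter and dropout move the
# sheet toward the disordered, enlarged phenotype.

#' An epithelial sheet with generator ground truth
#'
#' A [CellMosaic-class] that additionally records the Voronoi seeds, the
#' clipping window and the generator configuration, so that the sheet can
#' be rasterized exactly and its ground truth recovered.
#'
#' @slot seeds 2-column matrix of Voronoi seeds (one per cell, same order
#'   as the polygons).
#' @slot window numeric length-2 (width, height) in micrometres.
#' @slot config the [generatorConfig()] list used.
#' @export
setClass("EpithelialSheet",
    contains = "CellMosaic",
    representation(seeds = "matrix", window = "numeric", config = "list")
)

#' Generator configuration
#'
#' Defaults emulate a healthy (wild-type-like) murine RPE flatmount field:
#' 350 x 350 um windows of ~250 um^2 cells with mild positional jitter.
#'
#' @param window numeric (width, height) of the field in micrometres.
#' @param targetCellArea mean cell area in um^2.
#' @param jitterSigma seed jitter SD as a fraction of the lattice spacing
#'   (0 = perfect honeycomb).
#' @param lloydIterations centroidal relaxation steps (>= 0).
#' @param dropoutFraction fraction of seeds removed, creating enlarged
#'   cells (in [0, 1)).
#' @param seed RNG seed.
#' @param rasterPxPerUm raster resolution for [rasterizeSheet()].
#' @return named list of class `generatorConfig`.
#' @export
generatorConfig <- function(window = c(350, 350), targetCellArea = 250,
                            jitterSigma = 0.15, lloydIterations = 0L,
                            dropoutFraction = 0, seed = 1L,
                            rasterPxPerUm = 3) {
    stopifnot(length(window) == 2L, all(window > 0), targetCellArea > 0,
              jitterSigma >= 0, lloydIterations >= 0,
              dropoutFraction >= 0, dropoutFraction < 1, rasterPxPerUm > 0)
    structure(list(window = as.numeric(window),
                   targetCellArea = targetCellArea,
                   jitterSigma = jitterSigma,
                   lloydIterations = as.integer(lloydIterations),
                   dropoutFraction = dropoutFraction,
                   seed = as.integer(seed),
                   rasterPxPerUm = rasterPxPerUm),
              class = "generatorConfig")
}

# Clip a tagged polygon by the half-plane closer to p than to q.
# tags[i] tags the edge leaving vertex i; newTag tags edges created on the
# bisector. Returns NULL when the intersection is empty.
.clipHalfplane <- function(poly, tags, p, q, newTag) {
    d <- q - p; m <- (p + q) / 2
    f <- (poly[, 1L] - m[1L]) * d[1L] + (poly[, 2L] - m[2L]) * d[2L]
    if (all(f <= 0)) return(list(poly = poly, tags = tags))
    if (all(f > 0)) return(NULL)
    n <- nrow(poly)
    ox <- oy <- numeric(n + 4L); ot <- integer(n + 4L); k <- 0L
    for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        fi <- f[i]; fj <- f[j]
        if (fi <= 0) {
            k <- k + 1L; ox[k] <- poly[i, 1L]; oy[k] <- poly[i, 2L]
            ot[k] <- tags[i]
            if (fj > 0) {       # leaving: add intersection, bisector edge
                s <- fi / (fi - fj)
                k <- k + 1L
                ox[k] <- poly[i, 1L] + s * (poly[j, 1L] - poly[i, 1L])
                oy[k] <- poly[i, 2L] + s * (poly[j, 2L] - poly[i, 2L])
                ot[k] <- newTag
            }
        } else if (fj <= 0) {   # entering: intersection continues old edge
            s <- fi / (fi - fj)
            k <- k + 1L
            ox[k] <- poly[i, 1L] + s * (poly[j, 1L] - poly[i, 1L])
            oy[k] <- poly[i, 2L] + s * (poly[j, 2L] - poly[i, 2L])
            ot[k] <- tags[i]
        }
    }
    if (k < 3L) return(NULL)
    list(poly = cbind(ox[seq_len(k)], oy[seq_len(k)]), tags = ot[seq_len(k)])
}

# Voronoi cells of `seeds` clipped to [0,W]x[0,H]. Returns polygons, edge
# tags (positive: index of the neighboring seed; negative: window side)
# for every seed with a non-empty cell.
.clippedVoronoi <- function(seeds, window) {
    n <- nrow(seeds)
    W <- window[1L]; H <- window[2L]
    base <- cbind(c(0, W, W, 0), c(0, 0, H, H))
    baseTags <- c(-1L, -2L, -3L, -4L)
    d2 <- as.matrix(stats::dist(seeds))^2
    polys <- vector("list", n)
    tags <- vector("list", n)
    for (i in seq_len(n)) {
        ord <- order(d2[i, ])
        ord <- ord[ord != i]
        poly <- base; tg <- baseTags
        R2 <- max((poly[, 1L] - seeds[i, 1L])^2 +
                  (poly[, 2L] - seeds[i, 2L])^2)
        for (j in ord) {
            if (d2[i, j] >= 4 * R2) break
            res <- .clipHalfplane(poly, tg, seeds[i, ], seeds[j, ], j)
            if (is.null(res)) { poly <- NULL; break }
            poly <- res$poly; tg <- res$tags
            R2 <- max((poly[, 1L] - seeds[i, 1L])^2 +
                      (poly[, 2L] - seeds[i, 2L])^2)
        }
        polys[[i]] <- poly
        tags[[i]] <- if (is.null(poly)) NULL else tg
    }
    list(polys = polys, tags = tags)
}

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
}

#' Generate a synthetic epithelial sheet
#'
#' Places Voronoi seeds on a triangular lattice whose spacing matches the
#' target cell area, jitters them, optionally drops a fraction out,
#' tessellates, clips to the window and applies Lloyd relaxation. With
#' zero jitter and dropout the interior cells are exact regular hexagons
#' (hexagonality score 10). Deterministic given the seed.
#'
#' @param cfg a [generatorConfig()].
#' @return an [EpithelialSheet-class] with adjacency graph and ground
#'   truth recoverable from the vector geometry.
#' @export
generateSheet <- function(cfg) {
    stopifnot(inherits(cfg, "generatorConfig"))
    spacing <- sqrt(2 * cfg$targetCellArea / sqrt(3))
    W <- cfg$window[1L]; H <- cfg$window[2L]
    margin <- 3 * spacing
    rowH <- spacing * sqrt(3) / 2
    rows <- seq(-margin, H + margin, by = rowH)
    seeds <- .withSeed(cfg$seed, {
        pts <- do.call(rbind, lapply(seq_along(rows), function(r) {
            off <- if (r %% 2L == 0L) spacing / 2 else 0
            xs <- seq(-margin + off, W + margin, by = spacing)
            cbind(xs, rows[r])
        }))
        if (cfg$jitterSigma > 0)
            pts <- pts + matrix(stats::rnorm(length(pts), 0,
                cfg$jitterSigma * spacing), ncol = 2L)
        if (cfg$dropoutFraction > 0) {
            nDrop <- floor(cfg$dropoutFraction * nrow(pts))
            if (nDrop > 0)
                pts <- pts[-sample.int(nrow(pts), nDrop), , drop = FALSE]
        }
        pts
    })
    vor <- .clippedVoronoi(seeds, cfg$window)
    iter <- cfg$lloydIterations
    while (iter > 0L) {
        keep <- !vapply(vor$polys, is.null, logical(1))
        seeds <- t(vapply(vor$polys[keep], polygonCentroid, numeric(2)))
        vor <- .clippedVoronoi(seeds, cfg$window)
        iter <- iter - 1L
    }
    keep <- which(!vapply(vor$polys, is.null, logical(1)))
    if (length(keep) < 25L)
        stop("fewer than 25 cells in window; enlarge window or shrink cells")
    # renumber cells 1..n, remap neighbor tags
    remap <- integer(nrow(seeds)); remap[keep] <- seq_along(keep)
    polys <- vor$polys[keep]
    tagl <- vor$tags[keep]
    ids <- seq_along(keep)
    edges <- list()
    touches <- logical(length(keep))
    for (k in seq_along(keep)) {
        tg <- tagl[[k]]
        touches[k] <- any(tg < 0L)
        nb <- unique(tg[tg > 0L])
        nb <- remap[nb]; nb <- nb[nb > 0L]
        if (length(nb)) {
            p <- polys[[k]]
            lens <- sqrt(rowSums((p[c(2:nrow(p), 1L), ] - p)^2))
            el <- vapply(unique(tagl[[k]][tagl[[k]] > 0L]), function(j)
                sum(lens[tagl[[k]] == j]), numeric(1))
            valid <- remap[unique(tagl[[k]][tagl[[k]] > 0L])] > 0L
            edges[[k]] <- data.frame(
                a = ids[k],
                b = remap[unique(tagl[[k]][tagl[[k]] > 0L])][valid],
                length = el[valid])
        }
    }
    ed <- do.call(rbind, edges)
    ed2 <- data.frame(a = pmin(ed$a, ed$b), b = pmax(ed$a, ed$b),
                      length = ed$length)
    ed2 <- ed2[!duplicated(ed2[, c("a", "b")]), ]
    ed2 <- ed2[order(ed2$a, ed2$b), ]
    rownames(ed2) <- NULL
    graph <- new("AdjacencyGraph", nodes = as.integer(ids), edges = ed2)
    polys <- lapply(polys, function(p) {
        colnames(p) <- c("x", "y")
        if (.shoelace(p) < 0) p[nrow(p):1L, ] else p
    })
    names(polys) <- ids
    cells <- data.frame(cell_id = ids, sample_id = "",
                        touches_border = touches,
                        in_damaged_region = FALSE)
    new("EpithelialSheet",
        polygons = polys, cells = cells, graph = graph, sampleId = "",
        seeds = seeds[keep, , drop = FALSE], window = cfg$window,
        config = unclass(cfg))
}

#' Vector ground truth of a generated sheet
#'
#' Per-cell area, perimeter, neighbor count and border flag computed
#' directly from the exact vector geometry.
#'
#' @param sheet an [EpithelialSheet-class] (or any [CellMosaic-class] with
#'   a graph).
#' @return data.frame with `cell_id`, `area`, `perimeter`, `n_neighbors`,
#'   `touches_border`.
#' @export
vectorTruth <- function(sheet) {
    cells <- cellData(sheet)
    polys <- cellPolygons(sheet)
    deg <- neighborCounts(adjacency(sheet))
    data.frame(
        cell_id = cells$cell_id,
        area = vapply(polys, function(p) abs(.shoelace(p)), numeric(1)),
        perimeter = vapply(polys, .perimeterOf, numeric(1)),
        n_neighbors = as.integer(deg[as.character(cells$cell_id)]),
        touches_border = cells$touches_border,
        row.names = NULL
    )
}
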