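# Tracing pixel regions into polygons. Each pixel (row r, col c) occupies
# the half-open square [c-1, c) x [r-1, r) with x = column, y = row and the
# origin at the top-left, so a traced polygon's shoelace area equals the
# pixel count exactly. Outlines are the raw staircase boundary (no
# sub-pixel smoothing): deterministic and consistent with pixel-area
# bookkeeping.

# Exposed boundary edges of every labelled pixel, oriented so each region
# is traversed with positive shoelace area. Returns from/to vertex ids,
# direction code (0:+x, 1:+y, 2:-x, 3:-y) and the pixel's label.
.boundaryEdges <- function(px) {
    nr <- nrow(px); nc <- ncol(px)
    pad <- matrix(0L, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- px
    core <- pad[2:(nr + 1L), 2:(nc + 1L)]
    inside <- core > 0L
    vid <- function(x, y) x * (nr + 1L) + y + 1L
    out <- vector("list", 4L)
    # top edge (y = r-1), +x: exposed when the pixel above differs
    e <- inside & core != pad[1:nr, 2:(nc + 1L)]
    w <- which(e, arr.ind = TRUE)
    out[[1L]] <- list(from = vid(w[, 2L] - 1L, w[, 1L] - 1L),
                      to = vid(w[, 2L], w[, 1L] - 1L),
                      dir = rep(0L, nrow(w)), lab = core[e])
    # right edge (x = c), +y
    e <- inside & core != pad[2:(nr + 1L), 3:(nc + 2L)]
    w <- which(e, arr.ind = TRUE)
    out[[2L]] <- list(from = vid(w[, 2L], w[, 1L] - 1L),
                      to = vid(w[, 2L], w[, 1L]),
                      dir = rep(1L, nrow(w)), lab = core[e])
    # bottom edge (y = r), -x
    e <- inside & core != pad[3:(nr + 2L), 2:(nc + 1L)]
    w <- which(e, arr.ind = TRUE)
    out[[3L]] <- list(from = vid(w[, 2L], w[, 1L]),
                      to = vid(w[, 2L] - 1L, w[, 1L]),
                      dir = rep(2L, nrow(w)), lab = core[e])
    # left edge (x = c-1), -y
    e <- inside & core != pad[2:(nr + 1L), 1:nc]
    w <- which(e, arr.ind = TRUE)
    out[[4L]] <- list(from = vid(w[, 2L] - 1L, w[, 1L]),
                      to = vid(w[, 2L] - 1L, w[, 1L] - 1L),
                      dir = rep(3L, nrow(w)), lab = core[e])
    list(from = unlist(lapply(out, `[[`, "from")),
         to = unlist(lapply(out, `[[`, "to")),
         dir = unlist(lapply(out, `[[`, "dir")),
         lab = unlist(lapply(out, `[[`, "lab")))
}

# Chain one label's directed edges into closed rings. At pinch vertices
# (two outgoing edges) the continuation keeping the interior on the same
# side is preferred, splitting figure-eight outlines into separate rings.
.chainRings <- function(from, to, dir) {
    ne <- length(from)
    outIdx <- split(seq_len(ne), from)
    used <- logical(ne)
    rings <- list()
    for (s in seq_len(ne)) {
        if (used[s]) next
        startV <- from[s]
        cur <- s
        verts <- integer(0)
        repeat {
            used[cur] <- TRUE
            verts <- c(verts, to[cur])
            v <- to[cur]
            if (v == startV) break
            cand <- outIdx[[as.character(v)]]
            cand <- cand[!used[cand]]
            if (length(cand) == 0L)
                stop("open boundary chain; corrupt label region")
            if (length(cand) > 1L) {
                pref <- c((dir[cur] + 1L) %% 4L, dir[cur], (dir[cur] + 3L) %% 4L)
                cand <- cand[order(match(dir[cand], pref))]
            }
            cur <- cand[1L]
        }
        rings[[length(rings) + 1L]] <- c(startV, verts[-length(verts)])
    }
    rings
}

# Douglas-Peucker simplification of a closed ring (tolerance in the
# ring's coordinate units). Anchored at the two mutually farthest
# vertices so the split halves are open chains.
.simplifyRing <- function(poly, tol) {
    n <- nrow(poly)
    if (n <= 4L) return(poly)
    d2m <- 0; a <- 1L; b <- 2L
    for (i in seq_len(n - 1L)) {
        d2 <- (poly[(i + 1L):n, 1L] - poly[i, 1L])^2 +
              (poly[(i + 1L):n, 2L] - poly[i, 2L])^2
        j <- which.max(d2)
        if (d2[j] > d2m) { d2m <- d2[j]; a <- i; b <- i + j }
    }
    dpOpen <- function(idx) {
        keep <- logical(length(idx)); keep[1L] <- keep[length(idx)] <- TRUE
        stack <- list(c(1L, length(idx)))
        while (length(stack)) {
            seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
            i <- seg[1L]; j <- seg[2L]
            if (j - i < 2L) next
            p <- poly[idx[i], ]; q <- poly[idx[j], ]
            v <- q - p; len <- sqrt(sum(v^2))
            mid <- idx[(i + 1L):(j - 1L)]
            d <- if (len == 0) sqrt((poly[mid, 1L] - p[1L])^2 +
                                    (poly[mid, 2L] - p[2L])^2)
                 else abs((poly[mid, 1L] - p[1L]) * v[2L] -
                          (poly[mid, 2L] - p[2L]) * v[1L]) / len
            k <- which.max(d)
            if (d[k] > tol) {
                keep[i + k] <- TRUE
                stack <- c(stack, list(c(i, i + k), c(i + k, j)))
            }
        }
        idx[keep]
    }
    half1 <- dpOpen(a:b)
    half2 <- dpOpen(c(b:n, 1:a))
    keep <- unique(c(half1, half2))
    keep <- sort(keep[keep <= n])
    if (length(keep) < 3L) return(poly)
    poly[keep, , drop = FALSE]
}

.ringToPoly <- function(vids, nr) {
    x <- (vids - 1L) %/% (nr + 1L)
    y <- (vids - 1L) %% (nr + 1L)
    # drop collinear staircase vertices
    n <- length(x)
    px <- c(x[n], x[-n]); py <- c(y[n], y[-n])
    nx <- c(x[-1L], x[1L]); ny <- c(y[-1L], y[1L])
    keep <- (nx - x) * (y - py) != (ny - y) * (x - px)
    cbind(x = x[keep], y = y[keep])
}

#' Extract one polygon per cell from a label image
#'
#' Traces every label's pixel region into a closed staircase polygon in
#' physical units (pixel area convention: each pixel contributes
#' `pixelSize^2` of area, so polygon area equals pixel count times
#' `pixelSize^2` exactly). Cells touching the image border are flagged
#' `touches_border`; cells overlapping the exclusion mask are flagged
#' `in_damaged_region`.
#'
#' With `smooth = TRUE` the staircase is simplified by Douglas-Peucker
#' with a sub-pixel tolerance, recovering near-vector perimeters (the raw
#' staircase overestimates the perimeter of oblique edges); the exact
#' pixel-area identity then holds only approximately.
#'
#' @param img a [LabelImage-class].
#' @param sampleId identifier stored with the cells (default the empty
#'   string).
#' @param smooth simplify the staircase outline (default `FALSE`).
#' @param smoothTol Douglas-Peucker tolerance in pixels (default 1.5;
#'   values at or below 1 cannot absorb the unit staircase steps of
#'   oblique digital lines).
#' @return a [CellMosaic-class] (without adjacency graph; see
#'   [buildAdjacency()]).
#' @seealso [filterAnalysisSet()], [measureCells()]
#' @export
extractCellPolygons <- function(img, sampleId = "", smooth = FALSE,
                                smoothTol = 1.5) {
    stopifnot(is(img, "LabelImage"))
    px <- labelPixels(img)
    if (!any(px > 0L)) stop("label image contains no cells")
    nr <- nrow(px)
    ed <- .boundaryEdges(px)
    byLab <- split(seq_along(ed$lab), ed$lab)
    labs <- as.integer(names(byLab))
    scale <- pixelSize(img)

    mask <- exclusionMask(img)
    borderLabs <- unique(c(px[1L, ], px[nr, ], px[, 1L], px[, ncol(px)]))
    damagedLabs <- if (is.null(mask)) integer(0) else unique(px[mask & px > 0L])

    counts <- tabulate(px, nbins = max(labs))
    polys <- vector("list", length(labs))
    for (k in seq_along(labs)) {
        i <- byLab[[k]]
        rings <- .chainRings(ed$from[i], ed$to[i], ed$dir[i])
        ringPolys <- lapply(rings, .ringToPoly, nr = nr)
        areas <- vapply(ringPolys, .shoelace, numeric(1))
        if (sum(areas > 0) > 1L)
            stop("label ", labs[k],
                 " is split into multiple connected components")
        if (any(areas < 0))
            stop("label ", labs[k], " contains holes")
        poly <- ringPolys[[which(areas > 0)]]
        if (abs(.shoelace(poly) - counts[labs[k]]) > 1e-9)
            stop("internal error: traced area mismatch for label ", labs[k])
        if (smooth) {
            poly <- .simplifyRing(poly, smoothTol)
            # restore the unbiased pixel-count area lost to corner cutting
            ctr <- polygonCentroid(poly)
            s <- sqrt(counts[labs[k]] / .shoelace(poly))
            poly <- sweep(sweep(poly, 2L, ctr) * s, 2L, ctr, "+")
        }
        polys[[k]] <- poly * scale
    }
    names(polys) <- labs
    cells <- data.frame(
        cell_id = labs,
        sample_id = sampleId,
        touches_border = labs %in% borderLabs,
        in_damaged_region = labs %in% damagedLabs
    )
    new("CellMosaic", polygons = polys, cells = cells, graph = NULL,
        sampleId = sampleId)
}
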