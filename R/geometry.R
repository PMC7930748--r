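# Planar polygon primitives. Polygons are 2-column (x, y) matrices, open
# rings (last vertex != first), oriented counter-clockwise (positive
# shoelace area).

.checkPolygon <- function(poly) {
    if (!is.matrix(poly) || ncol(poly) != 2L || nrow(poly) < 3L)
        stop("polygon must be a 2-column matrix with at least 3 vertices")
    if (!all(is.finite(poly))) stop("polygon has non-finite vertices")
    invisible(poly)
}

.shoelace <- function(poly) {
    x <- poly[, 1L]; y <- poly[, 2L]
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    sum(x * yn - xn * y) / 2
}

.perimeterOf <- function(poly) {
    d <- poly - poly[c(2:nrow(poly), 1L), , drop = FALSE]
    sum(sqrt(rowSums(d^2)))
}

# counter-clockwise convex hull vertices
.convexHull <- function(poly) {
    idx <- grDevices::chull(poly[, 1L], poly[, 2L])   # clockwise order
    poly[rev(idx), , drop = FALSE]
}

#' Area, perimeter, convex hull and solidity of a cell polygon
#'
#' Area by the shoelace formula, perimeter as the sum of edge lengths, the
#' convex hull's area and perimeter, and solidity = area / hull area
#' (1 for convex cells).
#'
#' @param poly 2-column matrix of (x, y) vertices in physical units,
#'   counter-clockwise, open ring.
#' @return named list with `area`, `perimeter`, `hull_area`,
#'   `hull_perimeter`, `solidity`.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' basicGeometry(sq)$solidity  # 1
#' @export
basicGeometry <- function(poly) {
    .checkPolygon(poly)
    # center to keep the shoelace sums well conditioned far from origin
    poly <- sweep(poly, 2L, colMeans(poly))
    area <- .shoelace(poly)
    if (area < 0) { poly <- poly[nrow(poly):1L, , drop = FALSE]; area <- -area }
    if (area <= 0) stop("degenerate polygon with zero area")
    hull <- .convexHull(poly)
    list(
        area = area,
        perimeter = .perimeterOf(poly),
        hull_area = .shoelace(hull),
        hull_perimeter = .perimeterOf(hull),
        solidity = area / .shoelace(hull)
    )
}

#' Maximum and minimum Feret (caliper) diameters
#'
#' The maximum Feret diameter is the largest distance between two hull
#' vertices; the minimum is the smallest caliper width over hull edge
#' orientations (rotating-calipers width).
#'
#' @inheritParams basicGeometry
#' @return named list with `feret_max`, `feret_min`.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' feretDiameters(sq)  # sqrt(2), 1
#' @export
feretDiameters <- function(poly) {
    .checkPolygon(poly)
    h <- .convexHull(poly)
    n <- nrow(h)
    if (n < 2L) stop("degenerate polygon")
    dmax <- 0
    for (i in seq_len(n - 1L)) {
        d2 <- (h[(i + 1L):n, 1L] - h[i, 1L])^2 + (h[(i + 1L):n, 2L] - h[i, 2L])^2
        dmax <- max(dmax, d2)
    }
    # min width: for each hull edge, farthest vertex distance to the edge line
    wmin <- Inf
    for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        e <- h[j, ] - h[i, ]
        len <- sqrt(sum(e^2))
        if (len == 0) next
        nrm <- c(-e[2L], e[1L]) / len
        d <- abs((h[, 1L] - h[i, 1L]) * nrm[1L] + (h[, 2L] - h[i, 2L]) * nrm[2L])
        wmin <- min(wmin, max(d))
    }
    list(feret_max = sqrt(dmax), feret_min = wmin)
}

# polygon area moments: area, centroid, central second moments per unit
# area (the covariance matrix of the uniform distribution on the polygon)
.polygonMoments <- function(poly) {
    shift <- colMeans(poly)           # conditioning; undone on centroid
    x <- poly[, 1L] - shift[1L]; y <- poly[, 2L] - shift[2L]
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    cr <- x * yn - xn * y
    A <- sum(cr) / 2
    if (A < 0) { A <- -A; cr <- -cr }
    cx <- sum((x + xn) * cr) / (6 * A)
    cy <- sum((y + yn) * cr) / (6 * A)
    mxx <- sum((x^2 + x * xn + xn^2) * cr) / 12
    myy <- sum((y^2 + y * yn + yn^2) * cr) / 12
    mxy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
    list(area = A, centroid = c(cx, cy) + shift,
         cov = matrix(c(mxx / A - cx^2, mxy / A - cx * cy,
                        mxy / A - cx * cy, myy / A - cy^2), 2L))
}

#' Moment-ellipse eccentricity and aspect ratio
#'
#' Fits the equivalent ellipse from the polygon's area-weighted central
#' second moments. With semi-axes a >= b, eccentricity is
#' sqrt(1 - (b/a)^2) and aspect ratio a/b; both are invariant under
#' similarity transforms.
#'
#' @inheritParams basicGeometry
#' @return named list with `eccentricity`, `aspect_ratio`.
#' @examples
#' rect <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
#' ellipseDescriptors(rect)$aspect_ratio  # 2
#' @export
ellipseDescriptors <- function(poly) {
    .checkPolygon(poly)
    m <- .polygonMoments(poly)
    if (m$area <= 0) stop("degenerate polygon with zero area")
    ev <- eigen(m$cov, symmetric = TRUE, only.values = TRUE)$values
    if (ev[2L] <= 0) stop("degenerate second moments")
    ratio <- sqrt(ev[1L] / ev[2L])          # a / b
    list(eccentricity = sqrt(max(0, 1 - 1 / ratio^2)), aspect_ratio = ratio)
}

#' Centroid of a polygon
#'
#' Area-weighted centroid via the shoelace decomposition.
#'
#' @inheritParams basicGeometry
#' @return numeric length-2 (x, y).
#' @export
polygonCentroid <- function(poly) {
    .checkPolygon(poly)
    .polygonMoments(poly)$centroid
}
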