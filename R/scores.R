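# Regularity scores on the 0-10 scale: a cell is compared against the
# regular N-gon of equal area (perimeter ratio term) and of equal perimeter
# (area ratio term), each weighted by how convex the cell is. The
# reference perimeter of a regular N-gon of area A follows from
# A = (N/4) s^2 cot(pi/N):  P_ref = N * sqrt(4A / (N cot(pi/N))).

#' Polygonality score (0-10 regularity against the regular N-gon)
#'
#' Scores how closely a cell resembles the regular polygon with as many
#' sides as the cell has neighbors. Two sub-ratios are combined: the
#' perimeter sub-ratio
#' \deqn{PSR = \frac{P_{cell}}{P_{hull}}\Big[1 - \Big|1 -
#'   \frac{P_{cell}}{N\sqrt{4A_{cell}/(N\cot(\pi/N))}}\Big|\Big]}
#' and the area sub-ratio
#' \deqn{PAR = \frac{A_{cell}}{A_{hull}}\Big[1 - \Big|1 -
#'   \frac{4A_{cell}}{N (P_{cell}/N)^2 \cot(\pi/N)}\Big|\Big],}
#' with score \eqn{10\,(PSR + PAR)/2}. A regular N-gon with
#' `nNeighbors = N` scores exactly 10. All arguments are vectorized.
#'
#' Cells with fewer than 3 neighbors have no regular reference polygon;
#' their score is returned as `NA` with the reason in the `reason` field.
#' Extremely elongated cells can drive a bracket negative; raw (possibly
#' negative) values are reported unless `clamp = TRUE`.
#'
#' @param pCell,aCell cell perimeter and area (physical units).
#' @param pHull,aHull perimeter and area of the cell's convex hull.
#' @param nNeighbors neighbor count N of the cell (integer >= 3).
#' @param clamp clamp negative sub-ratios at 0 (default `FALSE`).
#' @return list with vectors `psr`, `par`, `score`, and `reason`
#'   (`NA_character_` where defined).
#' @examples
#' hexRing <- regularPolygon(6)
#' g <- basicGeometry(hexRing)
#' polygonalityScore(g$perimeter, g$area, g$hull_perimeter, g$hull_area, 6)$score
#' @export
polygonalityScore <- function(pCell, aCell, pHull, aHull, nNeighbors,
                              clamp = FALSE) {
    n <- max(length(pCell), length(aCell), length(pHull), length(aHull),
             length(nNeighbors))
    pCell <- rep_len(pCell, n); aCell <- rep_len(aCell, n)
    pHull <- rep_len(pHull, n); aHull <- rep_len(aHull, n)
    N <- rep_len(nNeighbors, n)
    ok <- !is.na(N) & N >= 3 & is.finite(pCell) & is.finite(aCell) &
        pCell > 0 & aCell > 0 & pHull > 0 & aHull > 0
    psr <- par <- score <- rep(NA_real_, n)
    reason <- rep(NA_character_, n)
    reason[!ok] <- ifelse(!is.na(N[!ok]) & N[!ok] < 3,
        "fewer than 3 neighbors", "non-positive geometry")
    if (any(ok)) {
        Nk <- N[ok]
        cotN <- 1 / tan(pi / Nk)
        pRef <- Nk * sqrt(4 * aCell[ok] / (Nk * cotN))
        psrK <- (pCell[ok] / pHull[ok]) * (1 - abs(1 - pCell[ok] / pRef))
        parK <- (aCell[ok] / aHull[ok]) *
            (1 - abs(1 - 4 * aCell[ok] / (Nk * (pCell[ok] / Nk)^2 * cotN)))
        if (clamp) { psrK <- pmax(psrK, 0); parK <- pmax(parK, 0) }
        psr[ok] <- psrK; par[ok] <- parK
        score[ok] <- 10 * (psrK + parK) / 2
    }
    list(psr = psr, par = par, score = score, reason = reason)
}

#' Hexagonality score (0-10 regularity against the regular hexagon)
#'
#' Identical to [polygonalityScore()] with the reference polygon fixed to
#' the hexagon (N = 6), the honeycomb reference for healthy epithelial
#' sheets. A regular hexagon scores exactly 10; a square about 8.957.
#'
#' @inheritParams polygonalityScore
#' @return list with vectors `hsr`, `har`, `score`.
#' @examples
#' g <- basicGeometry(regularPolygon(6))
#' hexagonalityScore(g$perimeter, g$area, g$hull_perimeter, g$hull_area)$score
#' @export
hexagonalityScore <- function(pCell, aCell, pHull, aHull, clamp = FALSE) {
    r <- polygonalityScore(pCell, aCell, pHull, aHull, nNeighbors = 6L,
                           clamp = clamp)
    list(hsr = r$psr, har = r$par, score = r$score)
}

#' Vertices of a regular N-gon
#'
#' Convenience constructor used throughout for reference shapes and tests.
#'
#' @param n number of sides (>= 3).
#' @param side side length (default 1).
#' @param center numeric length-2 center.
#' @return 2-column counter-clockwise vertex matrix.
#' @export
regularPolygon <- function(n, side = 1, center = c(0, 0)) {
    if (n < 3) stop("n must be >= 3")
    R <- side / (2 * sin(pi / n))
    th <- 2 * pi * (seq_len(n) - 1L) / n
    cbind(center[1L] + R * cos(th), center[2L] + R * sin(th))
}
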