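# Shared fixtures: reference polygons and small label images built in code.

# random star-shaped simple polygon around the origin; all angular gaps
# are kept below pi so every edge stays inside its wedge (simplicity)
randomPolygon <- function(nVert = 12L, rMin = 0.5, rMax = 2) {
    repeat {
        th <- sort(stats::runif(nVert, 0, 2 * pi))
        gaps <- diff(c(th, th[1L] + 2 * pi))
        if (max(gaps) < pi) break
    }
    r <- stats::runif(nVert, rMin, rMax)
    cbind(r * cos(th), r * sin(th))
}

# apply a similarity transform (rotation + scale + translation)
similarity <- function(poly, angle, scale, shift) {
    R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
    sweep(poly %*% t(R) * scale, 2L, shift, "+")
}

scoreOf <- function(poly, n = NULL) {
    g <- basicGeometry(poly)
    if (is.null(n))
        hexagonalityScore(g$perimeter, g$area, g$hull_perimeter,
                          g$hull_area)$score
    else
        polygonalityScore(g$perimeter, g$area, g$hull_perimeter,
                          g$hull_area, n)$score
}

# label image with a centered rectangular label
rectLabelImage <- function(nr = 8L, nc = 8L, r = 3:6, cc = 3:6,
                           pixelSize = 1) {
    px <- matrix(0L, nr, nc)
    px[r, cc] <- 1L
    LabelImage(px, pixelSize = pixelSize)
}

# n x n grid of square cells labelled row-wise 1..n^2, each sq x sq px,
# no membrane
gridLabelImage <- function(sq = 4L, n = 3L, pixelSize = 1) {
    px <- matrix(0L, n * sq, n * sq)
    lab <- 0L
    for (i in seq_len(n) - 1L) for (j in seq_len(n) - 1L) {
        lab <- lab + 1L
        px[i * sq + seq_len(sq), j * sq + seq_len(sq)] <- lab
    }
    LabelImage(px, pixelSize = pixelSize)
}

smallSheet <- function(seed = 1, jitter = 0.15, window = c(120, 120),
                       area = 100, ...) {
    generateSheet(generatorConfig(window = window, targetCellArea = area,
                                  jitterSigma = jitter, seed = seed, ...))
}
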