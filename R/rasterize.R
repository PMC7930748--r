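# Exact rasterization of a generated sheet: every pixel center is
# assigned to its nearest Voronoi seed, which reproduces the clipped
# tessellation without point-in-polygon tests.

# 4-connected components of equal-label pixels by iterative min-id
# propagation; returns a matrix of component ids (0 on background).
.labelComponents <- function(lab) {
    # vertical runs of constant label are the nodes; horizontal
    # same-label contacts between adjacent columns are the edges; the
    # component id of a run is the minimum run id reachable from it
    nr <- nrow(lab); nc <- ncol(lab)
    v <- as.vector(lab)
    n <- length(v)
    newrun <- c(TRUE, v[-1L] != v[-n])
    newrun[seq.int(1L, n, by = nr)] <- TRUE
    runId <- cumsum(newrun)
    runLab <- v[newrun]
    nRun <- runId[n]
    # horizontal same-label pixel contacts -> run-graph edges
    left <- v[seq_len(n - nr)]
    right <- v[seq_len(n - nr) + nr]
    e <- which(left == right & left != 0L)
    comp <- seq_len(nRun)
    if (length(e)) {
        ra <- runId[e]; rb <- runId[e + nr]
        key <- ra * (nRun + 1) + rb
        keep <- !duplicated(key)
        ra <- ra[keep]; rb <- rb[keep]
        oA <- order(ra); oB <- order(rb)
        raO <- ra[oA]; rbO <- rb[oB]
        repeat {
            mn <- pmin(comp[ra], comp[rb])
            new <- comp
            # per-run min over incident edges: last write wins, so write
            # in decreasing order within each run
            mA <- mn[oA]; sA <- order(raO, -mA)
            new[raO[sA]] <- pmin(new[raO[sA]], mA[sA])
            mB <- mn[oB]; sB <- order(rbO, -mB)
            new[rbO[sB]] <- pmin(new[rbO[sB]], mB[sB])
            if (identical(new, comp)) break
            comp <- new
        }
    }
    comp[runLab == 0L] <- 0L
    matrix(comp[runId], nr, nc)
}

# Pixel-center sampling of a convex region can leave diagonal-only tips
# at cell corners; keep each label's largest 4-connected component and
# turn strays into membrane (or hand them to a 4-neighbor when the sheet
# has no membrane, so labels stay space-filling).
.dropMinorComponents <- function(lab, toBackground = TRUE) {
    for (pass in 1:5) {
        comp <- .labelComponents(lab)
        ids <- which(lab > 0L)
        cv <- comp[ids]
        uc <- sort(unique(cv))
        if (length(uc) == length(unique(lab[ids]))) return(lab)
        sizes <- tabulate(cv)[uc]
        ulab <- lab[ids[match(uc, cv)]]
        ordr <- order(ulab, -sizes, uc)
        major <- uc[ordr][!duplicated(ulab[ordr])]
        minor <- setdiff(uc, major)
        bad <- matrix(comp %in% minor, nrow(lab), ncol(lab))
        if (toBackground) {
            lab[bad] <- 0L
        } else {
            nr <- nrow(lab); nc <- ncol(lab)
            idx <- which(bad)
            r <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
            pick <- function(rr, ccc) ifelse(rr >= 1L & rr <= nr &
                ccc >= 1L & ccc <= nc, lab[cbind(pmax(pmin(rr, nr), 1L),
                pmax(pmin(ccc, nc), 1L))], 0L)
            nb <- cbind(pick(r - 1L, cc), pick(r + 1L, cc),
                        pick(r, cc - 1L), pick(r, cc + 1L))
            own <- lab[idx]
            nb[nb == own] <- 0L
            repl <- apply(nb, 1L, function(v) {
                v <- v[v > 0L]
                if (length(v)) min(v) else 0L
            })
            lab[idx] <- as.integer(repl)
        }
    }
    lab
}

#' Rasterize an epithelial sheet to a label image
#'
#' Pixel centers are labelled by nearest-seed assignment (exact for
#' Voronoi cells); an optional membrane gap of `membranePx` background
#' pixels is carved along shared edges, emulating the 1-px cell-border
#' skeletons produced by border-segmentation networks.
#'
#' @param sheet an [EpithelialSheet-class].
#' @param pxPerUm raster resolution (pixels per micrometre); defaults to
#'   the generator config value.
#' @param membranePx width of the background membrane in pixels (0 =
#'   abutting cells).
#' @return a [LabelImage-class] with `pixelSize = 1/pxPerUm`; label ids
#'   equal the sheet's cell ids.
#' @export
rasterizeSheet <- function(sheet, pxPerUm = NULL, membranePx = 0L) {
    stopifnot(is(sheet, "EpithelialSheet"))
    if (is.null(pxPerUm)) pxPerUm <- sheet@config$rasterPxPerUm
    meanArea <- mean(vapply(cellPolygons(sheet),
                            function(p) abs(.shoelace(p)), numeric(1)))
    if (pxPerUm * sqrt(meanArea) < 5)
        stop("raster resolution below 5 px per cell diameter")
    W <- sheet@window[1L]; H <- sheet@window[2L]
    nc <- ceiling(W * pxPerUm); nr <- ceiling(H * pxPerUm)
    xs <- (seq_len(nc) - 0.5) / pxPerUm
    ys <- (seq_len(nr) - 0.5) / pxPerUm
    seeds <- sheet@seeds
    ids <- cellData(sheet)$cell_id
    # every pixel's nearest seed lies within the largest cell
    # circumradius, so each tile only needs seeds from a margin around it
    maxR <- sqrt(max(vapply(seq_along(ids), function(i) {
        p <- cellPolygons(sheet)[[i]]
        max((p[, 1L] - seeds[i, 1L])^2 + (p[, 2L] - seeds[i, 2L])^2)
    }, numeric(1))))
    margin <- maxR + 2 / pxPerUm
    lab <- matrix(0L, nr, nc)
    tile <- 160L
    s2 <- rowSums(seeds^2)
    for (r0 in seq(1L, nr, by = tile)) for (c0 in seq(1L, nc, by = tile)) {
        r1 <- min(nr, r0 + tile - 1L); c1 <- min(nc, c0 + tile - 1L)
        cand <- which(seeds[, 2L] >= ys[r0] - margin &
                      seeds[, 2L] <= ys[r1] + margin &
                      seeds[, 1L] >= xs[c0] - margin &
                      seeds[, 1L] <= xs[c1] + margin)
        gx <- rep(xs[c0:c1], each = r1 - r0 + 1L)
        gy <- rep(ys[r0:r1], times = c1 - c0 + 1L)
        G <- cbind(gx, gy)
        d2 <- outer(rep(1, nrow(G)), s2[cand]) -
            2 * G %*% t(seeds[cand, , drop = FALSE])
        nearest <- cand[max.col(-d2, ties.method = "first")]
        lab[r0:r1, c0:c1] <- ids[nearest]
    }
    if (membranePx == 1L) {
        # exactly one membrane pixel between facing cells, whatever the
        # boundary orientation: erode the smaller-label side of every
        # label change (a 1-px border skeleton)
        z <- matrix(FALSE, nr, nc)
        z[, -nc] <- z[, -nc] | (lab[, -nc] != lab[, -1L] &
                                lab[, -nc] < lab[, -1L])
        z[, -1L] <- z[, -1L] | (lab[, -1L] != lab[, -nc] &
                                lab[, -1L] < lab[, -nc])
        z[-nr, ] <- z[-nr, ] | (lab[-nr, ] != lab[-1L, ] &
                                lab[-nr, ] < lab[-1L, ])
        z[-1L, ] <- z[-1L, ] | (lab[-1L, ] != lab[-nr, ] &
                                lab[-1L, ] < lab[-nr, ])
        lab[z] <- 0L
    } else if (membranePx > 1L) {
        # wider membranes: carve where the second-nearest seed is less
        # than `membranePx` pixels farther than the nearest (offset
        # half-plane erosion, so the retained regions stay convex)
        w <- membranePx / pxPerUm
        X <- matrix(xs, nr, nc, byrow = TRUE)
        Y <- matrix(ys, nr, nc)
        sx <- seeds[, 1L][lab]; dim(sx) <- dim(lab)
        sy <- seeds[, 2L][lab]; dim(sy) <- dim(lab)
        d1 <- sqrt((X - sx)^2 + (Y - sy)^2)
        reach <- ceiling(membranePx) + 1L
        d2 <- matrix(Inf, nr, nc)
        shift <- function(mm, dr, dc, fill = 0L) {
            out <- matrix(fill, nr, nc)
            rs <- max(1L, 1L + dr):min(nr, nr + dr)
            cs <- max(1L, 1L + dc):min(nc, nc + dc)
            out[rs, cs] <- mm[rs - dr, cs - dc]
            out
        }
        for (dr in -reach:reach) for (dc in -reach:reach) {
            if (dr == 0L && dc == 0L) next
            cand <- shift(lab, dr, dc)
            use <- cand > 0L & cand != lab
            if (!any(use)) next
            ci <- pmax(cand, 1L)
            cx <- seeds[, 1L][ci]; cy <- seeds[, 2L][ci]
            d <- sqrt((X - cx)^2 + (Y - cy)^2)
            d2[use] <- pmin(d2[use], d[use])
        }
        lab[d2 - d1 < w] <- 0L
    }
    lab <- .dropMinorComponents(lab, toBackground = membranePx > 0L)
    LabelImage(lab, pixelSize = 1 / pxPerUm)
}

#' Paint circular damaged regions into an exclusion mask
#'
#' Adds (or creates) an exclusion mask marking damaged areas, emulating
#' manually annotated regions that are excluded from analysis.
#'
#' @param img a [LabelImage-class].
#' @param centers 2-column matrix of circle centers (physical units).
#' @param radii numeric vector of radii (physical units, recycled).
#' @return the [LabelImage-class] with an updated `exclusionMask`.
#' @export
paintDamageMask <- function(img, centers, radii) {
    stopifnot(is(img, "LabelImage"))
    centers <- matrix(centers, ncol = 2L)
    radii <- rep_len(radii, nrow(centers))
    px <- labelPixels(img); ps <- pixelSize(img)
    nr <- nrow(px); nc <- ncol(px)
    xs <- (seq_len(nc) - 0.5) * ps
    ys <- (seq_len(nr) - 0.5) * ps
    mask <- if (is.null(exclusionMask(img))) matrix(FALSE, nr, nc)
            else exclusionMask(img)
    for (i in seq_len(nrow(centers))) {
        dx2 <- outer(rep(1, nr), (xs - centers[i, 1L])^2)
        dy2 <- outer((ys - centers[i, 2L])^2, rep(1, nc))
        mask <- mask | (dx2 + dy2 <= radii[i]^2)
    }
    LabelImage(px, pixelSize = ps, exclusionMask = mask)
}
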