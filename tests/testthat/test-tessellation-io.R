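test_that("label TIFFs round-trip bit-exactly", {
    px <- matrix(0L, 4L, 4L)
    px[2:3, 2:3] <- 1L
    img <- LabelImage(px, pixelSize = 0.5)
    tf <- withr::local_tempfile(fileext = ".tif")
    writeLabelImage(img, tf)
    back <- readLabelImage(tf, pixelSize = 0.5)
    expect_identical(labelPixels(back), px)
    expect_identical(sort(unique(as.vector(labelPixels(back)))), c(0L, 1L))
    expect_equal(pixelSize(back), 0.5)

    # a generated sheet raster round-trips identically
    sheet <- smallSheet(seed = 3)
    ras <- rasterizeSheet(sheet, membranePx = 1L)
    tf2 <- withr::local_tempfile(fileext = ".tif")
    writeLabelImage(ras, tf2)
    expect_identical(labelPixels(readLabelImage(tf2)), labelPixels(ras))
})

test_that("8-bit PNG label masks are decoded to the original integers", {
    px <- matrix(0L, 6L, 6L)
    px[2:4, 3:5] <- 7L
    tf <- withr::local_tempfile(fileext = ".png")
    png::writePNG(px / 255, tf)
    expect_identical(labelPixels(readLabelImage(tf)), px)
})

test_that("malformed image input is rejected", {
    tf <- withr::local_tempfile(fileext = ".tif")
    rgb <- array(runif(48), dim = c(4L, 4L, 3L))
    tiff::writeTIFF(rgb, tf)
    expect_error(readLabelImage(tf), "RGB|channel")
    expect_error(readLabelImage("no/such/file.tif"), "not found")
})

test_that("LabelImage validity enforces the label-mask invariants", {
    expect_error(LabelImage(matrix(-1L, 2, 2)), "non-negative")
    expect_error(LabelImage(matrix(1L, 2, 2),
                            exclusionMask = matrix(FALSE, 3, 3)),
                 "dimensions")
    expect_error(LabelImage(matrix(1L, 2, 2), pixelSize = -1), "positive")
})

test_that("polygon extraction honors the pixel-area convention exactly", {
    img <- rectLabelImage(nr = 12L, nc = 12L, r = 2:11, cc = 2:11)
    mos <- extractCellPolygons(img)
    g <- basicGeometry(cellPolygons(mos)[[1L]])
    expect_equal(g$area, 100)
    expect_equal(g$perimeter, 40)
    expect_false(cellData(mos)$touches_border)

    # physical units: pixel_size scales area quadratically
    img2 <- rectLabelImage(nr = 12L, nc = 12L, r = 2:11, cc = 2:11,
                           pixelSize = 0.25)
    g2 <- basicGeometry(cellPolygons(extractCellPolygons(img2))[[1L]])
    expect_equal(g2$area, 100 * 0.25^2)

    # area = pixel count * pixelSize^2 for every label of a jittered sheet
    sheet <- smallSheet(seed = 8, jitter = 0.4)
    ras <- rasterizeSheet(sheet, membranePx = 1L)
    mos3 <- extractCellPolygons(ras)
    counts <- table(labelPixels(ras)[labelPixels(ras) > 0L])
    for (i in seq_len(nrow(cellData(mos3)))) {
        id <- cellData(mos3)$cell_id[i]
        expect_equal(abs(epimorph:::.shoelace(cellPolygons(mos3)[[i]])),
                     as.numeric(counts[[as.character(id)]]) *
                         pixelSize(ras)^2)
    }
})

test_that("border and damage flags are set from pixels and the mask", {
    px <- matrix(0L, 6L, 6L)
    px[1:2, 3:4] <- 1L          # touches row 1
    px[4:5, 4:5] <- 2L
    mask <- matrix(FALSE, 6L, 6L)
    mask[4L, 4L] <- TRUE
    mos <- extractCellPolygons(LabelImage(px, exclusionMask = mask))
    cd <- cellData(mos)
    expect_identical(cd$touches_border, c(TRUE, FALSE))
    expect_identical(cd$in_damaged_region, c(FALSE, TRUE))
})

test_that("multi-component labels are an error naming the label", {
    px <- matrix(0L, 6L, 6L)
    px[2L, 2L] <- 7L
    px[5L, 5L] <- 7L
    expect_error(extractCellPolygons(LabelImage(px)), "7.*components")
})

test_that("adjacency follows the facing-pixel-pair rule", {
    # two abutting 10x10 squares: one edge, degree 1 each
    px <- matrix(0L, 12L, 22L)
    px[2:11, 2:11] <- 1L
    px[2:11, 12:21] <- 2L
    g <- buildAdjacency(LabelImage(px))
    expect_equal(nrow(g@edges), 1L)
    expect_equal(unname(neighborCounts(g)), c(1L, 1L))
    expect_equal(g@edges$length, 10)

    # corner contact only: below the 3-pair threshold
    px2 <- matrix(0L, 9L, 9L)
    px2[1:4, 1:4] <- 1L
    px2[5:8, 5:8] <- 2L
    g2 <- buildAdjacency(LabelImage(px2), minSharedPx = 3L)
    expect_equal(nrow(g2@edges), 0L)

    # one membrane pixel between two cells still counts
    px3 <- matrix(0L, 6L, 11L)
    px3[2:5, 2:4] <- 1L
    px3[2:5, 6:9] <- 2L
    g3 <- buildAdjacency(LabelImage(px3))
    expect_equal(nrow(g3@edges), 1L)

    expect_error(buildAdjacency(LabelImage(px3), minSharedPx = 0L), ">= 1")
})

test_that("adjacency is symmetric and invariant under label permutation", {
    sheet <- smallSheet(seed = 4, jitter = 0.3)
    ras <- rasterizeSheet(sheet, membranePx = 1L)
    g <- buildAdjacency(ras)
    expect_true(all(g@edges$a < g@edges$b))

    # permute labels and compare edge sets through the permutation
    px <- labelPixels(ras)
    ids <- sort(unique(px[px > 0L]))
    set.seed(1)
    perm <- sample(ids)
    map <- integer(max(ids)); map[ids] <- perm
    px2 <- px; px2[px2 > 0L] <- map[px2[px2 > 0L]]
    g2 <- buildAdjacency(LabelImage(px2, pixelSize = pixelSize(ras)))
    k1 <- sort(paste(pmin(map[g@edges$a], map[g@edges$b]),
                     pmax(map[g@edges$a], map[g@edges$b])))
    k2 <- sort(paste(g2@edges$a, g2@edges$b))
    expect_identical(k1, k2)
})

test_that("shared boundary length of an interior cell stays below its perimeter", {
    sheet <- smallSheet(seed = 6, jitter = 0.25)
    ras <- rasterizeSheet(sheet, membranePx = 0L)
    g <- buildAdjacency(ras)
    mos <- extractCellPolygons(ras)
    cd <- cellData(mos)
    interior <- cd$cell_id[!cd$touches_border]
    perims <- vapply(cellPolygons(mos), epimorph:::.perimeterOf, numeric(1))
    for (id in interior) {
        shared <- sum(g@edges$length[g@edges$a == id | g@edges$b == id])
        deg <- sum(g@edges$a == id | g@edges$b == id)
        expect_lte(shared,
                   perims[[as.character(id)]] + deg * pixelSize(ras))
    }
})

test_that("filterAnalysisSet removes flagged cells but keeps their adjacency", {
    img <- gridLabelImage(sq = 4L)
    mos <- extractCellPolygons(img)
    g <- buildAdjacency(img)
    kept <- filterAnalysisSet(setAdjacency(mos, g))
    expect_identical(cellData(kept)$cell_id, 5L)  # center of the 3x3 grid
    m <- measureCells(kept)
    expect_equal(m$n_neighbors, 4L)   # 4-connected sharing, all 8 excluded
                                      # cells still counted as neighbors

    # mask over the left half of a 4x4 grid removes overlapping cells
    px <- labelPixels(gridLabelImage(sq = 3L, n = 4L))
    mask <- matrix(FALSE, nrow(px), ncol(px))
    mask[, 1:6] <- TRUE
    mos2 <- extractCellPolygons(LabelImage(px, exclusionMask = mask))
    expect_identical(cellData(filterAnalysisSet(mos2))$cell_id, c(7L, 11L))

    allBorder <- extractCellPolygons(rectLabelImage(r = 1:8, cc = 1:8))
    expect_warning(filterAnalysisSet(allBorder), "no cells remain")
})

test_that("metrics tables round-trip through CSV", {
    sheet <- smallSheet(seed = 2)
    m <- measureCells(filterAnalysisSet(sheet))
    m$mouse <- "m1"; m$genotype <- "control"; m$age <- 1
    tf <- withr::local_tempfile(fileext = ".csv")
    writeMetricsTable(m, tf)
    back <- readMetricsTable(tf)
    expect_identical(names(back)[1:4], c("mouse", "genotype", "age",
                                         "sample_id"))
    expect_equal(back$area, m$area, tolerance = 1e-12)
    expect_equal(back$hexagonality_score, m$hexagonality_score,
                 tolerance = 1e-12)

    # zero cells: header-only file
    tf2 <- withr::local_tempfile(fileext = ".csv")
    writeMetricsTable(m[0, ], tf2)
    expect_equal(nrow(readMetricsTable(tf2)), 0L)
    expect_error(writeMetricsTable(m, "no/such/dir/x.csv"), "cannot write")
})

test_that("GeoJSON polygon exchange preserves geometry and metadata", {
    sheet <- smallSheet(seed = 5)
    tf <- withr::local_tempfile(fileext = ".geojson")
    writePolygonsGeoJSON(sheet, tf)
    back <- readPolygonsGeoJSON(tf)
    expect_equal(nrow(cellData(back)), nrow(cellData(sheet)))
    expect_identical(cellData(back)$touches_border,
                     cellData(sheet)$touches_border)
    a0 <- vapply(cellPolygons(sheet), epimorph:::.shoelace, numeric(1))
    a1 <- vapply(cellPolygons(back), epimorph:::.shoelace, numeric(1))
    expect_equal(unname(a1), unname(a0), tolerance = 1e-12)
})
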