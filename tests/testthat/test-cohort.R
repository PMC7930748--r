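tinyDesign <- function(seed = 1, ...) {
    cohortDesign(ages = c(1, 6), micePerGroup = 2L, imagesPerMouse = 1L,
                 baseConfig = generatorConfig(window = c(120, 120),
                                              targetCellArea = 100,
                                              dropoutFraction = 0.005),
                 seed = seed, ...)
}

test_that("simulateCohort produces complete, consistent metadata and truth", {
    co <- simulateCohort(tinyDesign())
    imgs <- cohortImages(co)
    expect_equal(nrow(imgs), 2 * 2 * 2)   # genotype x age x mouse
    expect_setequal(unique(imgs$genotype), c("control", "mutant"))
    expect_equal(length(unique(imgs$mouse)), 8L)

    tr <- cohortTruth(co)
    expect_true(all(c("cell_id", "area", "perimeter", "n_neighbors",
                      "sample_id", "mouse", "genotype", "age")
                    %in% names(tr)))
    # truth agrees with the stored vector geometry
    sid <- imgs$sample_id[1L]
    sheet <- cohortSheets(co)[[sid]]
    areas <- vapply(cellPolygons(sheet),
                    function(p) abs(epimorph:::.shoelace(p)), numeric(1))
    expect_equal(unname(areas), tr$area[tr$sample_id == sid])
})

test_that("cohort simulation is deterministic in the design seed", {
    c1 <- simulateCohort(tinyDesign(seed = 42))
    c2 <- simulateCohort(tinyDesign(seed = 42))
    expect_identical(cohortTruth(c1), cohortTruth(c2))
    c3 <- simulateCohort(tinyDesign(seed = 43))
    expect_false(identical(cohortTruth(c1)$area, cohortTruth(c3)$area))
})

test_that("a null effect map makes the groups exchangeable", {
    em <- expand.grid(genotype = c("control", "mutant"), age = c(1, 6),
                      stringsAsFactors = FALSE)
    em$area_mult <- 1; em$jitter_mult <- 1; em$dropout_mult <- 1
    em$sd_mult <- 1
    co <- simulateCohort(tinyDesign(effectMap = em, mouseSd = 0))
    tr <- cohortTruth(co)
    agg <- tapply(tr$area[!tr$touches_border],
                  tr$genotype[!tr$touches_border], mean)
    expect_equal(unname(agg["mutant"] / agg["control"]), 1,
                 tolerance = 0.05)
})

test_that("injected area and jitter effects are realized in the images", {
    em <- expand.grid(genotype = c("control", "mutant"), age = 1,
                      stringsAsFactors = FALSE)
    em$area_mult <- ifelse(em$genotype == "mutant", 1.5, 1)
    em$jitter_mult <- ifelse(em$genotype == "mutant", 3, 1)
    em$dropout_mult <- 1
    em$sd_mult <- 1
    d <- cohortDesign(ages = 1, micePerGroup = 3L, imagesPerMouse = 1L,
                      mouseSd = 0.02, effectMap = em, seed = 7,
                      baseConfig = generatorConfig(window = c(160, 160),
                                                   targetCellArea = 100))
    m <- cohortMetrics(simulateCohort(d))
    aggA <- tapply(m$area, m$genotype, mean)
    expect_equal(unname(aggA["mutant"] / aggA["control"]), 1.5,
                 tolerance = 0.1)
    aggH <- tapply(m$hexagonality_score, m$genotype, mean)
    expect_lt(aggH["mutant"], aggH["control"])
})

test_that("cohortMetrics carries the grouping metadata the statistics need", {
    m <- cohortMetrics(simulateCohort(tinyDesign()))
    expect_identical(names(m)[1:5],
                     c("mouse", "genotype", "age", "sample_id", "cell_id"))
    expect_false(any(is.na(m$mouse)))
    counts <- table(unique(m[, c("genotype", "mouse")])$genotype)
    expect_true(all(counts >= 2L))
})

test_that("the table-level simulator matches its injected parameters", {
    d <- cohortDesign(ages = 1, micePerGroup = 8L, cellsPerMouse = 2000L,
                      mouseSd = 0, seed = 3,
                      effectMap = data.frame(
                          genotype = c("control", "mutant"), age = 1,
                          area_mult = c(1, 1.5), jitter_mult = 1,
                          dropout_mult = 1, sd_mult = 1))
    tab <- simulateCellTable(d, cellCV = 0.3)
    mu <- tapply(tab$area, tab$genotype, mean)
    expect_equal(unname(mu["mutant"] / mu["control"]), 1.5,
                 tolerance = 0.03)

    # a pure spread effect: equal means, doubled SD
    d2 <- d
    d2$effectMap$area_mult <- 1
    d2$effectMap$sd_mult <- c(1, 2)
    tab2 <- simulateCellTable(d2, cellCV = 0.3)
    mu2 <- tapply(tab2$area, tab2$genotype, mean)
    expect_equal(unname(mu2["mutant"] / mu2["control"]), 1,
                 tolerance = 0.03)
    s <- tapply(tab2$area, tab2$genotype, sd)
    expect_equal(unname(s["mutant"] / s["control"]), 2, tolerance = 0.1)

    # lognormal family keeps the mean ratio and adds right skew
    tabL <- simulateCellTable(d, cellCV = 0.3, family = "lognormal")
    muL <- tapply(tabL$area, tabL$genotype, mean)
    expect_equal(unname(muL["mutant"] / muL["control"]), 1.5,
                 tolerance = 0.05)
    expect_gt(e1071::skewness(tabL$area[tabL$genotype == "control"]), 0.3)
})

test_that("invalid designs are rejected", {
    expect_error(cohortDesign(effectMap = data.frame(genotype = "a")),
                 "genotype")
    em <- data.frame(genotype = c("control", "mutant"), age = 1,
                     area_mult = c(1, -1), jitter_mult = 1,
                     dropout_mult = 1)
    expect_error(cohortDesign(ages = 1, effectMap = em))
})
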