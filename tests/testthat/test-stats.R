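# Cohort tables for these tests are drawn from the hierarchical
# generator's distributional counterpart (simulateCellTable), which is
# fast enough for replicate loops.

nullDesign <- function(seed, mice = 4L, cells = 100L, mouseSd = 0.15) {
    cohortDesign(genotypes = c("control", "mutant"), ages = 1,
                 micePerGroup = mice, cellsPerMouse = cells,
                 mouseSd = mouseSd, seed = seed,
                 effectMap = data.frame(
                     genotype = rep(c("control", "mutant"), each = 1L),
                     age = 1, area_mult = 1, jitter_mult = 1,
                     dropout_mult = 1, sd_mult = 1))
}

effectDesign <- function(seed, areaMult = 1.5, sdMult = 1, mice = 4L,
                         cells = 500L) {
    d <- nullDesign(seed, mice = mice, cells = cells)
    d$effectMap$area_mult[d$effectMap$genotype == "mutant"] <- areaMult
    d$effectMap$sd_mult[d$effectMap$genotype == "mutant"] <- sdMult
    d
}

test_that("two identical groups give a zero mean difference exactly", {
    tab <- simulateCellTable(nullDesign(1))
    half <- tab[tab$genotype == "control", ]
    mirror <- half
    mirror$genotype <- "mutant"
    mirror$mouse <- paste0(mirror$mouse, "_copy")
    res <- fitMeanComparison(rbind(half, mirror), "area")
    expect_equal(res$mean_estimate, 0)
    expect_equal(res$n_cells1, res$n_cells2)

    vres <- fitVarianceComparison(rbind(half, mirror), "area")
    expect_equal(vres$variance_estimate, 0)
})

test_that("swapping group labels negates estimates and keeps p-values", {
    tab <- simulateCellTable(effectDesign(3))
    res1 <- fitMeanComparison(tab, "area")
    tab2 <- tab
    tab2$genotype <- ifelse(tab$genotype == "control", "b_mutant",
                            "a_control")
    res2 <- fitMeanComparison(tab2, "area")
    expect_equal(res2$mean_estimate, -res1$mean_estimate, tolerance = 1e-8)
    expect_equal(res2$mean_p, res1$mean_p, tolerance = 1e-8)

    v1 <- fitVarianceComparison(tab, "area")
    v2 <- fitVarianceComparison(tab2, "area")
    expect_equal(v2$variance_estimate, -v1$variance_estimate,
                 tolerance = 1e-8)
    expect_equal(v2$variance_p, v1$variance_p, tolerance = 1e-8)
})

test_that("the mean test recovers an injected area effect", {
    tab <- simulateCellTable(effectDesign(11))
    res <- fitMeanComparison(tab, "area")
    mu1 <- mean(tab$area[tab$genotype == "control"])
    ratio <- (mu1 + res$mean_estimate) / mu1
    expect_equal(ratio, 1.5, tolerance = 0.1)
    expect_lt(res$mean_p, 0.05)
})

test_that("the variance test detects a pure spread effect", {
    tab <- simulateCellTable(effectDesign(19, areaMult = 1, sdMult = 2))
    vres <- fitVarianceComparison(tab, "area")
    expect_gt(vres$variance_estimate, 0)
    expect_lt(vres$variance_p, 0.05)
    # and the mean test sees nothing dramatic
    mres <- fitMeanComparison(tab, "area")
    expect_gt(mres$mean_p, 0.01)
})

test_that("variance testing uses residuals from the group median", {
    tab <- simulateCellTable(nullDesign(7))
    med <- stats::ave(tab$area, tab$genotype, FUN = stats::median)
    tab2 <- tab
    tab2$area <- abs(tab$area - med)
    byHand <- fitMeanComparison(tab2, "area")
    viaApi <- fitVarianceComparison(tab, "area")
    expect_equal(viaApi$variance_estimate, byHand$mean_estimate)
    expect_equal(viaApi$variance_p, byHand$mean_p)

    # global-median and signed-residual variants differ
    vGlob <- fitVarianceComparison(tab, "area", medianScope = "global")
    expect_false(isTRUE(all.equal(vGlob$variance_estimate,
                                  viaApi$variance_estimate)))
    vSigned <- fitVarianceComparison(tab, "area", residual = "signed")
    expect_false(isTRUE(all.equal(vSigned$variance_estimate,
                                  viaApi$variance_estimate)))
})

test_that("Bonferroni-Dunn doubles and caps both assessment p-values", {
    res <- data.frame(mean_p = c(0.03, 0.7, 1e-6),
                      variance_p = c(0.2, 0.02, 0.6))
    adj <- bonferroniDunnAdjust(res)
    expect_equal(adj$mean_p_adj, c(0.06, 1, 2e-6))
    expect_equal(adj$variance_p_adj, c(0.4, 0.04, 1))
    expect_true(all(adj$mean_p_adj >= adj$mean_p))
    # adjusted ordering preserves raw ordering within the family
    expect_identical(order(adj$mean_p_adj[c(1, 3)]),
                     order(adj$mean_p[c(1, 3)]))
})

test_that("Tukey contrasts reduce to the plain contrast for two groups", {
    tab <- simulateCellTable(effectDesign(5))
    tk <- tukeyPairwise(tab, "area", groups = "genotype")
    res <- fitMeanComparison(tab, "area")
    expect_equal(nrow(tk), 1L)
    expect_equal(tk$estimate, res$mean_estimate, tolerance = 1e-8)
    expect_equal(tk$p_tukey, res$mean_p, tolerance = 1e-8)
})

test_that("Tukey flags only contrasts involving an outlying group", {
    d <- cohortDesign(genotypes = c("g1", "g2", "g3"), ages = 1,
                      micePerGroup = 4L, cellsPerMouse = 200L,
                      mouseSd = 0.05, seed = 2,
                      effectMap = data.frame(
                          genotype = c("g1", "g2", "g3"), age = 1,
                          area_mult = c(1, 1, 2), jitter_mult = 1,
                          dropout_mult = 1, sd_mult = 1))
    tab <- simulateCellTable(d)
    tk <- tukeyPairwise(tab, "area", groups = "genotype")
    expect_equal(nrow(tk), 3L)
    involves3 <- tk$group1 == "g3:1" | tk$group2 == "g3:1" |
        grepl("g3", tk$group1) | grepl("g3", tk$group2)
    expect_true(all(tk$p_tukey[involves3] < 0.05))
    expect_true(all(tk$p_tukey[!involves3] > 0.05))
})

test_that("age trends recover exact linear summaries and flag flat ones", {
    s <- data.frame(age = rep(c(1, 6, 12), each = 2),
                    value = rep(c(1, 6, 12), each = 2) * -0.25 + 3)
    tr <- suppressWarnings(ageTrend(s, "value"))  # lm warns on exact fits
    expect_equal(tr$slope, -0.25)
    expect_equal(tr$direction, "decreasing")
    expect_true(tr$ci_lo <= tr$slope && tr$slope <= tr$ci_hi)

    s$value <- 3
    tr0 <- suppressWarnings(ageTrend(s, "value"))
    expect_equal(tr0$slope, 0)
    expect_equal(tr0$direction, "none")

    expect_error(ageTrend(data.frame(age = c(1, 2), value = c(1, 2)),
                          "value"), "3 distinct ages")
})

test_that("normality diagnostics match distributional limits", {
    set.seed(101)
    tab <- data.frame(genotype = rep(c("a", "b"), each = 1e5),
                      x = c(rnorm(1e5), rexp(1e5)))
    nd <- normalityDiagnostics(tab, "x")
    mm <- nd$moments
    expect_equal(mm$skewness[mm$group == "a"], 0, tolerance = 0.05)
    expect_equal(mm$kurtosis[mm$group == "a"], 0, tolerance = 0.05)
    expect_equal(mm$skewness[mm$group == "b"], 2, tolerance = 0.2)
    qa <- nd$qq[nd$qq$group == "a", ]
    expect_equal(nrow(qa), 1e5)
    expect_true(!is.unsorted(qa$theoretical))
    expect_true(!is.unsorted(qa$sample))

    small <- data.frame(genotype = "a", x = rnorm(5))
    expect_warning(normalityDiagnostics(small, "x"), "n < 8")
})

test_that("ignoring the animal hierarchy inflates the false-positive rate", {
    # strong mouse effects, no genotype effect: the pooled cell-level test
    # rejects far above nominal, the mixed model must not (calibration of
    # the mixed model itself is checked at acceptance scale)
    reps <- 100
    pPooled <- numeric(reps)
    for (r in seq_len(reps)) {
        tab <- simulateCellTable(nullDesign(1000 + r, mouseSd = 0.3))
        pPooled[r] <- fitMeanComparison(tab, "area",
                                        method = "pooled")$mean_p
    }
    expect_gt(mean(pPooled < 0.05), 0.3)
})

test_that("a zero mouse-level variance degrades with a warning, not silence", {
    tab <- simulateCellTable(nullDesign(9, mouseSd = 0))
    w <- capture_warnings(res <- fitMeanComparison(tab, "area"))
    expect_true(any(grepl("singular", w)))
    expect_true(is.finite(res$mean_p))
})

test_that("compareGroups assembles per-age results with markers", {
    d <- cohortDesign(ages = c(1, 6), micePerGroup = 3L,
                      cellsPerMouse = 150L, seed = 4)
    tab <- simulateCellTable(d)
    res <- suppressWarnings(compareGroups(tab, "area"))
    expect_equal(nrow(res), 2L)
    expect_true(all(c("mean_p_adj", "variance_p_adj", "significance")
                    %in% names(res)))
    expect_true(all(res$mean_p_adj >= res$mean_p))
    expect_true(all(res$mean_p_adj <= 1))

    expect_error(fitMeanComparison(tab, "nope"), "missing columns")
    w <- capture_warnings(
        fitMeanComparison(tab[tab$mouse %in% unique(tab$mouse)[c(1, 4)], ],
                          "area"))
    expect_true(any(grepl("fewer than 2 mice", w)))
})
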