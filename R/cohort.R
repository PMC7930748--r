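# Hierarchical synthetic cohorts: cells nested in images nested in mice,
# with per-genotype-by-age effect multipliers and a per-mouse lognormal
# random effect on cell area — the structure needed to exercise the
# repeated-measures statistics.

#' Cohort design
#'
#' Describes a genotype x age x mouse x image design and the injected
#' effects. The default emulates a progressive mutant phenotype: cells
#' become larger (area multiplier), more disordered (jitter multiplier,
#' lowering hexagonality) and patchier (dropout) with age, while the
#' control stays at baseline.
#'
#' @param genotypes character vector (first level is the reference).
#' @param ages numeric vector of ages (e.g. months).
#' @param micePerGroup mice per genotype x age cell (>= 2 for any
#'   statistical use).
#' @param imagesPerMouse images (fields) per mouse.
#' @param effectMap data.frame with columns `genotype`, `age`,
#'   `area_mult`, `jitter_mult`, `dropout_mult` (all > 0); defaults to
#'   control at 1 and a mutant with area x1.5 and age-increasing jitter.
#' @param mouseSd SD of the per-mouse lognormal random effect on cell
#'   area (sdlog scale).
#' @param baseConfig baseline [generatorConfig()].
#' @param cellsPerMouse cells per mouse for the table-level simulator
#'   [simulateCellTable()].
#' @param seed RNG seed for the cohort.
#' @return named list of class `cohortDesign`.
#' @export
cohortDesign <- function(genotypes = c("control", "mutant"),
                         ages = c(1, 6, 12),
                         micePerGroup = 4L,
                         imagesPerMouse = 2L,
                         effectMap = NULL,
                         mouseSd = 0.1,
                         baseConfig = generatorConfig(dropoutFraction = 0.005),
                         cellsPerMouse = 500L,
                         seed = 1L) {
    if (is.null(effectMap)) {
        grid <- expand.grid(genotype = genotypes, age = ages,
                            stringsAsFactors = FALSE)
        mut <- grid$genotype != genotypes[1L]
        ageRank <- match(grid$age, sort(unique(grid$age)))
        effectMap <- data.frame(
            grid,
            area_mult = ifelse(mut, 1.2 + 0.3 * (ageRank - 1), 1),
            jitter_mult = ifelse(mut, 1.5 + 1 * (ageRank - 1), 1),
            dropout_mult = ifelse(mut, 4, 1),
            sd_mult = 1
        )
    }
    if (!"sd_mult" %in% names(effectMap)) effectMap$sd_mult <- 1
    stopifnot(all(c("genotype", "age", "area_mult", "jitter_mult",
                    "dropout_mult") %in% names(effectMap)),
              all(effectMap$area_mult > 0), all(effectMap$jitter_mult > 0),
              all(effectMap$dropout_mult > 0), micePerGroup >= 1L,
              imagesPerMouse >= 1L, mouseSd >= 0)
    structure(list(genotypes = genotypes, ages = ages,
                   micePerGroup = as.integer(micePerGroup),
                   imagesPerMouse = as.integer(imagesPerMouse),
                   effectMap = effectMap, mouseSd = mouseSd,
                   baseConfig = baseConfig,
                   cellsPerMouse = as.integer(cellsPerMouse),
                   seed = as.integer(seed)),
              class = "cohortDesign")
}

.substream <- function(seed, i) as.integer((as.double(seed) * 7919 +
    as.double(i) * 104729) %% 2147483647)

#' Simulate a full image-level cohort
#'
#' Generates one vector tessellation per image of the design: per-group
#' effect multipliers scale the target cell area, jitter and dropout; a
#' per-mouse lognormal random effect multiplies cell area. Deterministic
#' given the design seed (per-image substreams).
#'
#' @param design a [cohortDesign()].
#' @return a [SyntheticCohort-class].
#' @export
simulateCohort <- function(design) {
    stopifnot(inherits(design, "cohortDesign"))
    em <- design$effectMap
    base <- design$baseConfig
    grid <- expand.grid(genotype = design$genotypes, age = design$ages,
                        mouse_idx = seq_len(design$micePerGroup),
                        stringsAsFactors = FALSE)
    grid$mouse <- sprintf("%s_a%s_m%d", grid$genotype, grid$age,
                          grid$mouse_idx)
    mouseEff <- .withSeed(design$seed,
        stats::setNames(stats::rlnorm(nrow(grid), 0, design$mouseSd),
                        grid$mouse))
    sheets <- list(); imgRows <- list(); truthRows <- list()
    imgIdx <- 0L
    for (g in seq_len(nrow(grid))) {
        row <- em[em$genotype == grid$genotype[g] & em$age == grid$age[g], ]
        if (nrow(row) != 1L)
            stop("effectMap must have exactly one row per genotype x age")
        for (im in seq_len(design$imagesPerMouse)) {
            imgIdx <- imgIdx + 1L
            sid <- sprintf("%s_img%d", grid$mouse[g], im)
            cfg <- generatorConfig(
                window = base$window,
                targetCellArea = base$targetCellArea * row$area_mult *
                    mouseEff[[grid$mouse[g]]],
                jitterSigma = base$jitterSigma * row$jitter_mult,
                lloydIterations = base$lloydIterations,
                dropoutFraction = min(0.99,
                    base$dropoutFraction * row$dropout_mult),
                seed = .substream(design$seed, imgIdx),
                rasterPxPerUm = base$rasterPxPerUm)
            sheet <- generateSheet(cfg)
            sheet@sampleId <- sid
            sheet@cells$sample_id <- sid
            sheets[[sid]] <- sheet
            imgRows[[sid]] <- data.frame(
                sample_id = sid, mouse = grid$mouse[g],
                genotype = grid$genotype[g], age = grid$age[g],
                target_area = cfg$targetCellArea,
                jitter_sigma = cfg$jitterSigma,
                dropout = cfg$dropoutFraction)
            tr <- vectorTruth(sheet)
            tr$sample_id <- sid; tr$mouse <- grid$mouse[g]
            tr$genotype <- grid$genotype[g]; tr$age <- grid$age[g]
            truthRows[[sid]] <- tr
        }
    }
    new("SyntheticCohort",
        sheets = sheets,
        images = do.call(rbind, c(imgRows, list(make.row.names = FALSE))),
        truth = do.call(rbind, c(truthRows, list(make.row.names = FALSE))),
        design = unclass(design))
}

#' Per-cell metric table of a synthetic cohort
#'
#' Runs [measureCells()] on every sheet (after border exclusion) and
#' stacks the results with mouse/genotype/age metadata — the cohort table
#' consumed by the group-comparison statistics.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param clamp passed to [measureCells()].
#' @return data.frame of per-cell metrics with metadata columns.
#' @export
cohortMetrics <- function(cohort, clamp = FALSE) {
    stopifnot(is(cohort, "SyntheticCohort"))
    imgs <- cohortImages(cohort)
    out <- lapply(seq_len(nrow(imgs)), function(i) {
        sheet <- cohortSheets(cohort)[[imgs$sample_id[i]]]
        m <- measureCells(filterAnalysisSet(sheet))
        m$mouse <- imgs$mouse[i]; m$genotype <- imgs$genotype[i]
        m$age <- imgs$age[i]
        m
    })
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    meta <- c("mouse", "genotype", "age", "sample_id", "cell_id")
    res[, c(meta, setdiff(names(res), meta))]
}

#' Simulate a cohort table directly at the cell level
#'
#' Draws per-cell metric values from the hierarchical distribution the
#' image generator induces — group effect x lognormal mouse effect x cell
#' noise — without building tessellations. This is the desk-scale path
#' for Monte-Carlo calibration and power studies, where thousands of
#' cohort replicates are needed; means and SD ratios injected through the
#' effect map are exact at the population level.
#'
#' With `family = "normal"`, cell values are
#' `mu * area_mult * mouseEffect + Normal(0, cellCV * mu * sd_mult)`; with
#' `family = "lognormal"` the noise is multiplicative lognormal with unit
#' mean, giving the right-skewed areas seen in real sheets.
#'
#' @param design a [cohortDesign()]; `cellsPerMouse` and `sd_mult` of the
#'   effect map are honored.
#' @param cellCV cell-level coefficient of variation (default 0.35, the
#'   spread a mildly jittered Voronoi sheet produces).
#' @param family `"normal"` or `"lognormal"` cell noise.
#' @param metric name of the simulated metric column (default `"area"`).
#' @return data.frame with `mouse`, `genotype`, `age`, `sample_id` and
#'   the metric column.
#' @export
simulateCellTable <- function(design, cellCV = 0.35,
                              family = c("normal", "lognormal"),
                              metric = "area") {
    stopifnot(inherits(design, "cohortDesign"))
    family <- match.arg(family)
    em <- design$effectMap
    mu0 <- design$baseConfig$targetCellArea
    grid <- expand.grid(genotype = design$genotypes, age = design$ages,
                        mouse_idx = seq_len(design$micePerGroup),
                        stringsAsFactors = FALSE)
    grid$mouse <- sprintf("%s_a%s_m%d", grid$genotype, grid$age,
                          grid$mouse_idx)
    .withSeed(design$seed, {
        mouseEff <- stats::rlnorm(nrow(grid), 0, design$mouseSd)
        out <- lapply(seq_len(nrow(grid)), function(g) {
            row <- em[em$genotype == grid$genotype[g] &
                      em$age == grid$age[g], ]
            n <- design$cellsPerMouse
            mu <- mu0 * row$area_mult * mouseEff[g]
            y <- if (family == "normal") {
                mu + stats::rnorm(n, 0, cellCV * mu0 * row$area_mult *
                                         row$sd_mult)
            } else {
                s <- sqrt(log1p((cellCV * row$sd_mult)^2))
                mu * stats::rlnorm(n, -s^2 / 2, s)
            }
            df <- data.frame(mouse = rep(grid$mouse[g], n),
                             genotype = rep(grid$genotype[g], n),
                             age = rep(grid$age[g], n),
                             sample_id = rep(paste0(grid$mouse[g], "_img1"),
                                             n))
            df[[metric]] <- y
            df
        })
        do.call(rbind, c(out, list(make.row.names = FALSE)))
    })
}
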