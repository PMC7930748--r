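# Genotype/group comparison of morphometrics with the cells-in-mice
# hierarchy: mixed-model marginal-mean contrasts, a robust
# residual-from-median (Brown-Forsythe-style) variance test fitted with
# the same machinery, Bonferroni-Dunn doubling over the {mean, variance}
# assessment pair, Tukey pairwise contrasts, age trends and normality
# diagnostics.

# Cell-means mixed fit: y ~ 0 + group + (1 | mouse), REML. Returns group
# means, their covariance, and the containment (between-mouse) df used
# for contrasts — with few animals, cell-level df would be
# anti-conservative.
.fitCellMeans <- function(y, g, m, method = "mixed") {
    g <- factor(g); m <- factor(m)
    k <- nlevels(g)
    if (method == "pooled") {
        fit <- stats::lm(y ~ 0 + g)
        return(list(means = stats::coef(fit), V = stats::vcov(fit),
                    df = length(y) - k, levels = levels(g),
                    singular = FALSE))
    }
    dd <- data.frame(y = y, g = g, m = m)
    fit <- suppressMessages(lme4::lmer(y ~ 0 + g + (1 | m), data = dd,
                                       REML = TRUE))
    if (lme4::isSingular(fit, tol = 1e-4))
        warning("mouse-level variance estimated at zero (singular fit); ",
                "contrasts fall back to the pooled-residual covariance",
                call. = FALSE)
    means <- lme4::fixef(fit)
    names(means) <- levels(g)
    list(means = means, V = as.matrix(stats::vcov(fit)),
         df = max(1L, nlevels(m) - k), levels = levels(g),
         singular = lme4::isSingular(fit, tol = 1e-4))
}

.pairTest <- function(fit, i, j) {
    est <- fit$means[j] - fit$means[i]
    se <- sqrt(fit$V[i, i] + fit$V[j, j] - 2 * fit$V[i, j])
    tval <- if (se > 0) est / se else ifelse(est == 0, 0, sign(est) * Inf)
    p <- 2 * stats::pt(-abs(tval), fit$df)
    c(estimate = unname(est), se = unname(se), df = fit$df, p = unname(p))
}

#' Mixed-model comparison of group means
#'
#' Fits `metric ~ genotype` with a random intercept per mouse (REML) and
#' reports the marginal-mean difference between the two groups, its
#' standard error and the p-value of the contrast on between-mouse
#' (containment) degrees of freedom.
#'
#' @param data data.frame with one row per cell.
#' @param metric name of the metric column.
#' @param group name of the two-level grouping column (default
#'   `"genotype"`).
#' @param mouse name of the animal id column (default `"mouse"`).
#' @param method `"mixed"` (default) or `"pooled"`, the latter an
#'   ordinary linear model that ignores the animal hierarchy (kept for
#'   demonstrating why the hierarchy matters — it is anti-conservative).
#' @return one-row data.frame: `metric`, `group1`, `group2`,
#'   `mean_estimate` (group2 - group1), `mean_se`, `mean_df`, `mean_p`,
#'   `n_cells1`, `n_cells2`, `n_mice1`, `n_mice2`.
#' @export
fitMeanComparison <- function(data, metric, group = "genotype",
                              mouse = "mouse", method = c("mixed", "pooled")) {
    method <- match.arg(method)
    .checkCohortTable(data, metric, group, mouse)
    y <- data[[metric]]; g <- factor(data[[group]]); m <- data[[mouse]]
    if (nlevels(g) != 2L)
        stop("fitMeanComparison expects exactly 2 groups; see tukeyPairwise")
    fit <- .fitCellMeans(y, g, m, method)
    pt <- .pairTest(fit, 1L, 2L)
    data.frame(
        metric = metric, group1 = fit$levels[1L], group2 = fit$levels[2L],
        mean_estimate = pt[["estimate"]], mean_se = pt[["se"]],
        mean_df = pt[["df"]], mean_p = pt[["p"]],
        n_cells1 = sum(g == fit$levels[1L]),
        n_cells2 = sum(g == fit$levels[2L]),
        n_mice1 = length(unique(m[g == fit$levels[1L]])),
        n_mice2 = length(unique(m[g == fit$levels[2L]]))
    )
}

#' Robust comparison of group spread (residuals from the median)
#'
#' Transforms each observation to its absolute residual from the group
#' median (Brown-Forsythe convention; the signed variant and a global
#' median are available as options) and applies the same mixed-model
#' contrast as [fitMeanComparison()] to the transformed values. The
#' estimate is the difference in mean absolute residuals, a robust
#' dispersion difference.
#'
#' @inheritParams fitMeanComparison
#' @param residual `"absolute"` (default) or `"signed"` residuals.
#' @param medianScope `"group"` (default): median taken within each
#'   group; `"global"`: one median over all cells.
#' @return one-row data.frame like [fitMeanComparison()] but with
#'   `variance_estimate`, `variance_se`, `variance_df`, `variance_p`.
#' @export
fitVarianceComparison <- function(data, metric, group = "genotype",
                                  mouse = "mouse",
                                  method = c("mixed", "pooled"),
                                  residual = c("absolute", "signed"),
                                  medianScope = c("group", "global")) {
    method <- match.arg(method)
    residual <- match.arg(residual)
    medianScope <- match.arg(medianScope)
    .checkCohortTable(data, metric, group, mouse)
    y <- data[[metric]]
    g <- factor(data[[group]])
    med <- if (medianScope == "group")
        stats::ave(y, g, FUN = stats::median) else stats::median(y)
    r <- if (residual == "absolute") abs(y - med) else y - med
    d2 <- data
    d2[[metric]] <- r
    out <- fitMeanComparison(d2, metric, group, mouse, method)
    names(out) <- sub("^mean_", "variance_", names(out))
    names(out) <- sub("^n_", "n_", names(out))
    out
}

.checkCohortTable <- function(data, metric, group, mouse) {
    miss <- setdiff(c(metric, group, mouse), names(data))
    if (length(miss))
        stop("missing columns in cohort table: ", paste(miss, collapse = ", "))
    if (!is.numeric(data[[metric]])) stop("metric must be numeric")
    tab <- table(unique(data.frame(g = data[[group]],
                                   m = data[[mouse]]))$g)
    if (any(tab < 2L))
        warning("fewer than 2 mice in some group; mixed-model contrasts ",
                "are unreliable", call. = FALSE)
    invisible(TRUE)
}

#' Bonferroni-Dunn correction over the mean/variance assessment pair
#'
#' Each metric x contrast is assessed twice — once on raw values (mean)
#' and once on residuals from the median (variance) — so both p-values
#' are multiplied by 2 and capped at 1.
#'
#' @param results data.frame containing `mean_p` and/or `variance_p`
#'   columns.
#' @return the data.frame with `mean_p_adj` / `variance_p_adj` added.
#' @export
bonferroniDunnAdjust <- function(results) {
    if ("mean_p" %in% names(results))
        results$mean_p_adj <- pmin(1, 2 * results$mean_p)
    if ("variance_p" %in% names(results))
        results$variance_p_adj <- pmin(1, 2 * results$variance_p)
    results
}

#' Tukey-adjusted pairwise marginal-mean contrasts
#'
#' Fits one joint mixed model over all genotype x age cells (random
#' intercept per mouse) and tests every pairwise difference of marginal
#' means with the studentized-range (Tukey) family-wise adjustment on
#' between-mouse degrees of freedom. With two groups the Tukey p-value
#' reduces exactly to the unadjusted contrast p-value.
#'
#' @inheritParams fitMeanComparison
#' @param groups character vector of grouping columns whose interaction
#'   defines the cells (default `c("genotype", "age")`).
#' @return data.frame with one row per pair: `group1`, `group2`,
#'   `estimate`, `se`, `df`, `p_tukey`.
#' @export
tukeyPairwise <- function(data, metric, groups = c("genotype", "age"),
                          mouse = "mouse", method = c("mixed", "pooled")) {
    method <- match.arg(method)
    miss <- setdiff(c(metric, groups, mouse), names(data))
    if (length(miss))
        stop("missing columns in cohort table: ", paste(miss, collapse = ", "))
    g <- interaction(data[groups], sep = ":", drop = TRUE)
    fit <- .fitCellMeans(data[[metric]], g, data[[mouse]], method)
    k <- length(fit$levels)
    pairs <- utils::combn(k, 2L)
    out <- lapply(seq_len(ncol(pairs)), function(c0) {
        i <- pairs[1L, c0]; j <- pairs[2L, c0]
        pt <- .pairTest(fit, i, j)
        q <- sqrt(2) * abs(pt[["estimate"]]) / pt[["se"]]
        pT <- if (k == 2L) pt[["p"]]
              else stats::ptukey(q, nmeans = k, df = pt[["df"]],
                                 lower.tail = FALSE)
        data.frame(metric = metric,
                   group1 = fit$levels[i], group2 = fit$levels[j],
                   estimate = pt[["estimate"]], se = pt[["se"]],
                   df = pt[["df"]], p_tukey = pT)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Age trend of a per-group summary
#'
#' Ordinary least-squares slope of a summary statistic (e.g. per-mouse
#' mean hexagonality) against age, with a normal-approximation confidence
#' interval. The direction is the slope's sign when the CI excludes 0,
#' otherwise `"none"`.
#'
#' @param summaries data.frame of summary values (one row per mouse or
#'   group).
#' @param value name of the summary column.
#' @param age name of the age column.
#' @param level CI level (default 0.95).
#' @return one-row data.frame: `slope`, `se`, `ci_lo`, `ci_hi`,
#'   `direction`.
#' @export
ageTrend <- function(summaries, value, age = "age", level = 0.95) {
    x <- summaries[[age]]; y <- summaries[[value]]
    if (length(unique(x)) < 3L)
        stop("age trend needs at least 3 distinct ages")
    fit <- stats::lm(y ~ x)
    est <- stats::coef(fit)[["x"]]
    se <- sqrt(stats::vcov(fit)["x", "x"])
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- est - z * se; hi <- est + z * se
    data.frame(slope = est, se = se, ci_lo = lo, ci_hi = hi,
               direction = if (lo > 0) "increasing"
                           else if (hi < 0) "decreasing" else "none")
}

#' Normality diagnostics per group
#'
#' Standardized skewness and excess kurtosis plus sample-vs-theoretical
#' quantile pairs for q-q plotting, computed per group.
#'
#' @inheritParams fitMeanComparison
#' @param groups grouping columns (default `"genotype"`).
#' @return list with `moments` (data.frame: group, n, skewness, kurtosis,
#'   `small_n` flag for n < 8) and `qq` (data.frame: group, theoretical,
#'   sample).
#' @export
normalityDiagnostics <- function(data, metric, groups = "genotype") {
    g <- interaction(data[groups], sep = ":", drop = TRUE)
    y <- data[[metric]]
    lev <- levels(g)
    mom <- lapply(lev, function(l) {
        x <- y[g == l & is.finite(y)]
        data.frame(group = l, n = length(x),
                   skewness = e1071::skewness(x, type = 1),
                   kurtosis = e1071::kurtosis(x, type = 1),
                   small_n = length(x) < 8L)
    })
    mom <- do.call(rbind, c(mom, list(make.row.names = FALSE)))
    if (any(mom$small_n))
        warning("groups with n < 8: moment estimates are unstable",
                call. = FALSE)
    qq <- lapply(lev, function(l) {
        x <- sort(y[g == l & is.finite(y)])
        data.frame(group = l,
                   theoretical = stats::qnorm(stats::ppoints(length(x))),
                   sample = x)
    })
    list(moments = mom, qq = do.call(rbind, c(qq,
        list(make.row.names = FALSE))))
}

#' Per-age mean and variance comparison of one or more metrics
#'
#' The full comparison the morphometry study runs: at every age, the two
#' genotypes are compared in mean (mixed model on raw values) and in
#' spread (mixed model on absolute residuals from the group median), and
#' the two p-values per metric x age are Bonferroni-Dunn adjusted.
#' Significance markers follow the `*` (mean) / `#` (variance)
#' convention at the given alpha.
#'
#' @inheritParams fitMeanComparison
#' @param metrics character vector of metric columns.
#' @param age name of the age column; set `NULL` to pool ages.
#' @param alpha significance level for the markers (default 0.05).
#' @param ... passed to [fitVarianceComparison()] (residual/medianScope).
#' @return data.frame with one row per metric x age.
#' @export
compareGroups <- function(data, metrics, group = "genotype", age = "age",
                          mouse = "mouse", alpha = 0.05, ...) {
    ages <- if (is.null(age)) NA else sort(unique(data[[age]]))
    out <- list()
    for (metric in metrics) {
        for (a in ages) {
            dd <- if (is.na(a)) data else data[data[[age]] == a, ]
            mres <- fitMeanComparison(dd, metric, group, mouse)
            vres <- fitVarianceComparison(dd, metric, group, mouse, ...)
            row <- cbind(age = a, mres,
                         vres[, c("variance_estimate", "variance_se",
                                  "variance_df", "variance_p")])
            out[[length(out) + 1L]] <- row
        }
    }
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    res <- bonferroniDunnAdjust(res)
    res$significance <- paste0(ifelse(res$mean_p_adj <= alpha, "*", ""),
                               ifelse(res$variance_p_adj <= alpha, "#", ""))
    res
}
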