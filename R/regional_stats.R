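## Covariate-adjusted regional volumetrics: ANCOVA group comparison per ROI
## and partial Spearman correlation, with Bonferroni correction over the ROI
## family.

#' ANCOVA comparison of an ROI volume between groups
#'
#' Fits `outcome ~ group + covariate` by least squares and tests the group
#' factor with the nested-model F-test (group effect adjusted for the
#' covariate, e.g. estimated intracranial volume).  Adjusted group means are
#' evaluated at the covariate mean.  Bonferroni correction over `mTests`
#' (the number of ROIs in the family; a parameter, never hard-coded).
#'
#' @param values numeric outcome per subject (one ROI's volumes).
#' @param groups group label per subject (>= 2 groups of >= 3 subjects).
#' @param covariate numeric per-subject covariate; must be non-constant.
#' @param mTests Bonferroni family size.
#' @param roi label recorded in the result.
#' @return data.frame row with `roi`, `test`, `statistic` (F), `df1`, `df2`,
#'   `p_raw`, `p_adjusted`, and `mean_<group>` adjusted means.
#' @export
ancovaGroupCompare <- function(values, groups, covariate, mTests = 28L,
                               roi = "roi") {
    groups <- as.factor(groups)
    if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
    if (any(table(groups) < 3)) stop("each group needs >= 3 subjects", call. = FALSE)
    if (var(covariate) == 0) stop("constant covariate", call. = FALSE)
    full <- lm(values ~ groups + covariate)
    if (any(is.na(coef(full)))) stop("singular design", call. = FALSE)
    reduced <- lm(values ~ covariate)
    rssF <- stats::deviance(full)
    rssR <- stats::deviance(reduced)
    df1 <- stats::df.residual(reduced) - stats::df.residual(full)
    df2 <- stats::df.residual(full)
    Fstat <- (max(0, rssR - rssF) / df1) / (rssF / df2)
    p <- pf(Fstat, df1, df2, lower.tail = FALSE)
    cf <- coef(full)
    cm <- mean(covariate)
    adj <- setNames(numeric(nlevels(groups)), levels(groups))
    adj[1] <- cf["(Intercept)"] + cf["covariate"] * cm
    for (lv in levels(groups)[-1])
        adj[lv] <- adj[1] + cf[paste0("groups", lv)]
    out <- data.frame(roi = roi, test = "ancova_group", statistic = Fstat,
                      df1 = df1, df2 = df2, p_raw = p,
                      p_adjusted = min(1, mTests * p),
                      stringsAsFactors = FALSE)
    for (lv in levels(groups)) out[[paste0("mean_", lv)]] <- adj[[lv]]
    out
}

#' Partial Spearman correlation with one covariate
#'
#' Rank-transforms `x`, `y` and the covariate, residualizes the ranks of `x`
#' and `y` against an intercept plus the covariate ranks, and correlates the
#' residuals (Pearson on ranks).  The p-value uses the t approximation with
#' `n - 3` degrees of freedom.
#'
#' @param x,y numeric vectors (>= 5 complete observations).
#' @param covariate numeric vector, same length.
#' @return list with `rho` and `p`.
#' @export
spearmanPartial <- function(x, y, covariate) {
    keep <- stats::complete.cases(x, y, covariate)
    x <- x[keep]; y <- y[keep]; covariate <- covariate[keep]
    n <- length(x)
    if (n < 5) stop("need at least 5 complete triples", call. = FALSE)
    if (var(x) == 0 || var(y) == 0 || var(covariate) == 0)
        stop("constant input", call. = FALSE)
    rx <- rank(x); ry <- rank(y); rc <- rank(covariate)
    q <- qr(cbind(1, rc))
    ex <- qr.resid(q, rx)
    ey <- qr.resid(q, ry)
    rho <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
    rho <- max(-1, min(1, rho))
    df <- n - 3
    if (abs(rho) >= 1) {
        p <- 0
    } else {
        tval <- rho * sqrt(df / (1 - rho^2))
        p <- 2 * pt(-abs(tval), df)
    }
    list(rho = rho, p = p)
}

#' Regional statistics across all ROIs of a cohort
#'
#' Runs [ancovaGroupCompare()] for every ROI of a (raw or normalized) volume
#' table, using a named covariate column, with Bonferroni correction over the
#' number of ROIs tested.
#'
#' @param x a `RoiVolumeExperiment` with >= 2 groups.
#' @param covariateName covariate column to adjust for (e.g. `"ICV"`).
#' @return data.frame, one row per ROI, in ROI order.
#' @export
regionalAncova <- function(x, covariateName = "ICV") {
    stopifnot(is(x, "RoiVolumeExperiment"))
    vm <- volumeMatrix(x)
    g <- groupLabels(x)
    cv <- covariates(x, covariateName)
    m <- ncol(vm)
    do.call(rbind, lapply(seq_len(m), function(j)
        ancovaGroupCompare(vm[, j], g, cv, mTests = m, roi = colnames(vm)[j])))
}

#' Covariate-adjusted Spearman correlations of ROI volumes with a variable
#'
#' @param x a `RoiVolumeExperiment`.
#' @param partner numeric per-subject variable (e.g. a cognitive score).
#' @param covariateName covariate column to adjust for.
#' @param partnerName label recorded in the result.
#' @return data.frame with `roi`, `test`, `partner_variable`, `rho`, `p_raw`,
#'   `p_adjusted` (Bonferroni over ROIs).
#' @export
regionalSpearman <- function(x, partner, covariateName = "ICV",
                             partnerName = "score") {
    stopifnot(is(x, "RoiVolumeExperiment"))
    vm <- volumeMatrix(x)
    cv <- covariates(x, covariateName)
    m <- ncol(vm)
    do.call(rbind, lapply(seq_len(m), function(j) {
        r <- spearmanPartial(vm[, j], partner, cv)
        data.frame(roi = colnames(vm)[j], test = "spearman_partial",
                   partner_variable = partnerName, rho = r$rho, p_raw = r$p,
                   p_adjusted = min(1, m * r$p), stringsAsFactors = FALSE)
    }))
}
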