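## Permutation inference on nodal network metrics between two groups, with
## Benjamini-Hochberg FDR correction.

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjustment: with p-values sorted ascending,
#' `adjusted_(i) = min_{j >= i} min(1, m * p_(j) / j)`, mapped back to the
#' original order (ties stable); rejection where `adjusted <= alpha`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param alpha significance level in (0, 1).
#' @return list with `adjusted` (same order as `p`) and `reject` (logical).
#' @export
bhFdr <- function(p, alpha = 0.05) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
    m <- length(p)
    ord <- order(p)                      # stable: ties keep original index order
    val <- m * p[ord] / seq_len(m)
    adjSorted <- pmin(1, rev(cummin(rev(val))))
    adjusted <- numeric(m)
    adjusted[ord] <- adjSorted
    list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Permutation comparison of a nodal metric between two group networks
#'
#' The observed statistic is the per-node difference
#' `metric(netA) - metric(netB)`.  Two null models are available:
#'
#' * `nullMode = "rewire"`: each permutation draws one
#'   degree-preserving rewired surrogate of each network and records the
#'   per-node metric difference between the surrogate pair, building a null
#'   distribution of differences per node.
#' * `nullMode = "subject_permutation"`: group labels are shuffled across the
#'   pooled subject table and both covariance networks are rebuilt from the
#'   shuffled groups each permutation (requires `tableA`/`tableB`, the
#'   normalized single-group volume tables the networks were built from).
#'   This null is exchangeable under "no group difference" and is the mode
#'   with a guaranteed type-I calibration property.
#'
#' Raw p-values use the add-one rule
#' `p = (1 + #exceedances) / (1 + nPerm)` (never exactly zero);
#' `sidedness = "two_sided_abs"` (default) counts `|null| >= |observed|`,
#' `"one_sided_greater"` counts `null >= observed`.  BH-FDR is applied across
#' nodes.  Deterministic given `seed`.
#'
#' @param netA,netB `GroupNetwork` objects sharing the same ROI order.
#' @param metric `"strength"`, `"betweenness"` or `"weighted_clustering"`.
#' @param nPerm number of permutations (study-scale default 10000).
#' @param seed integer RNG seed.
#' @param nullMode `"rewire"` or `"subject_permutation"`.
#' @param sidedness `"two_sided_abs"` or `"one_sided_greater"`.
#' @param alpha FDR significance level.
#' @param tableA,tableB normalized single-group `RoiVolumeExperiment`s
#'   (subject_permutation only).
#' @param swapMultiplier attempted swaps per edge for rewire surrogates.
#' @return a [PermutationComparison-class].
#' @export
nodalPermutationTest <- function(netA, netB,
                                 metric = c("strength", "betweenness",
                                            "weighted_clustering"),
                                 nPerm = 10000L, seed = 1L,
                                 nullMode = c("rewire", "subject_permutation"),
                                 sidedness = c("two_sided_abs",
                                               "one_sided_greater"),
                                 alpha = 0.05, tableA = NULL, tableB = NULL,
                                 swapMultiplier = 10L) {
    metric <- match.arg(metric)
    nullMode <- match.arg(nullMode)
    sidedness <- match.arg(sidedness)
    stopifnot(is(netA, "GroupNetwork"), is(netB, "GroupNetwork"), nPerm >= 1)
    if (!identical(netA@roiNames, netB@roiNames))
        stop("networks must share the same ROI names and order", call. = FALSE)
    n <- length(netA@roiNames)
    obsA <- metricKernel(netA@weights, metric)
    obsB <- metricKernel(netB@weights, metric)
    obsDiff <- obsA - obsB

    nullDiffs <- matrix(0, nrow = nPerm, ncol = n)
    if (nullMode == "rewire") {
        for (b in seq_len(nPerm)) {
            wa <- rewireKernel(netA@weights, swapMultiplier, subSeed(seed, 2L * b - 1L))
            wb <- rewireKernel(netB@weights, swapMultiplier, subSeed(seed, 2L * b))
            nullDiffs[b, ] <- metricKernel(wa, metric) - metricKernel(wb, metric)
        }
    } else {
        if (is.null(tableA) || is.null(tableB))
            stop("subject_permutation requires tableA and tableB", call. = FALSE)
        stopifnot(is(tableA, "RoiVolumeExperiment"),
                  is(tableB, "RoiVolumeExperiment"))
        if (!isNormalized(tableA) || !isNormalized(tableB))
            stop("subject_permutation tables must be TIV-normalized", call. = FALSE)
        vmA <- volumeMatrix(tableA)
        vmB <- volumeMatrix(tableB)
        if (!identical(colnames(vmA), netA@roiNames) ||
            !identical(colnames(vmB), netB@roiNames))
            stop("tables must match network ROI order", call. = FALSE)
        covNames <- netA@covariatesUsed
        covPool <- NULL
        if (length(covNames)) {
            covPool <- rbind(
                matrix(sapply(covNames, function(nm) covariates(tableA, nm)),
                       ncol = length(covNames)),
                matrix(sapply(covNames, function(nm) covariates(tableB, nm)),
                       ncol = length(covNames)))
            colnames(covPool) <- covNames
        }
        pool <- rbind(vmA, vmB)
        nA <- nrow(vmA)
        nTot <- nrow(pool)
        for (b in seq_len(nPerm)) {
            old <- .Random.seed.save()
            set.seed(subSeed(seed, b))
            idx <- sample.int(nTot, nA)
            .Random.seed.restore(old)
            inA <- logical(nTot)
            inA[idx] <- TRUE
            wa <- truncatedCorrelation(pool[inA, , drop = FALSE],
                                       if (is.null(covPool)) NULL
                                       else covPool[inA, , drop = FALSE])
            wb <- truncatedCorrelation(pool[!inA, , drop = FALSE],
                                       if (is.null(covPool)) NULL
                                       else covPool[!inA, , drop = FALSE])
            nullDiffs[b, ] <- metricKernel(wa, metric) - metricKernel(wb, metric)
        }
    }

    exceed <- if (sidedness == "two_sided_abs") {
        colSums(abs(nullDiffs) >= matrix(abs(obsDiff), nPerm, n, byrow = TRUE))
    } else {
        colSums(nullDiffs >= matrix(obsDiff, nPerm, n, byrow = TRUE))
    }
    pRaw <- (1 + exceed) / (1 + nPerm)
    fdr <- bhFdr(pRaw, alpha)
    nullSummary <- data.frame(
        roi = netA@roiNames,
        null_mean = colMeans(nullDiffs),
        null_sd = apply(nullDiffs, 2, sd),
        null_q025 = apply(nullDiffs, 2, stats::quantile, probs = 0.025),
        null_q975 = apply(nullDiffs, 2, stats::quantile, probs = 0.975),
        row.names = NULL, stringsAsFactors = FALSE)
    new("PermutationComparison", metric = metric,
        groupPair = c(netA@group, netB@group), roiNames = netA@roiNames,
        observedA = unname(obsA), observedB = unname(obsB),
        observedDiff = unname(obsDiff), nullSummary = nullSummary,
        pRaw = unname(pRaw), pFdr = unname(fdr$adjusted),
        significant = unname(fdr$reject), alpha = alpha,
        nPerm = as.integer(nPerm), seed = as.integer(seed),
        nullMode = nullMode, sidedness = sidedness)
}

#' Write a permutation comparison as tidy CSV plus JSON null summaries
#'
#' The CSV mirrors the shape of published nodal-comparison tables: one row
#' per brain region with the metric values in both groups, their difference
#' (A - B, the convention recorded in the JSON metadata), and raw and
#' FDR-corrected p-values.  The JSON sidecar (`<path>.meta.json`) carries the
#' per-node null summaries and full run metadata.
#'
#' @param comparison a `PermutationComparison`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeComparison <- function(comparison, path) {
    stopifnot(is(comparison, "PermutationComparison"))
    df <- data.frame(brain_region = comparison@roiNames,
                     metric = comparison@metric,
                     value_A = fmt17(comparison@observedA),
                     value_B = fmt17(comparison@observedB),
                     difference = fmt17(comparison@observedDiff),
                     p_raw = fmt17(comparison@pRaw),
                     p_fdr = fmt17(comparison@pFdr),
                     significant = comparison@significant,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
    meta <- list(group_A = comparison@groupPair[1],
                 group_B = comparison@groupPair[2],
                 difference_convention = "A_minus_B",
                 metric = comparison@metric, n_perm = comparison@nPerm,
                 seed = comparison@seed, null_mode = comparison@nullMode,
                 sidedness = comparison@sidedness, alpha = comparison@alpha,
                 null_summary = comparison@nullSummary)
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", pretty = TRUE)
    invisible(path)
}
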