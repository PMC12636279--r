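## End-to-end driver: cohort -> per-group networks -> nodal + global metrics
## -> all pairwise permutation comparisons -> tidy artifacts + manifest.

pipelineLog <- function(level, fmt, ...) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Run the full structural covariance network pipeline
#'
#' Stages: load (or simulate) the cohort, TIV-normalize, optionally restrict
#' to an ROI list, split by group, build one covariance network per group,
#' compute nodal metrics and small-world indices, and compare every pair of
#' groups on every nodal metric with the permutation test.  Writes, per
#' group: `adjacency_<group>.csv` (+ `.meta.json`), `nodal_<group>.csv`,
#' `global_<group>.csv`; per group pair and metric:
#' `compare_<A>_vs_<B>_<metric>.csv` (+ `.meta.json`); plus `manifest.json`
#' echoing the configuration, seeds and package version.  All randomness
#' derives from the single `seed`, so a rerun reproduces every table
#' byte-for-byte (the manifest timestamp aside).
#'
#' @param input a `RoiVolumeExperiment`, a `SyntheticCohortSpec`, or a path
#'   to a CSV/TSV volume table.
#' @param outputDir directory for artifacts (created if needed).
#' @param rois optional ordered ROI subset (default: all ROIs in the table).
#' @param method `"auto"` (partial_pearson with ICV when an ICV covariate is
#'   present, else pearson), `"pearson"`, or `"partial_pearson"`.
#' @param covariateNames covariates for partial_pearson (default `"ICV"`).
#' @param nPerm permutations per group comparison.
#' @param nNullSmallworld null-ensemble size for small-worldness.
#' @param alpha FDR significance level, in (0, 1).
#' @param sidedness permutation sidedness (see [nodalPermutationTest()]).
#' @param nullMode permutation null (`"rewire"` is the SCN-standard
#'   rewiring null; `"subject_permutation"` relabels subjects).
#' @param seed root integer seed for every stage.
#' @param minSubjects smallest admissible group.
#' @return invisibly, a list with the networks, metric tables, global
#'   summaries, comparisons and the manifest path.
#' @export
runPipeline <- function(input, outputDir, rois = NULL,
                        method = c("auto", "pearson", "partial_pearson"),
                        covariateNames = "ICV", nPerm = 10000L,
                        nNullSmallworld = 10000L, alpha = 0.05,
                        sidedness = "two_sided_abs", nullMode = "rewire",
                        seed = 1L, minSubjects = 4L) {
    method <- match.arg(method)
    if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
        stop("alpha must be in (0, 1)", call. = FALSE)
    if (nPerm < 1 || nNullSmallworld < 1)
        stop("nPerm and nNullSmallworld must be positive", call. = FALSE)
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)

    pipelineLog("INFO", "stage load")
    tab <- if (is(input, "RoiVolumeExperiment")) input
           else if (is(input, "SyntheticCohortSpec")) generateCohort(input)
           else readVolumeTable(input)
    if (length(unique(groupLabels(tab))) < 2)
        stop("pipeline requires at least 2 groups", call. = FALSE)

    pipelineLog("INFO", "stage normalize")
    if (!isNormalized(tab)) tab <- normalizeToTivFraction(tab)
    if (!is.null(rois)) tab <- selectRois(tab, rois)

    if (method == "auto") {
        haveCovs <- all(covariateNames %in% colnames(covariates(tab)))
        method <- if (haveCovs) "partial_pearson" else "pearson"
        pipelineLog("INFO", "method auto-resolved to %s", method)
    }
    if (method == "pearson") covariateNames <- character()

    pipelineLog("INFO", "stage networks (method=%s)", method)
    tables <- splitByGroup(tab, minSubjects)
    nets <- lapply(tables, buildCovarianceNetwork, method = method,
                   covariateNames = covariateNames)

    summaries <- list()
    gi <- 0L
    for (g in names(nets)) {
        gi <- gi + 1L
        safe <- gsub("[^A-Za-z0-9_-]", "-", g)
        writeAdjacency(nets[[g]], file.path(outputDir,
                                            sprintf("adjacency_%s.csv", safe)))
        writeNodalMetrics(nets[[g]], file.path(outputDir,
                                               sprintf("nodal_%s.csv", safe)))
        pipelineLog("INFO", "stage smallworld %s", g)
        sw <- smallWorldness(nets[[g]], nNull = nNullSmallworld,
                             seed = subSeed(seed, 1000L + gi))
        if (sw@disconnected)
            pipelineLog("WARN", "group %s network is disconnected", g)
        writeGlobalMetrics(sw, g, file.path(outputDir,
                                            sprintf("global_%s.csv", safe)))
        summaries[[g]] <- sw
    }

    metrics <- c("strength", "betweenness", "weighted_clustering")
    comparisons <- list()
    labels <- names(nets)
    pairIdx <- 0L
    for (a in seq_along(labels)) for (b in seq_along(labels)) {
        if (b <= a) next
        pairIdx <- pairIdx + 1L
        for (mi in seq_along(metrics)) {
            m <- metrics[mi]
            pipelineLog("INFO", "stage compare %s vs %s (%s)",
                        labels[a], labels[b], m)
            cmp <- nodalPermutationTest(
                nets[[labels[a]]], nets[[labels[b]]], metric = m,
                nPerm = nPerm, seed = subSeed(seed, 2000L + 10L * pairIdx + mi),
                nullMode = nullMode, sidedness = sidedness, alpha = alpha,
                tableA = tables[[labels[a]]], tableB = tables[[labels[b]]])
            sa <- gsub("[^A-Za-z0-9_-]", "-", labels[a])
            sb <- gsub("[^A-Za-z0-9_-]", "-", labels[b])
            writeComparison(cmp, file.path(outputDir,
                sprintf("compare_%s_vs_%s_%s.csv", sa, sb, m)))
            comparisons[[sprintf("%s_vs_%s_%s", labels[a], labels[b], m)]] <- cmp
        }
    }

    manifest <- list(
        package = "scovnet",
        version = as.character(utils::packageVersion("scovnet")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        config = list(method = method, covariates = covariateNames,
                      n_perm = nPerm, n_null_smallworld = nNullSmallworld,
                      alpha = alpha, sidedness = sidedness,
                      null_mode = nullMode, seed = seed,
                      min_subjects = minSubjects),
        groups = lapply(tables, function(t) ncol(t)),
        rois = roiNames(tab))
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    pipelineLog("INFO", "pipeline complete: %s", outputDir)
    invisible(list(networks = nets, global = summaries,
                   comparisons = comparisons,
                   manifest = file.path(outputDir, "manifest.json")))
}
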