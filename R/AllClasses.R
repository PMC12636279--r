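#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom stats cor lm pf pt qnorm rnorm sd setNames var coef anova
#'   complete.cases quantile p.adjust
#' @importFrom utils read.csv write.csv write.table combn packageVersion
#' @importFrom Rcpp sourceCpp
#' @useDynLib scovnet, .registration = TRUE
NULL

#' Subject-by-ROI volume container
#'
#' `RoiVolumeExperiment` holds a cohort of regional gray-matter volumes as a
#' [SummarizedExperiment::SummarizedExperiment] with ROIs as rows and subjects
#' as columns.  `colData` carries the required per-subject fields `subject_id`
#' (unique), `group` and `tiv` (total intracranial volume, > 0), plus any
#' number of additional numeric covariate columns (e.g. `ICV`, `age`).
#' `metadata(x)$normalized` records whether the single `"volumes"` assay holds
#' raw volumes or TIV fractions.
#'
#' Validity requires: unique subject ids matching `colnames`, a group label
#' for every subject, strictly positive `tiv`, no missing cells, strictly
#' positive volumes, and — once normalized — every value in (0, 1).
#'
#' @aliases RoiVolumeExperiment
#' @export
setClass("RoiVolumeExperiment", contains = "SummarizedExperiment")

setValidity("RoiVolumeExperiment", function(object) {
    msgs <- character()
    cd <- colData(object)
    need <- c("subject_id", "group", "tiv")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(sprintf("missing required colData column(s): %s",
                       paste(miss, collapse = ", ")))
    if (!"volumes" %in% names(assays(object)))
        return("assay 'volumes' is required")
    ids <- as.character(cd$subject_id)
    if (anyDuplicated(ids))
        msgs <- c(msgs, sprintf("duplicated subject_id: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (!identical(ids, colnames(object)))
        msgs <- c(msgs, "colnames must equal colData$subject_id")
    if (any(is.na(cd$group)) || any(!nzchar(as.character(cd$group))))
        msgs <- c(msgs, "every subject needs a non-empty group label")
    if (any(is.na(cd$tiv)) || any(cd$tiv <= 0))
        msgs <- c(msgs, "tiv must be positive for every subject")
    v <- assay(object, "volumes")
    if (any(is.na(v))) {
        bad <- which(is.na(v), arr.ind = TRUE)[1, ]
        msgs <- c(msgs, sprintf("missing volume for subject '%s', ROI '%s'",
                                colnames(v)[bad[2]], rownames(v)[bad[1]]))
    } else if (any(v <= 0)) {
        bad <- which(v <= 0, arr.ind = TRUE)[1, ]
        msgs <- c(msgs, sprintf("non-positive volume for subject '%s', ROI '%s'",
                                colnames(v)[bad[2]], rownames(v)[bad[1]]))
    } else if (isTRUE(metadata(object)$normalized) && any(v >= 1)) {
        msgs <- c(msgs, "normalized volume fractions must lie in (0, 1)")
    }
    if (length(msgs)) msgs else TRUE
})

#' Weighted group-level structural covariance network
#'
#' One symmetric, nonnegative, zero-diagonal adjacency matrix built from the
#' across-subject (partial) Pearson correlations of ROI volumes within one
#' group.  Negative correlations are truncated to zero, so all weights lie in
#' \[0, 1\].
#'
#' @slot group group label the network was built from.
#' @slot roiNames ordered ROI identifiers (rows/cols of `weights`).
#' @slot weights n x n numeric adjacency matrix.
#' @slot nSubjects number of subjects the correlations were estimated from.
#' @slot method `"pearson"` or `"partial_pearson"`.
#' @slot covariatesUsed covariate names partialled out (empty for pearson).
#' @slot metadata free-form provenance list (negative rule, seeds, notes).
#' @export
setClass("GroupNetwork",
    representation(group = "character", roiNames = "character",
                   weights = "matrix", nSubjects = "integer",
                   method = "character", covariatesUsed = "character",
                   metadata = "list"),
    prototype(metadata = list(negative_rule = "truncate_zero")))

setValidity("GroupNetwork", function(object) {
    w <- object@weights
    n <- length(object@roiNames)
    if (!is.numeric(w) || nrow(w) != n || ncol(w) != n)
        return("weights must be a numeric matrix matching roiNames")
    if (any(is.na(w))) return("weights must not contain NA")
    if (max(abs(w - t(w))) > 1e-12) return("weights must be symmetric")
    if (any(diag(w) != 0)) return("diagonal must be exactly 0")
    if (any(w < 0) || any(w > 1)) return("weights must lie in [0, 1]")
    if (!object@method %in% c("pearson", "partial_pearson"))
        return("method must be 'pearson' or 'partial_pearson'")
    TRUE
})

#' Global small-world metric summary
#'
#' Holds the global clustering coefficient `C`, characteristic path length
#' `L`, their means `Crand`, `Lrand` over an ensemble of degree-preserving
#' rewired surrogates, the normalized ratios `gamma = C/Crand`,
#' `lambda = L/Lrand`, and the small-world index `sigma = gamma/lambda`.
#'
#' @slot C,L observed global clustering and characteristic path length.
#' @slot Crand,Lrand null-ensemble means.
#' @slot gamma,lambda,sigma normalized ratios and small-world index.
#' @slot nNull ensemble size. @slot seed RNG seed used.
#' @slot disconnected TRUE when some node pair was unreachable.
#' @export
setClass("GlobalMetricSummary",
    representation(C = "numeric", L = "numeric", Crand = "numeric",
                   Lrand = "numeric", gamma = "numeric", lambda = "numeric",
                   sigma = "numeric", nNull = "integer", seed = "integer",
                   disconnected = "logical"))

setValidity("GlobalMetricSummary", function(object) {
    if (abs(object@sigma - object@gamma / object@lambda) > 1e-12)
        return("sigma must equal gamma/lambda")
    TRUE
})

#' Permutation comparison of nodal metrics between two group networks
#'
#' @slot metric one of `"strength"`, `"betweenness"`, `"weighted_clustering"`.
#' @slot groupPair labels (A, B) of the compared networks.
#' @slot roiNames node order shared by both networks.
#' @slot observedA,observedB per-node metric values.
#' @slot observedDiff per-node A - B.
#' @slot nullSummary per-node data.frame of null mean, sd, q025, q975.
#' @slot pRaw,pFdr raw and BH-adjusted permutation p-values.
#' @slot significant logical mask at `alpha` after FDR.
#' @slot alpha significance level.
#' @slot nPerm permutation count. @slot seed RNG seed.
#' @slot nullMode `"rewire"` or `"subject_permutation"`.
#' @slot sidedness `"two_sided_abs"` or `"one_sided_greater"`.
#' @export
setClass("PermutationComparison",
    representation(metric = "character", groupPair = "character",
                   roiNames = "character", observedA = "numeric",
                   observedB = "numeric", observedDiff = "numeric",
                   nullSummary = "data.frame", pRaw = "numeric",
                   pFdr = "numeric", significant = "logical",
                   alpha = "numeric", nPerm = "integer", seed = "integer",
                   nullMode = "character", sidedness = "character"))

setValidity("PermutationComparison", function(object) {
    lo <- 1 / (object@nPerm + 1)
    if (any(object@pRaw < lo - 1e-12) || any(object@pRaw > 1 + 1e-12))
        return("pRaw must lie in [1/(nPerm+1), 1]")
    if (any(object@pFdr + 1e-12 < object@pRaw))
        return("pFdr must be >= pRaw elementwise")
    if (!identical(object@significant, unname(object@pFdr <= object@alpha)))
        return("significant must equal pFdr <= alpha")
    TRUE
})

#' Generative recipe for a synthetic cohort
#'
#' Describes a multi-group cohort of TIV fractions drawn from multivariate
#' normal distributions with a shared base correlation target and optional
#' per-group edge perturbations (added to the base correlation, then repaired
#' to the nearest positive-semidefinite correlation matrix).
#'
#' @slot groups named integer vector of group sizes.
#' @slot nRoi number of ROIs.
#' @slot baseCorrelation nRoi x nRoi target correlation matrix.
#' @slot edgePerturbations named list (by group) of data.frames with columns
#'   `i`, `j`, `delta` added to the base correlation for that group.
#' @slot roiMeanFraction per-ROI mean TIV fraction.
#' @slot roiCv per-ROI coefficient of variation of the fractions.
#' @slot tivMean,tivSd TIV distribution parameters (same units as volumes).
#' @slot seed RNG seed.
#' @export
setClass("SyntheticCohortSpec",
    representation(groups = "integer", nRoi = "integer",
                   baseCorrelation = "matrix", edgePerturbations = "list",
                   roiMeanFraction = "numeric", roiCv = "numeric",
                   tivMean = "numeric", tivSd = "numeric", seed = "integer"))

setValidity("SyntheticCohortSpec", function(object) {
    n <- object@nRoi
    if (is.null(names(object@groups)) || any(object@groups < 1))
        return("groups must be a named vector of positive sizes")
    R <- object@baseCorrelation
    if (nrow(R) != n || ncol(R) != n) return("baseCorrelation must be nRoi x nRoi")
    if (max(abs(diag(R) - 1)) > 1e-10) return("baseCorrelation diagonal must be 1")
    if (max(abs(R - t(R))) > 1e-10) return("baseCorrelation must be symmetric")
    for (g in names(object@edgePerturbations)) {
        Rg <- perturbedCorrelation(object, g)
        ev <- min(eigen(Rg, symmetric = TRUE, only.values = TRUE)$values)
        if (ev < -1e-10)
            return(sprintf("perturbed correlation for group '%s' not PSD after repair", g))
    }
    if (length(object@roiMeanFraction) != n || any(object@roiMeanFraction <= 0))
        return("roiMeanFraction must be positive, length nRoi")
    if (length(object@roiCv) != n || any(object@roiCv <= 0))
        return("roiCv must be positive, length nRoi")
    if (object@tivMean <= 0 || object@tivSd <= 0)
        return("tivMean and tivSd must be positive")
    TRUE
})

setMethod("show", "RoiVolumeExperiment", function(object) {
    cat(sprintf("RoiVolumeExperiment: %d subjects x %d ROIs (%s)\n",
                ncol(object), nrow(object),
                if (isTRUE(metadata(object)$normalized)) "TIV fractions" else "raw volumes"))
    tab <- table(colData(object)$group)
    cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                           collapse = ", "), "\n")
})

setMethod("show", "GroupNetwork", function(object) {
    w <- object@weights
    pos <- sum(w[upper.tri(w)] > 0)
    cat(sprintf("GroupNetwork '%s': %d nodes, %d positive edges, method=%s%s, n=%d subjects\n",
                object@group, length(object@roiNames), pos, object@method,
                if (length(object@covariatesUsed))
                    sprintf(" (covariates: %s)", paste(object@covariatesUsed, collapse = ","))
                else "", object@nSubjects))
})

setMethod("show", "GlobalMetricSummary", function(object) {
    cat(sprintf(paste0("GlobalMetricSummary: C=%.4f L=%.4f  Crand=%.4f Lrand=%.4f  ",
                       "gamma=%.3f lambda=%.3f sigma=%.3f  (%d nulls%s)\n"),
                object@C, object@L, object@Crand, object@Lrand, object@gamma,
                object@lambda, object@sigma, object@nNull,
                if (object@disconnected) ", disconnected" else ""))
})

setMethod("show", "PermutationComparison", function(object) {
    cat(sprintf("PermutationComparison %s vs %s, metric=%s, %d permutations (%s, %s)\n",
                object@groupPair[1], object@groupPair[2], object@metric,
                object@nPerm, object@nullMode, object@sidedness))
    cat(sprintf("  significant nodes at FDR %.2g: %d of %d\n",
                object@alpha, sum(object@significant), length(object@roiNames)))
})

setMethod("show", "SyntheticCohortSpec", function(object) {
    cat(sprintf("SyntheticCohortSpec: %d ROIs, groups %s, seed %d\n",
                object@nRoi,
                paste(sprintf("%s=%d", names(object@groups), object@groups),
                      collapse = " "), object@seed))
})
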