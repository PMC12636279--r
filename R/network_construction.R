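#' Build a weighted structural covariance network for one group
#'
#' Edges are the pairwise Pearson correlation coefficients of ROI volume
#' fractions across the subjects of one group; for
#' `method = "partial_pearson"` each ROI vector is first residualized against
#' an intercept plus the named covariates (least-squares projection) and the
#' Pearson correlation of the residuals is used.  Negative correlations are
#' truncated to zero after the (partial) correlation is computed, and the
#' diagonal is forced to zero, so the adjacency is symmetric with weights in
#' \[0, 1\].
#'
#' @param x a TIV-normalized single-group `RoiVolumeExperiment`.
#' @param method `"pearson"` (default) or `"partial_pearson"`.
#' @param covariateNames covariate columns to partial out (partial_pearson
#'   only); each must be a non-constant numeric colData column.
#' @return a validated [GroupNetwork-class].
#' @export
buildCovarianceNetwork <- function(x, method = c("pearson", "partial_pearson"),
                                   covariateNames = character()) {
    method <- match.arg(method)
    stopifnot(is(x, "RoiVolumeExperiment"))
    if (!isNormalized(x))
        stop("network construction requires a TIV-normalized table", call. = FALSE)
    g <- unique(groupLabels(x))
    if (length(g) != 1)
        stop("expected a single-group table; use splitByGroup() first", call. = FALSE)
    vm <- volumeMatrix(x)
    if (method == "pearson") covariateNames <- character()
    covs <- NULL
    if (method == "partial_pearson") {
        if (!length(covariateNames))
            stop("partial_pearson requires at least one covariate name", call. = FALSE)
        covs <- sapply(covariateNames, function(nm) covariates(x, nm))
        covs <- matrix(covs, nrow = nrow(vm),
                       dimnames = list(NULL, covariateNames))
        const <- apply(covs, 2, function(v) var(v) == 0)
        if (any(const))
            stop(sprintf("zero-variance covariate: %s",
                         paste(covariateNames[const], collapse = ", ")),
                 call. = FALSE)
    }
    w <- truncatedCorrelation(vm, covs)
    new("GroupNetwork", group = g, roiNames = colnames(vm), weights = w,
        nSubjects = nrow(vm), method = method,
        covariatesUsed = as.character(covariateNames),
        metadata = list(negative_rule = "truncate_zero",
                        distance_rule = "inverse_weight"))
}

# Core adjacency computation on a subjects x ROIs matrix; covs NULL for plain
# Pearson, else a subjects x k covariate matrix partialled out by projection
# onto [1, covs].  Used directly (without S4 wrapping) inside permutation
# loops where construction cost matters.
truncatedCorrelation <- function(vm, covs = NULL) {
    n <- nrow(vm)
    k <- if (is.null(covs)) 0L else ncol(covs)
    if (n < 4L + k)
        stop(sprintf("insufficient subjects (%d) for %d covariate(s): need >= %d",
                     n, k, 4L + k), call. = FALSE)
    sds <- apply(vm, 2, sd)
    if (any(sds == 0))
        stop(sprintf("zero-variance ROI within group: %s",
                     paste(colnames(vm)[sds == 0], collapse = ", ")),
             call. = FALSE)
    if (!is.null(covs)) {
        q <- qr(cbind(1, covs))
        vm <- qr.resid(q, vm)
        sds <- apply(vm, 2, sd)
        if (any(sds == 0))
            stop(sprintf("ROI fully explained by covariates: %s",
                         paste(colnames(vm)[sds == 0], collapse = ", ")),
                 call. = FALSE)
    }
    r <- cor(vm)
    w <- pmax(r, 0)
    diag(w) <- 0
    w <- (w + t(w)) / 2
    dimnames(w) <- NULL
    w
}

#' Write / read a GroupNetwork adjacency as CSV plus JSON metadata
#'
#' `writeAdjacency()` emits a square CSV with ROI names as header row and
#' first column (values printed with 17 significant digits, so the read-back
#' is bit-exact) and a `<path>.meta.json` sidecar with group, method,
#' covariates, subject count and provenance.  `readAdjacency()` inverts it.
#'
#' @param network a `GroupNetwork`.
#' @param path CSV file path.
#' @return `writeAdjacency`: `path` invisibly; `readAdjacency`: a
#'   `GroupNetwork`.
#' @export
writeAdjacency <- function(network, path) {
    stopifnot(is(network, "GroupNetwork"))
    w <- networkWeights(network)
    df <- data.frame(roi = rownames(w),
                     apply(w, 2, fmt17), check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
    meta <- list(group = network@group, roi_names = network@roiNames,
                 n_subjects = network@nSubjects, method = network@method,
                 covariates_used = network@covariatesUsed,
                 metadata = network@metadata)
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname writeAdjacency
#' @export
readAdjacency <- function(path) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    rois <- df$roi
    w <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(w) <- "double"
    dimnames(w) <- NULL
    meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
    new("GroupNetwork", group = meta$group, roiNames = rois, weights = w,
        nSubjects = as.integer(meta$n_subjects), method = meta$method,
        covariatesUsed = as.character(meta$covariates_used),
        metadata = as.list(meta$metadata))
}

# Internal: wrap a raw weight matrix as a GroupNetwork reusing provenance.
networkLike <- function(template, w, note = NULL) {
    md <- template@metadata
    if (!is.null(note)) md$note <- note
    new("GroupNetwork", group = template@group, roiNames = template@roiNames,
        weights = w, nSubjects = template@nSubjects, method = template@method,
        covariatesUsed = template@covariatesUsed, metadata = md)
}

#' Construct a GroupNetwork directly from a weight matrix
#'
#' Convenience constructor for simulation studies and tests: wraps a
#' symmetric nonnegative matrix (diagonal ignored, forced to zero) as a
#' `GroupNetwork`.
#'
#' @param w square numeric matrix of weights in \[0, 1\].
#' @param group label recorded on the network.
#' @param roiNames node names; defaults to `V1..Vn` or dimnames of `w`.
#' @param nSubjects subject count recorded in provenance (0 when synthetic).
#' @return a validated `GroupNetwork`.
#' @export
groupNetworkFromMatrix <- function(w, group = "net",
                                   roiNames = NULL, nSubjects = 0L) {
    w <- as.matrix(w)
    if (is.null(roiNames))
        roiNames <- if (!is.null(rownames(w))) rownames(w)
                    else paste0("V", seq_len(nrow(w)))
    diag(w) <- 0
    dimnames(w) <- NULL
    new("GroupNetwork", group = group, roiNames = roiNames, weights = w,
        nSubjects = as.integer(nSubjects), method = "pearson",
        covariatesUsed = character(),
        metadata = list(negative_rule = "truncate_zero",
                        distance_rule = "inverse_weight"))
}
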