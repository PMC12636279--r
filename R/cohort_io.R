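#' Construct a RoiVolumeExperiment from plain vectors and a matrix
#'
#' @param volumes subjects x ROIs numeric matrix of positive volumes, with
#'   ROI column names.
#' @param subjectId character vector of unique subject identifiers.
#' @param group group label per subject.
#' @param tiv positive total intracranial volume per subject, same units as
#'   `volumes`.
#' @param covariates optional data.frame of per-subject numeric covariates.
#' @param normalized set TRUE only when `volumes` already holds TIV fractions.
#' @return a validated [RoiVolumeExperiment-class].
#' @export
RoiVolumeExperiment <- function(volumes, subjectId, group, tiv,
                                covariates = NULL, normalized = FALSE) {
    volumes <- as.matrix(volumes)
    if (is.null(colnames(volumes)))
        stop("volumes must have ROI column names", call. = FALSE)
    subjectId <- as.character(subjectId)
    cd <- DataFrame(subject_id = subjectId, group = as.character(group),
                    tiv = as.numeric(tiv), row.names = subjectId)
    if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
        covariates <- as.data.frame(covariates)
        for (nm in colnames(covariates)) cd[[nm]] <- as.numeric(covariates[[nm]])
    }
    a <- t(volumes)
    colnames(a) <- subjectId
    se <- SummarizedExperiment(assays = list(volumes = a), colData = cd)
    metadata(se)$normalized <- isTRUE(normalized)
    new("RoiVolumeExperiment", se)
}

#' Read a subject-by-ROI volume table from CSV/TSV
#'
#' Expects a header `subject_id,group,tiv[,cov:<name>...],<roi1>,<roi2>,...`;
#' columns prefixed `cov:` are stored as per-subject covariates, every other
#' column after `tiv` is an ROI.  Values must be positive with no missing
#' cells; `subject_id` must be unique.  Row order is preserved and the result
#' is marked unnormalized.
#'
#' @param path file to read.
#' @param format `"csv"` or `"tsv"`; default guessed from the file extension.
#' @return a validated [RoiVolumeExperiment-class] with `normalized = FALSE`.
#' @export
readVolumeTable <- function(path, format = c("auto", "csv", "tsv")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    df <- read.csv(path, sep = if (format == "tsv") "\t" else ",",
                   check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("subject_id", "group", "tiv")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
             call. = FALSE)
    ids <- as.character(df$subject_id)
    if (anyDuplicated(ids))
        stop(sprintf("duplicated subject_id: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             call. = FALSE)
    covCols <- grep("^cov:", colnames(df), value = TRUE)
    roiCols <- setdiff(colnames(df), c(need, covCols))
    if (!length(roiCols)) stop("no ROI columns found", call. = FALSE)
    vols <- as.matrix(df[, roiCols, drop = FALSE])
    if (!is.numeric(vols) || any(is.na(vols))) {
        bad <- which(is.na(suppressWarnings(apply(vols, 2, as.numeric))),
                     arr.ind = TRUE)
        if (length(bad))
            stop(sprintf("non-numeric or missing volume for subject '%s', ROI '%s'",
                         ids[bad[1, 1]], roiCols[bad[1, 2]]), call. = FALSE)
        storage.mode(vols) <- "double"
    }
    if (any(vols <= 0)) {
        bad <- which(vols <= 0, arr.ind = TRUE)[1, ]
        stop(sprintf("non-positive volume (%g) for subject '%s', ROI '%s'",
                     vols[bad[1], bad[2]], ids[bad[1]], roiCols[bad[2]]),
             call. = FALSE)
    }
    rownames(vols) <- ids
    covs <- NULL
    if (length(covCols)) {
        covs <- df[, covCols, drop = FALSE]
        colnames(covs) <- sub("^cov:", "", covCols)
    }
    RoiVolumeExperiment(vols, ids, df$group, df$tiv, covariates = covs,
                        normalized = FALSE)
}

#' Write a volume table in the package's CSV/TSV dialect
#'
#' Round-trips the format accepted by [readVolumeTable()]: covariates are
#' emitted with a `cov:` prefix, numeric values at full double precision.
#'
#' @param x a `RoiVolumeExperiment`.
#' @param path output file.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeVolumeTable <- function(x, path, format = c("csv", "tsv")) {
    format <- match.arg(format)
    stopifnot(is(x, "RoiVolumeExperiment"))
    covs <- covariates(x)
    df <- data.frame(subject_id = subjectIds(x), group = groupLabels(x),
                     tiv = fmt17(tiv(x)), check.names = FALSE,
                     stringsAsFactors = FALSE)
    for (nm in colnames(covs)) df[[paste0("cov:", nm)]] <- fmt17(covs[[nm]])
    vm <- volumeMatrix(x)
    for (r in colnames(vm)) df[[r]] <- fmt17(vm[, r])
    write.table(df, path, sep = if (format == "tsv") "\t" else ",",
                row.names = FALSE, quote = FALSE)
    invisible(path)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Convert raw ROI volumes to TIV fractions
#'
#' Divides each subject's ROI volumes by that subject's total intracranial
#' volume, yielding the dimensionless fractions from which covariance
#' networks are built.  Refuses to normalize twice.
#'
#' @param x an unnormalized `RoiVolumeExperiment`.
#' @return the same cohort with `volumes` as TIV fractions and
#'   `metadata(x)$normalized == TRUE`.
#' @export
normalizeToTivFraction <- function(x) {
    stopifnot(is(x, "RoiVolumeExperiment"))
    if (isNormalized(x))
        stop("table is already TIV-normalized", call. = FALSE)
    a <- assay(x, "volumes")
    a <- sweep(a, 2, tiv(x), "/")
    assays(x, withDimnames = FALSE)[["volumes"]] <- a
    metadata(x)$normalized <- TRUE
    validObject(x)
    x
}

#' @importFrom SummarizedExperiment assays<-
NULL

#' Restrict a cohort to an ordered subset of ROIs
#'
#' @param x a `RoiVolumeExperiment`.
#' @param rois ordered character vector of ROI names to keep; defaults to the
#'   shipped 28-region thalamic subdivision list ([thalamicRoiNames()]).
#' @return the cohort restricted to `rois` in the requested order.
#' @export
selectRois <- function(x, rois = thalamicRoiNames()) {
    stopifnot(is(x, "RoiVolumeExperiment"))
    miss <- setdiff(rois, roiNames(x))
    if (length(miss))
        stop(sprintf("ROI(s) not present: %s", paste(miss, collapse = ", ")),
             call. = FALSE)
    x[rois, ]
}

#' Split a cohort into one table per group
#'
#' @param x a `RoiVolumeExperiment`.
#' @param minSubjects smallest group size accepted (correlation networks are
#'   degenerate below it); default 4.
#' @return named list of `RoiVolumeExperiment`, one per group label, each
#'   inheriting the normalized flag; the union of subjects equals the input.
#' @export
splitByGroup <- function(x, minSubjects = 4L) {
    stopifnot(is(x, "RoiVolumeExperiment"))
    g <- groupLabels(x)
    tab <- table(g)
    small <- names(tab)[tab < minSubjects]
    if (length(small))
        stop(sprintf("group(s) below the minimum of %d subjects: %s",
                     minSubjects, paste(small, collapse = ", ")), call. = FALSE)
    out <- lapply(unique(g), function(lbl) x[, g == lbl])
    names(out) <- unique(g)
    out
}

#' Default thalamic ROI list (28 bilateral subdivisions)
#'
#' The 14 AAL3 thalamic subdivisions in both hemispheres, with the reuniens
#' nucleus excluded (too small for reliable registration).  Shipped as an
#' editable plain-text config (`inst/extdata/thalamic_rois.txt`); the network
#' engine itself is atlas-agnostic.
#'
#' @return character vector of 28 ROI names (left/right interleaved).
#' @export
thalamicRoiNames <- function() {
    path <- system.file("extdata", "thalamic_rois.txt", package = "scovnet",
                        mustWork = TRUE)
    readLines(path)
}

#' Homologous left/right ROI index pairs for a bilateral ROI list
#'
#' For an ROI naming scheme with `_L`/`_R` suffixes, returns the index pairs
#' of left/right homologues — the node pairs whose coupling the synthetic
#' cohort generator elevates.
#'
#' @param rois character vector of ROI names.
#' @return data.frame with columns `i`, `j` (1-based indices into `rois`).
#' @export
homologousPairs <- function(rois = thalamicRoiNames()) {
    left <- grep("_L$", rois)
    base <- sub("_L$", "", rois[left])
    right <- match(paste0(base, "_R"), rois)
    keep <- !is.na(right)
    data.frame(i = left[keep], j = right[keep])
}
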