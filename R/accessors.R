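#' Accessors for the package's S4 containers
#'
#' Small generics used throughout the pipeline instead of direct slot access:
#' `roiNames()` (node/ROI order), `volumeMatrix()` (subjects x ROIs numeric
#' matrix), `groupLabels()`, `tiv()`, `subjectIds()`, `isNormalized()`,
#' `networkWeights()`, `networkGroup()`, `networkMethod()`.
#'
#' @param x a `RoiVolumeExperiment` or `GroupNetwork` as appropriate.
#' @return vectors or matrices as described per generic.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' @rdname accessors
#' @export
setGeneric("volumeMatrix", function(x) standardGeneric("volumeMatrix"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("tiv", function(x) standardGeneric("tiv"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("networkWeights", function(x) standardGeneric("networkWeights"))

#' @rdname accessors
#' @export
setGeneric("networkGroup", function(x) standardGeneric("networkGroup"))

#' @rdname accessors
#' @export
setGeneric("networkMethod", function(x) standardGeneric("networkMethod"))

#' @rdname accessors
setMethod("roiNames", "RoiVolumeExperiment", function(x) rownames(x))

#' @rdname accessors
setMethod("roiNames", "GroupNetwork", function(x) x@roiNames)

#' @rdname accessors
setMethod("volumeMatrix", "RoiVolumeExperiment",
          function(x) t(assay(x, "volumes")))

#' @rdname accessors
setMethod("groupLabels", "RoiVolumeExperiment",
          function(x) as.character(colData(x)$group))

#' @rdname accessors
setMethod("tiv", "RoiVolumeExperiment", function(x) as.numeric(colData(x)$tiv))

#' @rdname accessors
setMethod("subjectIds", "RoiVolumeExperiment",
          function(x) as.character(colData(x)$subject_id))

#' @rdname accessors
setMethod("isNormalized", "RoiVolumeExperiment",
          function(x) isTRUE(metadata(x)$normalized))

#' @rdname accessors
setMethod("networkWeights", "GroupNetwork", function(x) {
    w <- x@weights
    dimnames(w) <- list(x@roiNames, x@roiNames)
    w
})

#' @rdname accessors
setMethod("networkGroup", "GroupNetwork", function(x) x@group)

#' @rdname accessors
setMethod("networkMethod", "GroupNetwork", function(x) x@method)

#' Covariate values stored with a cohort
#'
#' Returns the named per-subject covariate columns of the cohort's `colData`
#' (everything beyond `subject_id`, `group`, `tiv`) as a data.frame, or a
#' single covariate as a numeric vector.
#'
#' @param x a `RoiVolumeExperiment`.
#' @param name optional single covariate name.
#' @return data.frame of covariates, or numeric vector when `name` is given.
#' @export
covariates <- function(x, name = NULL) {
    stopifnot(is(x, "RoiVolumeExperiment"))
    cd <- as.data.frame(colData(x))
    extra <- setdiff(colnames(cd), c("subject_id", "group", "tiv"))
    if (is.null(name)) return(cd[, extra, drop = FALSE])
    if (!name %in% extra)
        stop(sprintf("covariate '%s' not present (have: %s)", name,
                     paste(extra, collapse = ", ")), call. = FALSE)
    as.numeric(cd[[name]])
}
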