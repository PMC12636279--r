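## Degree-preserving randomized surrogates of a weighted network, used both
## to normalize small-world indices and as the permutation null for nodal
## group comparisons.

# Deterministic sub-seed derivation: one root seed, per-draw substreams by
# counter, so ensembles are reproducible and order-independent.
subSeed <- function(seed, i) {
    m <- 2147483647
    s <- (as.numeric(seed) %% m + 104729 * as.numeric(i)) %% m
    as.integer(s) + 1L
}

# Raw-matrix rewiring kernel: swapMultiplier * |edges| attempted double-edge
# swaps under a local seed, weights carried with their edges.
rewireKernel <- function(w, swapMultiplier, seed) {
    m <- sum(w[upper.tri(w)] > 0)
    if (m < 2) return(w)
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(seed)
    .rewire_swaps(w, as.integer(swapMultiplier * m))
}

.Random.seed.save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.Random.seed.restore <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' Degree-preserving rewiring of a weighted network
#'
#' Performs `swapMultiplier * |edges|` attempted double-edge swaps on the
#' positive-weight edge set: a proposed swap of edges (a,b), (c,d) to (a,d),
#' (c,b) is accepted only if it creates no self-loop and no duplicate edge.
#' Edges carry their weights through swaps, so the binary degree sequence and
#' the edge-weight multiset of the surrogate both equal the original's
#' exactly; symmetry and the zero diagonal are preserved.  Deterministic
#' given `seed`.  Graphs admitting no valid swap (e.g. a triangle, or any
#' complete graph) are returned unchanged.
#'
#' @param network a [GroupNetwork-class] with at least 2 positive edges (a
#'   copy is returned below that).
#' @param swapMultiplier attempted swaps per edge (default 10, a standard
#'   mixing heuristic).
#' @param seed integer RNG seed.
#' @return a rewired `GroupNetwork` carrying the source's provenance.
#' @export
degreePreservingRewire <- function(network, swapMultiplier = 10L, seed = 1L) {
    stopifnot(is(network, "GroupNetwork"), swapMultiplier >= 1)
    ws <- rewireKernel(network@weights, swapMultiplier, seed)
    networkLike(network, ws,
                note = sprintf("degree-preserving rewire, seed=%d, swaps/edge=%d",
                               seed, as.integer(swapMultiplier)))
}

#' Ensemble of independent rewired surrogates
#'
#' Each surrogate is generated by [degreePreservingRewire()] under a distinct
#' deterministic substream of the root seed, so the ensemble is byte-
#' reproducible and its order does not depend on evaluation order.
#'
#' @inheritParams degreePreservingRewire
#' @param count ensemble size (>= 1).
#' @return list of `GroupNetwork` surrogates of length `count`.
#' @export
generateNullEnsemble <- function(network, count, swapMultiplier = 10L,
                                 seed = 1L) {
    stopifnot(is(network, "GroupNetwork"), count >= 1)
    lapply(seq_len(count), function(i)
        degreePreservingRewire(network, swapMultiplier, subSeed(seed, i)))
}
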