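## Weighted graph metrics on a structural covariance network.
##
## Conventions (recorded in network metadata):
##  - edge weight 0 means "no edge" (negative correlations were truncated);
##  - path metrics map weight w to distance 1/w (stronger covariance =
##    shorter path);
##  - betweenness is normalized by (n-1)(n-2)/2, so values lie in [0, 1];
##  - the Onnela clustering coefficient normalizes weights by the global
##    maximum edge weight of the graph.

# ---- internal kernels on raw matrices (hot paths avoid S4 dispatch) ----

strengthKernel <- function(w) rowSums(w)

clusteringKernel <- function(w) {
    deg <- rowSums(w > 0)
    mx <- max(w)
    if (mx == 0) return(rep(0, nrow(w)))
    m <- (w / mx)^(1 / 3)
    num <- diag(m %*% m %*% m)          # sum over ordered neighbor pairs
    denom <- deg * (deg - 1)
    out <- ifelse(deg >= 2, num / denom, 0)
    pmin(pmax(out, 0), 1)
}

asIgraph <- function(w) {
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    g
}

betweennessKernel <- function(w) {
    n <- nrow(w)
    if (n < 3) return(rep(0, n))
    g <- asIgraph(w)
    if (igraph::ecount(g) == 0) return(rep(0, n))
    b <- igraph::betweenness(g, directed = FALSE,
                             weights = 1 / igraph::E(g)$weight,
                             normalized = FALSE)
    out <- numeric(n)
    out[as.integer(igraph::V(g))] <- b
    out / ((n - 1) * (n - 2) / 2)
}

# Mean shortest 1/w path over reachable unordered pairs + disconnection flag.
pathLengthKernel <- function(w) {
    n <- nrow(w)
    g <- asIgraph(w)
    if (igraph::ecount(g) == 0) stop("empty graph: no reachable pair", call. = FALSE)
    d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    ut <- d[upper.tri(d)]
    reachable <- is.finite(ut)
    if (!any(reachable)) stop("empty graph: no reachable pair", call. = FALSE)
    list(L = mean(ut[reachable]), disconnected = !all(reachable))
}

# ---- exported metric surface ----

#' Nodal strength
#'
#' Sum of the weights of all edges incident to each node.
#'
#' @param network a [GroupNetwork-class].
#' @return named numeric vector, one value per ROI.
#' @export
nodalStrength <- function(network) {
    stopifnot(is(network, "GroupNetwork"))
    setNames(strengthKernel(network@weights), network@roiNames)
}

#' Normalized weighted betweenness centrality
#'
#' Fraction of all shortest paths between other node pairs that pass through
#' each node, on distances `1/weight` (zero weight = absent edge), counting
#' all shortest paths with multiplicity (Brandes accumulation), normalized by
#' `(n-1)(n-2)/2` so values lie in \[0, 1\].  Unreachable pairs contribute 0;
#' an isolated node scores 0.
#'
#' @inheritParams nodalStrength
#' @return named numeric vector in \[0, 1\].
#' @export
betweennessCentrality <- function(network) {
    stopifnot(is(network, "GroupNetwork"))
    if (length(network@roiNames) < 3)
        stop("betweenness needs at least 3 nodes", call. = FALSE)
    setNames(betweennessKernel(network@weights), network@roiNames)
}

#' Onnela weighted clustering coefficient
#'
#' Geometric-mean triangle intensity per node:
#' `c_u = (1 / (deg(u) (deg(u)-1))) * sum_{v,w} (what_uv what_uw what_vw)^(1/3)`
#' with `what = w / max(w)` (global maximum normalization), the sum over
#' ordered neighbor pairs (each triangle twice, cancelling the ordered-pair
#' denominator), and `deg(u)` the count of positive-weight incident edges.
#' Nodes with fewer than two neighbors score 0; an edgeless graph returns all
#' zeros.
#'
#' @inheritParams nodalStrength
#' @return named numeric vector in \[0, 1\].
#' @export
weightedClustering <- function(network) {
    stopifnot(is(network, "GroupNetwork"))
    setNames(clusteringKernel(network@weights), network@roiNames)
}

#' All three nodal metrics as a tidy table
#'
#' @inheritParams nodalStrength
#' @return data.frame with columns `roi`, `strength`, `betweenness`,
#'   `weighted_clustering`.
#' @export
nodalMetrics <- function(network) {
    stopifnot(is(network, "GroupNetwork"))
    data.frame(roi = network@roiNames,
               strength = strengthKernel(network@weights),
               betweenness = betweennessKernel(network@weights),
               weighted_clustering = clusteringKernel(network@weights),
               row.names = NULL, stringsAsFactors = FALSE)
}

# Internal dispatcher used by the permutation machinery.
metricKernel <- function(w, metric) {
    switch(metric,
           strength = strengthKernel(w),
           betweenness = betweennessKernel(w),
           weighted_clustering = clusteringKernel(w),
           stop(sprintf("unknown metric '%s'", metric), call. = FALSE))
}

#' Global clustering coefficient and characteristic path length
#'
#' `C` is the mean Onnela nodal clustering coefficient; `L` is the mean
#' shortest-path distance (`1/weight`) over all reachable unordered node
#' pairs.  When truncation disconnects the graph, unreachable pairs are
#' excluded from `L` and the disconnection is flagged.
#'
#' @inheritParams nodalStrength
#' @return list with elements `C`, `L`, `disconnected`.
#' @export
globalClusteringAndPathLength <- function(network) {
    stopifnot(is(network, "GroupNetwork"))
    if (length(network@roiNames) < 2)
        stop("need at least 2 nodes", call. = FALSE)
    pl <- pathLengthKernel(network@weights)
    list(C = mean(clusteringKernel(network@weights)), L = pl$L,
         disconnected = pl$disconnected)
}

#' Small-worldness against a degree-preserving null ensemble
#'
#' Computes `C` and `L` for the observed network, the ensemble means `Crand`
#' and `Lrand` over `nNull` degree-preserving rewired surrogates (weights
#' carried through double-edge swaps; see [degreePreservingRewire()]), and
#' the ratios `gamma = C/Crand`, `lambda = L/Lrand`,
#' `sigma = gamma/lambda`.  Networks with `sigma` clearly above 1 exhibit
#' small-world organization.  Deterministic given `seed`.
#'
#' @inheritParams nodalStrength
#' @param nNull ensemble size (study-scale default 10000; simulations in the
#'   package's own tests use a few hundred).
#' @param seed integer RNG seed.
#' @param swapMultiplier attempted swaps per edge for each surrogate.
#' @return a [GlobalMetricSummary-class].
#' @export
smallWorldness <- function(network, nNull = 10000L, seed = 1L,
                           swapMultiplier = 10L) {
    stopifnot(is(network, "GroupNetwork"), nNull >= 1)
    obs <- globalClusteringAndPathLength(network)
    cs <- numeric(nNull)
    ls <- numeric(nNull)
    for (i in seq_len(nNull)) {
        ws <- rewireKernel(network@weights, swapMultiplier, subSeed(seed, i))
        cs[i] <- mean(clusteringKernel(ws))
        ls[i] <- pathLengthKernel(ws)$L
    }
    Crand <- mean(cs)
    Lrand <- mean(ls)
    if (Crand == 0 || Lrand == 0)
        stop("degenerate null ensemble (Crand or Lrand is zero)", call. = FALSE)
    gamma <- obs$C / Crand
    lambda <- obs$L / Lrand
    new(Class = "GlobalMetricSummary", C = obs$C, L = obs$L, Crand = Crand,
        Lrand = Lrand, gamma = gamma, lambda = lambda,
        sigma = gamma / lambda, nNull = as.integer(nNull),
        seed = as.integer(seed), disconnected = obs$disconnected)
}

#' Write nodal / global metric tables as tidy CSV
#'
#' `writeNodalMetrics()` writes one row per (group, roi, metric, value);
#' `writeGlobalMetrics()` one row per group with the small-world summary.
#'
#' @param network a `GroupNetwork` (nodal) .
#' @param summary a `GlobalMetricSummary` (global).
#' @param group group label for the global row.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeNodalMetrics <- function(network, path) {
    nm <- nodalMetrics(network)
    long <- data.frame(group = network@group,
                       roi = rep(nm$roi, 3),
                       metric = rep(c("strength", "betweenness",
                                      "weighted_clustering"), each = nrow(nm)),
                       value = fmt17(c(nm$strength, nm$betweenness,
                                       nm$weighted_clustering)),
                       stringsAsFactors = FALSE)
    write.table(long, path, sep = ",", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeNodalMetrics
#' @export
writeGlobalMetrics <- function(summary, group, path) {
    stopifnot(is(summary, "GlobalMetricSummary"))
    df <- data.frame(group = group, C = fmt17(summary@C), L = fmt17(summary@L),
                     Crand = fmt17(summary@Crand), Lrand = fmt17(summary@Lrand),
                     gamma = fmt17(summary@gamma), lambda = fmt17(summary@lambda),
                     sigma = fmt17(summary@sigma), n_null = summary@nNull,
                     seed = summary@seed, disconnected = summary@disconnected,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
    invisible(path)
}
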