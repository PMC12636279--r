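# Independent brute-force oracles used to validate the graph-metric,
# null-model and inference implementations.  These deliberately share no
# code with the package internals: plain loops, exhaustive enumeration.

# per-row loop summation
oracleStrength <- function(w) {
    n <- nrow(w)
    out <- numeric(n)
    for (i in seq_len(n)) for (j in seq_len(n)) out[i] <- out[i] + w[i, j]
    out
}

# direct evaluation of the geometric-mean triangle formula: for each node u,
# sum over ordered pairs (v, w) of distinct other nodes of
# (what_uv * what_uw * what_vw)^(1/3), divided by deg(u)(deg(u)-1),
# with what = w / max(w) and deg = count of positive incident weights.
oracleClustering <- function(w) {
    n <- nrow(w)
    mx <- max(w)
    if (mx == 0) return(numeric(n))
    wh <- w / mx
    out <- numeric(n)
    for (u in seq_len(n)) {
        deg <- sum(w[u, ] > 0)
        if (deg < 2) next
        acc <- 0
        for (v in seq_len(n)) for (x in seq_len(n)) {
            if (v == u || x == u || v == x) next
            acc <- acc + (wh[u, v] * wh[u, x] * wh[v, x])^(1 / 3)
        }
        out[u] <- acc / (deg * (deg - 1))
    }
    out
}

# Exhaustive simple-path enumeration per node pair on distances 1/w:
# returns the shortest distance and the list of minimal paths (node index
# vectors).  Branch-and-bound pruning on the partial distance is exact for
# positive weights.
enumerateShortest <- function(w, s, t, tol = 1e-12) {
    n <- nrow(w)
    best <- Inf
    paths <- list()
    visit <- function(node, dist, path) {
        if (dist > best + tol) return()
        if (node == t) {
            if (dist < best - tol) {
                best <<- dist
                paths <<- list(path)
            } else if (abs(dist - best) <= tol) {
                paths[[length(paths) + 1L]] <<- path
            }
            return()
        }
        for (nb in seq_len(n)) {
            if (w[node, nb] > 0 && !(nb %in% path)) {
                visit(nb, dist + 1 / w[node, nb], c(path, nb))
            }
        }
    }
    visit(s, 0, s)
    list(dist = best, paths = paths)
}

oracleBetweenness <- function(w, tol = 1e-12) {
    n <- nrow(w)
    acc <- numeric(n)
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        sh <- enumerateShortest(w, s, t, tol)
        if (!is.finite(sh$dist)) next
        np <- length(sh$paths)
        for (p in sh$paths) {
            interior <- p[-c(1, length(p))]
            for (v in interior) acc[v] <- acc[v] + 1 / np
        }
    }
    acc / ((n - 1) * (n - 2) / 2)
}

oraclePathLength <- function(w, tol = 1e-12) {
    n <- nrow(w)
    ds <- c()
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        sh <- enumerateShortest(w, s, t, tol)
        if (is.finite(sh$dist)) ds <- c(ds, sh$dist)
    }
    mean(ds)
}

# explicit step-up search: adjusted_(i) = min over j >= i of min(1, m p_(j)/j)
oracleBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    sorted <- p[ord]
    adjSorted <- numeric(m)
    for (i in seq_len(m)) {
        best <- 1
        for (j in i:m) best <- min(best, m * sorted[j] / j)
        adjSorted[i] <- best
    }
    adj <- numeric(m)
    adj[ord] <- adjSorted
    adj
}

# pairwise Pearson from the closed-form definition
oraclePearson <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random symmetric truncated weight matrix fixture
randomWeightMatrix <- function(n, p = 0.4, seed = 1) {
    set.seed(seed)
    w <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (runif(1) < p) {
            v <- runif(1, 0.2, 1)
            w[i, j] <- v
            w[j, i] <- v
        }
    }
    w
}

testNet <- function(w, group = "test") groupNetworkFromMatrix(w, group = group)

# ring lattice with k nearest neighbours each side plus random shortcuts
ringLattice <- function(n, halfK = 2, shortcuts = 0, seed = 1) {
    w <- matrix(0, n, n)
    for (i in seq_len(n)) for (d in seq_len(halfK)) {
        j <- ((i - 1 + d) %% n) + 1
        w[i, j] <- 1
        w[j, i] <- 1
    }
    if (shortcuts > 0) {
        set.seed(seed)
        added <- 0
        while (added < shortcuts) {
            ij <- sample.int(n, 2)
            if (w[ij[1], ij[2]] == 0) {
                w[ij[1], ij[2]] <- 1
                w[ij[2], ij[1]] <- 1
                added <- added + 1
            }
        }
    }
    w
}

completeGraph <- function(n) {
    w <- matrix(1, n, n)
    diag(w) <- 0
    w
}

# small well-formed cohort CSV fixture written to a temp file
writeCohortFixture <- function(path, nSubj = 3, nRoi = 4, dup = FALSE,
                               negCell = FALSE) {
    ids <- paste0("s", seq_len(nSubj))
    if (dup) ids[2] <- ids[1]
    set.seed(11)
    vols <- matrix(round(runif(nSubj * nRoi, 0.3, 1.2), 4), nSubj, nRoi)
    if (negCell) vols[2, 2] <- -2.0
    df <- data.frame(subject_id = ids,
                     group = rep(c("A", "B"), length.out = nSubj),
                     tiv = seq(1400, 1400 + 10 * (nSubj - 1), by = 10),
                     `cov:ICV` = seq(1400, 1400 + 10 * (nSubj - 1), by = 10),
                     check.names = FALSE)
    for (k in seq_len(nRoi)) df[[paste0("ROI", k)]] <- vols[, k]
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
}
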