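test_that("nodal strength sums incident weights", {
    w <- matrix(0, 3, 3)
    w[1, 2] <- w[2, 1] <- 0.2
    w[1, 3] <- w[3, 1] <- 0.3
    w[2, 3] <- w[3, 2] <- 0.5
    s <- nodalStrength(testNet(w))
    expect_equal(unname(s[1]), 0.5)

    expect_equal(unname(nodalStrength(testNet(matrix(0, 4, 4)))), rep(0, 4))

    w28 <- randomWeightMatrix(28, p = 0.4, seed = 99)
    expect_equal(unname(nodalStrength(testNet(w28))), oracleStrength(w28),
                 tolerance = 1e-12)
})

test_that("betweenness on canonical topologies and against path enumeration", {
    # 3-node path a-b-c: b intermediates the single pair
    w <- matrix(0, 3, 3)
    w[1, 2] <- w[2, 1] <- 1
    w[2, 3] <- w[3, 2] <- 1
    expect_equal(unname(betweennessCentrality(testNet(w))), c(0, 1, 0))

    # 5-node star: center on every leaf pair
    ws <- matrix(0, 5, 5)
    ws[1, 2:5] <- ws[2:5, 1] <- 1
    expect_equal(unname(betweennessCentrality(testNet(ws))), c(1, 0, 0, 0, 0))

    # weighted 6-node graph vs exhaustive enumeration
    w6 <- randomWeightMatrix(6, p = 0.6, seed = 7)
    expect_equal(unname(betweennessCentrality(testNet(w6))),
                 oracleBetweenness(w6), tolerance = 1e-10)
})

test_that("weighted clustering follows the geometric-mean triangle formula", {
    # single incident edge: denominator convention gives 0
    w <- matrix(0, 3, 3)
    w[1, 2] <- w[2, 1] <- 0.7
    expect_equal(unname(weightedClustering(testNet(w))), c(0, 0, 0))

    # equal-weight triangle: all normalized weights 1, so c = 1 everywhere
    wt <- matrix(0.4, 3, 3)
    diag(wt) <- 0
    expect_equal(unname(weightedClustering(testNet(wt))), rep(1, 3))

    # seeded 8-node graph vs triangle enumeration
    w8 <- randomWeightMatrix(8, p = 0.55, seed = 12)
    expect_equal(unname(weightedClustering(testNet(w8))),
                 oracleClustering(w8), tolerance = 1e-12)
})

test_that("ordered-pair summation equals unordered pairs with halved denominator", {
    w <- randomWeightMatrix(9, p = 0.5, seed = 31)
    mx <- max(w)
    wh <- w / mx
    n <- nrow(w)
    unordered <- numeric(n)
    for (u in seq_len(n)) {
        deg <- sum(w[u, ] > 0)
        if (deg < 2) next
        acc <- 0
        for (v in seq_len(n - 1)) for (x in (v + 1):n) {
            if (v == u || x == u) next
            acc <- acc + (wh[u, v] * wh[u, x] * wh[v, x])^(1 / 3)
        }
        unordered[u] <- acc / (deg * (deg - 1) / 2)
    }
    expect_equal(unname(weightedClustering(testNet(w))), unordered,
                 tolerance = 1e-12)
})

test_that("global C and L match hand and oracle computations", {
    k5 <- completeGraph(5)
    g <- globalClusteringAndPathLength(testNet(k5))
    expect_equal(g$C, 1)
    expect_equal(g$L, 1)
    expect_false(g$disconnected)

    # 3-node unit path: pairs at distance 1, 1, 2
    w <- matrix(0, 3, 3)
    w[1, 2] <- w[2, 1] <- 1
    w[2, 3] <- w[3, 2] <- 1
    expect_equal(globalClusteringAndPathLength(testNet(w))$L, 4 / 3)

    w10 <- randomWeightMatrix(10, p = 0.4, seed = 8)
    g10 <- globalClusteringAndPathLength(testNet(w10))
    expect_equal(g10$L, oraclePathLength(w10), tolerance = 1e-10)
    expect_equal(g10$C, mean(oracleClustering(w10)), tolerance = 1e-12)

    expect_error(globalClusteringAndPathLength(testNet(matrix(0, 4, 4))),
                 "empty graph")
})

test_that("disconnected graphs are flagged and isolated nodes score zero", {
    w <- matrix(0, 5, 5)
    w[1, 2] <- w[2, 1] <- 1
    w[3, 4] <- w[4, 3] <- 1          # node 5 isolated, two components
    g <- globalClusteringAndPathLength(testNet(w))
    expect_true(g$disconnected)
    expect_equal(g$L, 1)             # only reachable pairs counted
    expect_equal(unname(betweennessCentrality(testNet(w))), rep(0, 5))
})

test_that("metrics are equivariant under node relabeling and weight scaling", {
    w <- randomWeightMatrix(10, p = 0.5, seed = 17)
    net <- testNet(w)
    set.seed(3)
    perm <- sample(10)
    wp <- w[perm, perm]
    netp <- testNet(wp)
    expect_equal(unname(nodalStrength(netp)), unname(nodalStrength(net))[perm],
                 tolerance = 1e-12)
    expect_equal(unname(weightedClustering(netp)),
                 unname(weightedClustering(net))[perm], tolerance = 1e-12)
    expect_equal(unname(betweennessCentrality(netp)),
                 unname(betweennessCentrality(net))[perm], tolerance = 1e-10)

    # scaling by k > 0: strength scales, clustering/betweenness invariant
    k <- 0.37
    netk <- testNet(w * k)
    expect_equal(unname(nodalStrength(netk)), k * unname(nodalStrength(net)),
                 tolerance = 1e-12)
    expect_equal(unname(weightedClustering(netk)),
                 unname(weightedClustering(net)), tolerance = 1e-12)
    expect_equal(unname(betweennessCentrality(netk)),
                 unname(betweennessCentrality(net)), tolerance = 1e-10)
})

test_that("complete-graph small-worldness is the rewiring fixed point", {
    sw <- smallWorldness(testNet(completeGraph(8)), nNull = 25, seed = 4)
    expect_equal(sw@gamma, 1)
    expect_equal(sw@lambda, 1)
    expect_equal(sw@sigma, 1)
    expect_equal(sw@sigma, sw@gamma / sw@lambda, tolerance = 1e-12)
})

test_that("small-worldness is deterministic given the seed", {
    w <- randomWeightMatrix(12, p = 0.4, seed = 23)
    a <- smallWorldness(testNet(w), nNull = 30, seed = 11)
    b <- smallWorldness(testNet(w), nNull = 30, seed = 11)
    expect_identical(a@sigma, b@sigma)
    expect_identical(a@Crand, b@Crand)
})
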