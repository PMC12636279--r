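makeGroupTable <- function(vols, group = "A", tivs = NULL, covs = NULL) {
    n <- nrow(vols)
    if (is.null(tivs)) tivs <- rep(1500, n)
    tab <- RoiVolumeExperiment(vols, paste0("s", seq_len(n)), group, tivs,
                               covariates = covs)
    normalizeToTivFraction(tab)
}

test_that("perfect proportionality yields weight 1 and negatives truncate to 0", {
    set.seed(7)
    x <- runif(6, 0.3, 0.9)
    vols <- cbind(R1 = x, R2 = 2 * x, R3 = 1 - 0.5 * x)  # R3 anti-correlated
    net <- buildCovarianceNetwork(makeGroupTable(vols))
    w <- networkWeights(net)
    expect_equal(w["R1", "R2"], 1, tolerance = 1e-12)
    expect_equal(w["R1", "R3"], 0)       # r = -1 truncated
    expect_equal(diag(w), setNames(rep(0, 3), colnames(vols)))
})

test_that("pearson matrix matches the closed-form pairwise oracle", {
    set.seed(42)
    vols <- matrix(runif(8 * 5, 0.2, 1.2), 8, 5,
                   dimnames = list(NULL, paste0("R", 1:5)))
    tab <- makeGroupTable(vols, tivs = runif(8, 1300, 1700))
    net <- buildCovarianceNetwork(tab, method = "pearson")
    w <- networkWeights(net)
    fr <- volumeMatrix(tab)
    for (i in 1:4) for (j in (i + 1):5) {
        r <- oraclePearson(fr[, i], fr[, j])
        expect_equal(unname(w[i, j]), max(0, r), tolerance = 1e-10)
    }
})

test_that("partial pearson equals correlation of least-squares residuals", {
    set.seed(43)
    n <- 9
    icv <- runif(n, 1300, 1700)
    vols <- matrix(runif(n * 4, 0.2, 1.2), n, 4,
                   dimnames = list(NULL, paste0("R", 1:4)))
    tab <- makeGroupTable(vols, tivs = icv, covs = data.frame(ICV = icv))
    net <- buildCovarianceNetwork(tab, method = "partial_pearson",
                                  covariateNames = "ICV")
    expect_identical(networkMethod(net), "partial_pearson")
    w <- networkWeights(net)
    fr <- volumeMatrix(tab)
    res <- apply(fr, 2, function(y) residuals(lm(y ~ icv)))
    for (i in 1:3) for (j in (i + 1):4) {
        r <- oraclePearson(res[, i], res[, j])
        expect_equal(unname(w[i, j]), max(0, r), tolerance = 1e-10)
    }
})

test_that("network is invariant to subject order, global rescaling, and ROI affine maps", {
    set.seed(44)
    vols <- matrix(runif(10 * 4, 0.2, 1.2), 10, 4,
                   dimnames = list(NULL, paste0("R", 1:4)))
    tab <- makeGroupTable(vols)
    w0 <- networkWeights(buildCovarianceNetwork(tab))

    perm <- sample(10)
    tabP <- makeGroupTable(vols[perm, ])
    expect_equal(networkWeights(buildCovarianceNetwork(tabP)), w0,
                 tolerance = 1e-12)

    tabS <- makeGroupTable(vols * 3)
    expect_equal(networkWeights(buildCovarianceNetwork(tabS)), w0,
                 tolerance = 1e-12)

    # positive-slope affine transform per ROI leaves Pearson unchanged
    volsA <- sweep(sweep(vols, 2, c(2, 0.5, 3, 1.5), "*"), 2,
                   c(0.01, 0.02, 0.0, 0.03), "+")
    colnames(volsA) <- colnames(vols)
    expect_equal(networkWeights(buildCovarianceNetwork(makeGroupTable(volsA))),
                 w0, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected with informative errors", {
    vols <- matrix(c(rep(0.5, 6), runif(6, 0.2, 1)), 6, 2,
                   dimnames = list(NULL, c("Rconst", "R2")))
    tab <- makeGroupTable(vols)
    expect_error(buildCovarianceNetwork(tab), "Rconst")

    set.seed(9)
    small <- matrix(runif(3 * 4, 0.2, 1), 3, 4,
                    dimnames = list(NULL, paste0("R", 1:4)))
    expect_error(buildCovarianceNetwork(makeGroupTable(small)), "insufficient")

    # zero-variance covariate
    set.seed(10)
    vols <- matrix(runif(8 * 3, 0.2, 1), 8, 3,
                   dimnames = list(NULL, paste0("R", 1:3)))
    tab <- makeGroupTable(vols, covs = data.frame(ICV = rep(1500, 8)))
    expect_error(buildCovarianceNetwork(tab, "partial_pearson", "ICV"),
                 "zero-variance covariate")

    # unnormalized table refused
    raw <- RoiVolumeExperiment(vols, paste0("s", 1:8), "A", rep(1500, 8))
    expect_error(buildCovarianceNetwork(raw), "normalized")
})

test_that("adjacency CSV + JSON sidecar round-trips bit-exactly", {
    set.seed(45)
    vols <- matrix(runif(12 * 5, 0.2, 1.2), 12, 5,
                   dimnames = list(NULL, paste0("R", 1:5)))
    net <- buildCovarianceNetwork(makeGroupTable(vols))
    f <- withr::local_tempfile(fileext = ".csv")
    writeAdjacency(net, f)
    back <- readAdjacency(f)
    expect_identical(back@weights, net@weights)
    expect_identical(back@roiNames, net@roiNames)
    expect_identical(back@method, net@method)
    expect_identical(back@nSubjects, net@nSubjects)
})
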