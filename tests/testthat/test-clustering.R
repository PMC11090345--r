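test_that("RBF kernel entries match the closed form", {
    set.seed(2)
    X <- matrix(rnorm(8), 4, 2)
    km <- rbfKernel(X, bandwidth = 1.5)
    D <- as.matrix(dist(X))
    expect_equal(kernelValues(km), exp(-D^2 / (2 * 1.5^2)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unname(diag(kernelValues(km))), rep(1, 4))

    # two points at distance sigma * sqrt(2) have kernel value e^-1
    Y <- rbind(c(0, 0), c(sqrt(2) * 1.5, 0))
    expect_equal(rbfKernel(Y, 1.5)@values[1, 2], exp(-1), tolerance = 1e-12)

    expect_error(rbfKernel(matrix(1, 3, 2), "median"), "identical")
})

test_that("kernel K-means recovers separable blobs and is deterministic", {
    b <- blobData(nPer = 20, sep = 10, seed = 4)
    a1 <- kernelKMeans(rbfKernel(b$X), K = 2, seed = 99)
    expect_true(sameBipartition(clusterLabels(a1), b$truth))
    expect_true(a1@converged)
    a2 <- kernelKMeans(rbfKernel(b$X), K = 2, seed = 99)
    expect_identical(clusterLabels(a1), clusterLabels(a2))
    expect_identical(objectiveValue(a1), objectiveValue(a2))
})

test_that("kernel K-means objective is nonincreasing across iterations", {
    set.seed(8)
    X <- matrix(rnorm(60 * 3), 60, 3)
    M <- rbfKernel(X)
    init <- rep(1:2, 30)
    objs <- vapply(1:6, function(it)
        objectiveValue(kernelKMeans(M, K = 2, seed = 1, initial = init,
                                    maxIter = it)), numeric(1))
    expect_true(all(diff(objs) <= 1e-10))
})

test_that("kernel K-means rejects invalid kernels and K", {
    b <- blobData(nPer = 5, seed = 1)
    M <- rbfKernel(b$X)
    expect_error(kernelKMeans(M, K = 11, seed = 1), "exceed")
    bad <- kernelValues(M)
    bad[1, 2] <- bad[2, 1] <- 5 # breaks PSD
    expect_error(kernelKMeans(bad, K = 2, seed = 1), "positive semidefinite")
})

test_that("every point its own cluster gives zero objective", {
    set.seed(10)
    X <- matrix(rnorm(12), 6, 2)
    a <- kernelKMeans(rbfKernel(X), K = 6, seed = 3, restarts = 1)
    expect_equal(objectiveValue(a), 0, tolerance = 1e-9)
    expect_equal(sort(clusterLabels(a)), 1:6)
})

test_that("kernel K-means with a linear kernel is Lloyd's K-means", {
    # algebraic identity: with M = XX' the kernel-space distance to a
    # cluster mean equals the squared Euclidean distance to the centroid,
    # so from a shared initial partition both algorithms coincide
    set.seed(12)
    for (i in 1:8) {
        n <- 40
        X <- matrix(rnorm(n * 3), n, 3) +
            rep(c(0, 1.5), each = n / 2)
        init <- sample(rep(1:2, n / 2))
        kk <- kernelKMeans(linearKernel(X), K = 2, seed = 1, initial = init)
        ll <- lloydKMeans(X, K = 2, seed = 1, initial = init)
        expect_equal(objectiveValue(kk), objectiveValue(ll),
                     tolerance = 1e-8)
        expect_true(sameBipartition(clusterLabels(kk), clusterLabels(ll)))
    }
})

test_that("Lloyd baseline clusters 1-D anchor points correctly", {
    X <- matrix(c(0, 1, 10, 11), 4, 1)
    a <- lloydKMeans(X, K = 2, seed = 5)
    expect_true(sameBipartition(clusterLabels(a), c(1, 1, 2, 2)))
    b <- blobData(nPer = 15, sep = 8, seed = 3)
    expect_true(sameBipartition(
        clusterLabels(lloydKMeans(b$X, K = 2, seed = 5)), b$truth))
})

test_that("fuzzy c-means memberships behave on separable and symmetric data", {
    b <- blobData(nPer = 15, sep = 12, sd = 0.5, seed = 6)
    a <- fuzzyCMeans(b$X, K = 2, seed = 21)
    expect_true(sameBipartition(clusterLabels(a), b$truth))
    own <- membershipMatrix(a)[cbind(seq_len(30), clusterLabels(a))]
    expect_true(all(own > 0.99))

    # a point equidistant between two symmetric groups splits 0.5/0.5
    X <- matrix(c(-2, -2.1, -1.9, 2, 2.1, 1.9, 0), ncol = 1)
    a2 <- fuzzyCMeans(X, K = 2, seed = 3, epsilon = 1e-10)
    expect_equal(unname(membershipMatrix(a2)[7, ]), c(0.5, 0.5),
                 tolerance = 1e-6)
})

test_that("fuzzy c-means follows the Bezdek update equations exactly", {
    # hand-rolled trace of 3 iterations, written independently of the
    # implementation, from the same seeded initial memberships
    set.seed(31)
    X <- matrix(c(0, 0.2, 0.4, 5, 5.2, 5.4), ncol = 1)
    n <- 6; K <- 2; f <- 2
    U <- local({
        set.seed(17)
        u <- matrix(runif(n * K), n, K)
        u / rowSums(u)
    })
    for (it in 1:3) {
        Um <- U^f
        ctr <- colSums(Um * as.vector(X)) / colSums(Um)
        d2 <- outer(as.vector(X), ctr, function(a, b) (a - b)^2)
        U <- 1 / (d2 * rowSums(1 / d2)) # u_ik = 1 / sum_j (d_ik/d_ij)^2
    }
    a <- fuzzyCMeans(X, K = 2, fuzzifier = 2, seed = 17, maxIter = 3,
                     epsilon = 0)
    expect_false(a@converged)
    expect_equal(membershipMatrix(a), U, tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("fuzzy c-means agrees with the e1071 reference at convergence", {
    b <- blobData(nPer = 10, sep = 9, sd = 0.7, seed = 13)
    mine <- fuzzyCMeans(b$X, K = 2, seed = 41, epsilon = 1e-10)
    ref <- e1071::cmeans(b$X, centers = 2, m = 2, iter.max = 500)
    expect_true(sameBipartition(clusterLabels(mine), ref$cluster))
    # align columns before comparing soft memberships
    Um <- membershipMatrix(mine)
    Ur <- ref$membership
    if (mean(abs(Um - Ur)) > mean(abs(Um - Ur[, 2:1]))) Ur <- Ur[, 2:1]
    expect_equal(Um, Ur, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("assignments serialize with memberships when available", {
    b <- blobData(nPer = 5, sep = 9, seed = 2)
    a <- fuzzyCMeans(b$X, K = 2, seed = 1)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeAssignment(a, sprintf("s%02d", 1:10), path)
    back <- read.delim(path)
    expect_equal(back$cluster, clusterLabels(a))
    expect_true("membership_1" %in% names(back))
})
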