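test_that("grid mutual information matches the entropy decomposition", {
    expect_equal(gridMutualInformation(matrix(c(5, 0, 0, 5), 2)), 1)
    expect_equal(gridMutualInformation(matrix(3, 2, 2)), 0)

    # hand evaluation of I = Hx + Hy - Hxy on the 10-point [[4,1],[1,4]] grid
    cnt <- matrix(c(4, 1, 1, 4), 2)
    expected <- entropyOf(rowSums(cnt)) + entropyOf(colSums(cnt)) -
        entropyOf(cnt)
    expect_equal(gridMutualInformation(cnt), expected, tolerance = 1e-12)

    expect_error(gridMutualInformation(matrix(c(-1, 2, 2, 2), 2)),
                 "nonnegative")

    # identity and bounds hold on random tables
    set.seed(1)
    for (i in 1:20) {
        tab <- matrix(rpois(12, 4), 3, 4)
        if (sum(tab) == 0) next
        I <- gridMutualInformation(tab)
        hx <- entropyOf(rowSums(tab))
        hy <- entropyOf(colSums(tab))
        expect_equal(I, hx + hy - entropyOf(tab), tolerance = 1e-12)
        expect_lte(I, min(hx, hy) + 1e-12)
    }
})

test_that("the grid budget B(n) = n^0.6 bounds admissible shapes", {
    expect_identical(admissibleGridShapes(14),
                     matrix(c(2L, 2L), 1, dimnames = list(NULL, c("nx", "ny"))))
    sh20 <- admissibleGridShapes(20)
    expect_setequal(paste(sh20[, 1], sh20[, 2]), c("2 2", "2 3", "3 2"))
    # strict inequality, un-floored, for every shape at any n
    for (n in c(11, 25, 63, 126)) {
        sh <- admissibleGridShapes(n)
        expect_true(all(sh[, 1] * sh[, 2] < n^0.6))
        expect_true(all(sh >= 2))
    }
})

test_that("maxGridMI maximizes over legal cut placements", {
    x <- as.numeric(1:20)
    expect_equal(maxGridMI(x, x, 2, 2), 1) # any median split is diagonal

    # independent pair: equals the brute-force maximum over all single-cut
    # placements on both axes
    x12 <- as.numeric(1:12)
    set.seed(5)
    y12 <- sample(x12)
    brute <- 0
    for (i in 1:11) {
        for (j in 1:11) {
            tab <- table(x12 > i + 0.5, y12 > j + 0.5)
            brute <- max(brute, gridMutualInformation(tab))
        }
    }
    expect_equal(maxGridMI(x12, y12, 2, 2, exhaustive = "always"), brute,
                 tolerance = 1e-12)

    expect_equal(maxGridMI(rep(1, 15), rnorm(15), 2, 2), 0)
})

test_that("micScore honors the B(n) precondition and basic limits", {
    x <- as.numeric(1:63)
    expect_equal(micScore(x, x), 1, tolerance = 1e-12)
    expect_equal(micScore(x, rep(2, 63)), 0)
    expect_error(micScore(1:10, 1:10), "B\\(n\\)")
    expect_error(micScore(c(1:62, NA), 1:63), "non-finite")
})

test_that("MIC is symmetric, bounded and rank-invariant", {
    set.seed(11)
    for (i in 1:15) {
        x <- rnorm(40)
        y <- 0.3 * x + rnorm(40)
        s <- micScore(x, y)
        expect_gte(s, 0)
        expect_lte(s, 1)
        expect_identical(s, micScore(y, x))
        # strictly increasing transforms change nothing: partitions are
        # rank-based
        expect_identical(micScore(exp(x), y^3 + 2 * y), micScore(x, y))
    }
})

test_that("the heuristic search never beats the exhaustive oracle", {
    set.seed(21)
    for (i in 1:10) {
        n <- sample(11:20, 1)
        x <- rnorm(n)
        y <- rnorm(n) + 0.5 * x
        oracle <- micOracle(x, y)
        expect_lte(micScore(x, y, exhaustive = "never"), oracle + 1e-12)
        expect_equal(micScore(x, y, exhaustive = "always"), oracle,
                     tolerance = 1e-12)
    }
    expect_error(micOracle(rnorm(21), rnorm(21)), "n > 20")
})

test_that("micProfile scores each locus and ignores patient order", {
    set.seed(31)
    m <- 3
    n <- 14
    blood <- matrix(rnorm(n * m, 2, 0.3), n, m)
    cancer <- blood + matrix(rnorm(n * m, 0, 0.2), n, m)
    cancer[, 1] <- blood[, 1] # exact equality at locus 1
    co <- pairedCohort(cancer, blood)
    prof <- micProfile(co, exhaustive = "always")
    expect_equal(micScores(prof)[1], 1, tolerance = 1e-12)
    for (j in 1:m)
        expect_equal(micScores(prof)[j], micOracle(blood[, j], cancer[, j]),
                     tolerance = 1e-12)

    perm <- sample(n)
    co2 <- pairedCohort(cancer[perm, ], blood[perm, ])
    expect_identical(micScores(micProfile(co2, exhaustive = "always")),
                     micScores(prof))
})

test_that("MIC profiles serialize to a two-column TSV", {
    prof <- new("MICProfile", chromosome = "7",
                scores = c(0.2, 0.9, 0.5), n = 63L)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeMICProfile(prof, path)
    back <- read.delim(path)
    expect_equal(back$mic, c(0.2, 0.9, 0.5))
    expect_equal(back$locus_index, 1:3)
})
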