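test_that("true rate takes the better of the two cluster-label mappings", {
    labels <- rep(c("cancer", "blood"), 63)
    perfect <- ifelse(labels == "cancer", 1L, 2L)
    expect_equal(trueRate(perfect, labels), 1)
    expect_equal(trueRate(3L - perfect, labels), 1) # label swap is free

    # 126 samples, clusters of size 70/56 with 40 cancer in cluster 1:
    # expected value from enumerating both mappings
    z <- c(rep(1L, 70), rep(2L, 56))
    lab <- c(rep("cancer", 40), rep("blood", 30),
             rep("cancer", 23), rep("blood", 33))
    acc1 <- (40 + 33) / 126 # cluster1 -> cancer, cluster2 -> blood
    acc2 <- (30 + 23) / 126
    expect_equal(trueRate(z, lab), max(acc1, acc2))

    expect_error(trueRate(c(1L, 2L, 3L, 1L), rep(c("a", "b"), 2)),
                 "two-cluster")
    expect_error(trueRate(c(1L, 2L), c("a", "a")), "two classes")
})

test_that("any balanced two-way assignment scores at least one half", {
    labels <- rep(c("cancer", "blood"), 63)
    set.seed(14)
    for (i in 1:50) {
        z <- sample(1:2, 126, replace = TRUE)
        if (length(unique(z)) < 2) next
        expect_gte(trueRate(z, labels), 0.5)
    }
})

test_that("NMI matches direct entropy arithmetic and its conventions", {
    lab <- rep(c("x", "y"), each = 35)
    expect_equal(nmiScore(rep(1:2, each = 35), lab), 1)
    expect_equal(nmiScore(rep(1L, 70), lab), 0) # zero-entropy convention

    # contingency [[30,10],[5,25]] evaluated by hand
    z <- c(rep(1L, 40), rep(2L, 30))
    lab2 <- c(rep("a", 30), rep("b", 10), rep("a", 5), rep("b", 25))
    tab <- matrix(c(30, 5, 10, 25), 2)
    hz <- entropyOf(rowSums(tab)); hl <- entropyOf(colSums(tab))
    I <- hz + hl - entropyOf(tab)
    expect_equal(nmiScore(z, lab2), I / sqrt(hz * hl), tolerance = 1e-12)
    expect_equal(nmiScore(z, lab2, "min"), I / min(hz, hl))
    expect_equal(nmiScore(z, lab2, "max"), I / max(hz, hl))
    expect_equal(nmiScore(z, lab2, "arithmetic"), I / ((hz + hl) / 2))

    # symmetric and invariant under relabeling either partition
    expect_equal(nmiScore(z, lab2),
                 nmiScore(ifelse(lab2 == "a", 1L, 2L),
                          ifelse(z == 1L, "u", "v")))
    expect_equal(nmiScore(3L - z, lab2), nmiScore(z, lab2))
})

test_that("PD and APD reproduce the published worked comparisons", {
    # chromosome 19: EFS 0.524 vs RFS 0.675
    expect_equal(performanceDifference(0.524, 0.675), 15.1,
                 tolerance = 1e-10)
    expect_equal(round(adjustedPerformanceDifference(0.524, 0.675)), 29)
    # chromosome 18: 0.571 vs 0.651
    expect_equal(performanceDifference(0.571, 0.651), 8, tolerance = 1e-10)
    expect_equal(round(adjustedPerformanceDifference(0.571, 0.651)), 14)
    # chromosome 12
    expect_equal(round(adjustedPerformanceDifference(0.540, 0.595)), 10)

    expect_equal(performanceDifference(0.6, 0.6), 0)
    expect_error(adjustedPerformanceDifference(0, 0.5), "undefined")
})

test_that("PD/APD are antisymmetric and mutually consistent", {
    set.seed(15)
    for (i in 1:25) {
        a <- runif(1, 0.1, 1); b <- runif(1, 0.1, 1)
        expect_equal(performanceDifference(a, b),
                     -performanceDifference(b, a))
        expect_equal(adjustedPerformanceDifference(a, b) * a,
                     performanceDifference(a, b), tolerance = 1e-12)
        same <- sign(performanceDifference(a, b)) ==
            sign(adjustedPerformanceDifference(a, b))
        expect_true(same || performanceDifference(a, b) == 0)
    }
})

test_that("proportional feature-set size reproduces the published extremes", {
    expect_equal(round(proportionalSize(5, 8149), 2), 0.06)
    expect_equal(round(proportionalSize(392, 22215), 2), 1.76)
    expect_equal(proportionalSize(100, 100), 100)
    expect_equal(proportionalSize(0, 50), 0)
    expect_error(proportionalSize(9, 8), "v <= m")
})

test_that("report builder pivots records and renders zero blocks", {
    recs <- rbind(
        evaluationRecord("1", "EFS", 100L, nmi = 0.02, tr = 0.57),
        evaluationRecord("1", "MIC>0.65", 4L, nmi = 0.01, tr = 0.51),
        evaluationRecord("1", "MIC>0.52", 10L, nmi = 0.03, tr = 0.6),
        evaluationRecord("5", "EFS", 80L, nmi = 0.03, tr = 0.6),
        evaluationRecord("5", "MIC>0.65", 0L),
        evaluationRecord("5", "MIC>0.52", 3L, nmi = 0.01, tr = 0.55),
        evaluationRecord("10", "EFS", 60L, nmi = 0.01, tr = 0.55),
        evaluationRecord("10", "MIC>0.65", 2L, nmi = 0.01, tr = 0.52),
        evaluationRecord("10", "MIC>0.52", 5L, nmi = 0.02, tr = 0.56))
    rep <- buildReport(recs)
    expect_equal(rep$chromosome, c("1", "5", "10")) # numeric order
    # chromosome 5 has no locus above 0.65: a 0/0/0 block, run not aborted
    r5 <- rep[rep$chromosome == "5", ]
    expect_equal(unlist(r5[, c("MIC_0_65_features", "MIC_0_65_nmi",
                               "MIC_0_65_tr")], use.names = FALSE),
                 c(0, 0, 0))
    expect_equal(r5$pd, (0.55 - 0.6) * 100)
    expect_equal(r5$apd, (0.55 - 0.6) / 0.6 * 100)
    expect_equal(r5$proportional_size, 3 / 80 * 100)

    expect_error(buildReport(rbind(recs, recs[1, ])), "duplicate")

    imp <- improvementTable(recs)
    expect_equal(imp$chromosome, c("1", "10")) # only improved chromosomes
    expect_equal(imp$improvement_pct[1],
                 round((0.6 - 0.57) / 0.57 * 100))
})

test_that("published improvement inputs reproduce their printed percents", {
    tab <- studyImprovementInputs()
    recomputed <- round(mapply(adjustedPerformanceDifference,
                               tab$efs_tr, tab$rfs_tr))
    expect_equal(unname(recomputed), tab$published_improvement_pct)
})
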