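# Fixture builders shared across the suite; everything is generated in code
# under fixed seeds.

# random paired cohort with no engineered structure
randomCohort <- function(n = 5, m = 10, seed = 1, chromosome = "1") {
    set.seed(seed)
    pairedCohort(
        cancer = matrix(runif(n * m, 1, 3), n, m),
        blood = matrix(runif(n * m, 1, 3), n, m),
        chromosome = chromosome)
}

# two well-separated Gaussian blobs in 2-D
blobData <- function(nPer = 20, sep = 10, sd = 1, seed = 1) {
    set.seed(seed)
    X <- rbind(
        cbind(rnorm(nPer, 0, sd), rnorm(nPer, 0, sd)),
        cbind(rnorm(nPer, sep, sd), rnorm(nPer, 0, sd)))
    list(X = X, truth = rep(1:2, each = nPer))
}

# same partition up to swapping the two cluster labels
sameBipartition <- function(a, b) {
    identical(as.integer(a), as.integer(b)) ||
        identical(as.integer(a), as.integer(3L - b))
}

# independent entropy arithmetic used as the evaluation oracle
entropyOf <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
}
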