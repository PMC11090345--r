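# Clustering of the unlabeled 2n samples: kernel K-means on a precomputed
# kernel matrix (the kernel trick -- the feature map is never materialized),
# plus Lloyd's K-means and fuzzy c-means baselines. All algorithms take an
# explicit seed; the caller's RNG state is saved and restored.

.withSeed <- function(seed, code) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
    code
}

.sampleMatrix <- function(samples) {
    if (is(samples, "UnlabeledSamples")) samples@values
    else as.matrix(samples)
}

#' Gaussian (RBF) kernel matrix
#'
#' \code{values[i, j] = exp(-||x_i - x_j||^2 / (2 sigma^2))}. With
#' \code{bandwidth = "median"}, sigma is set to the median nonzero pairwise
#' Euclidean distance (the median heuristic).
#'
#' @param samples an [UnlabeledSamples-class] or numeric matrix (rows =
#'   samples).
#' @param bandwidth positive sigma, or \code{"median"}.
#' @return a [KernelMatrix-class].
#' @export
rbfKernel <- function(samples, bandwidth = "median") {
    X <- .sampleMatrix(samples)
    D <- as.matrix(dist(X))
    if (identical(bandwidth, "median")) {
        pos <- D[upper.tri(D)]
        pos <- pos[pos > 0]
        if (length(pos) == 0L)
            stop("median bandwidth undefined: all samples are identical",
                 call. = FALSE)
        sigma <- median(pos)
    } else {
        sigma <- as.numeric(bandwidth)
        if (!is.finite(sigma) || sigma <= 0)
            stop("bandwidth must be a positive number or 'median'",
                 call. = FALSE)
    }
    M <- exp(-D^2 / (2 * sigma^2))
    diag(M) <- 1
    M <- (M + t(M)) / 2
    new("KernelMatrix", values = M, bandwidth = sigma)
}

#' Linear kernel matrix
#'
#' \code{M = X X'}. With a linear kernel, kernel K-means reduces exactly to
#' Lloyd's K-means in the input space, which makes this kernel the
#' algebraic cross-check for the kernel machinery.
#'
#' @inheritParams rbfKernel
#' @return a [KernelMatrix-class] with \code{bandwidth = NA}.
#' @export
linearKernel <- function(samples) {
    X <- .sampleMatrix(samples)
    M <- tcrossprod(X)
    M <- (M + t(M)) / 2
    new("KernelMatrix", values = M, bandwidth = NA_real_)
}

.balancedInit <- function(n, K) sample(rep_len(seq_len(K), n))

# per-cluster kernel statistics: column means of M restricted to each
# cluster, and the mean within-cluster kernel value
.kernelStats <- function(M, z, K) {
    rowm <- matrix(0, nrow(M), K)
    within <- numeric(K)
    for (k in seq_len(K)) {
        idx <- which(z == k)
        rowm[, k] <- rowMeans(M[, idx, drop = FALSE])
        within[k] <- mean(M[idx, idx, drop = FALSE])
    }
    list(rowm = rowm, within = within)
}

.kernelKMeansOnce <- function(M, K, init, epsilon, maxIter) {
    n <- nrow(M)
    dM <- diag(M)
    z <- init
    st <- .kernelStats(M, z, K)
    objTrace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    repeat {
        iter <- iter + 1L
        # squared kernel-space distance of sample i to the center of k
        dist <- dM - 2 * st$rowm + rep(st$within, each = n)
        znew <- max.col(-dist, ties.method = "first")
        # empty-cluster repair: move the worst-fitting point in
        for (k in seq_len(K)) {
            if (!any(znew == k)) {
                own <- dist[cbind(seq_len(n), znew)]
                own[tabulate(znew, K)[znew] <= 1L] <- -Inf
                znew[which.max(own)] <- k
            }
        }
        stNew <- .kernelStats(M, znew, K)
        # kernel-space center displacement |mu_{k,t} - mu_{k,t-1}|
        move <- vapply(seq_len(K), function(k) {
            cross <- mean(M[znew == k, z == k, drop = FALSE])
            sqrt(max(stNew$within[k] + st$within[k] - 2 * cross, 0))
        }, numeric(1L))
        distNew <- dM - 2 * stNew$rowm + rep(stNew$within, each = n)
        obj <- sum(distNew[cbind(seq_len(n), znew)])
        objTrace <- c(objTrace, obj)
        same <- identical(znew, z)
        z <- znew
        st <- stNew
        if (max(move) < epsilon || same) { converged <- TRUE; break }
        if (iter >= maxIter) break
    }
    list(labels = z, objective = obj, iterations = iter,
         converged = converged, trace = objTrace)
}

#' Kernel K-means clustering
#'
#' Partitions samples into K groups using only the kernel matrix: the
#' squared distance of sample i to the center of cluster \eqn{\pi_k} in the
#' implicit feature space expands to
#' \deqn{k(x_i, x_i) - \frac{2}{|\pi_k|}\sum_{j \in \pi_k} k(x_i, x_j)
#'   + \frac{1}{|\pi_k|^2}\sum_{j, c \in \pi_k} k(x_j, x_c),}
#' so centers are never materialized. Iteration stops when every implicit
#' center moves less than \code{epsilon} (kernel-space displacement,
#' computed from the kernel matrix and the two consecutive memberships) or
#' when assignments stop changing. Each restart starts from a random
#' balanced assignment; the best-objective restart is returned. Distance
#' ties go to the lower cluster index, and an emptied cluster is repaired
#' by moving in the sample farthest from its current center.
#'
#' @param kernel a [KernelMatrix-class] (or plain symmetric PSD matrix).
#' @param K number of clusters (>= 2).
#' @param seed integer seed; required, the global RNG is left untouched.
#' @param epsilon convergence tolerance on center displacement.
#' @param maxIter iteration cap per restart.
#' @param restarts number of seeded initializations.
#' @param initial optional explicit initial assignment (length n, values
#'   1..K); when given, restarts are ignored.
#' @return a [ClusterAssignment-class].
#' @export
kernelKMeans <- function(kernel, K = 2L, seed, epsilon = 1e-6,
                         maxIter = 300L, restarts = 10L, initial = NULL) {
    M <- if (is(kernel, "KernelMatrix")) kernel@values else as.matrix(kernel)
    n <- nrow(M)
    K <- as.integer(K)
    if (K < 2L) stop("K must be at least 2", call. = FALSE)
    if (K > n) stop("K cannot exceed the number of samples", call. = FALSE)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(1, abs(ev[1L])))
        stop("kernel matrix is not positive semidefinite", call. = FALSE)
    if (missing(seed)) stop("a seed is required", call. = FALSE)
    seed <- as.integer(seed)

    runs <- .withSeed(seed, {
        if (!is.null(initial)) {
            init <- as.integer(initial)
            stopifnot(length(init) == n, all(init >= 1L), all(init <= K))
            list(.kernelKMeansOnce(M, K, init, epsilon, maxIter))
        } else {
            lapply(seq_len(restarts), function(r)
                .kernelKMeansOnce(M, K, .balancedInit(n, K), epsilon,
                                  maxIter))
        }
    })
    best <- runs[[which.min(vapply(runs, `[[`, numeric(1L), "objective"))]]
    new("ClusterAssignment", labels = best$labels, K = K,
        objective = best$objective, iterations = best$iterations,
        converged = best$converged, seed = seed,
        restartsUsed = length(runs), membership = matrix(0, 0, 0))
}

#' Lloyd's K-means baseline
#'
#' Standard K-means in the input space, run through [stats::kmeans()]
#' (Lloyd iteration) from seeded random balanced initial partitions, with
#' the same restart and determinism contract as [kernelKMeans()].
#'
#' @param samples an [UnlabeledSamples-class] or numeric matrix.
#' @inheritParams kernelKMeans
#' @return a [ClusterAssignment-class].
#' @export
lloydKMeans <- function(samples, K = 2L, seed, epsilon = 1e-6,
                        maxIter = 100L, restarts = 10L, initial = NULL) {
    X <- .sampleMatrix(samples)
    n <- nrow(X)
    K <- as.integer(K)
    if (K < 2L || K > n) stop("need 2 <= K <= n", call. = FALSE)
    if (missing(seed)) stop("a seed is required", call. = FALSE)
    seed <- as.integer(seed)

    oneRun <- function(init) {
        C <- rowsum(X, init) / as.vector(table(factor(init, seq_len(K))))
        res <- tryCatch(
            suppressWarnings(kmeans(X, centers = C, iter.max = maxIter,
                                    algorithm = "Lloyd")),
            error = function(e) NULL)
        if (is.null(res)) return(NULL)
        list(labels = as.integer(res$cluster),
             objective = res$tot.withinss,
             iterations = as.integer(res$iter),
             converged = res$iter < maxIter)
    }
    runs <- .withSeed(seed, {
        if (!is.null(initial)) {
            list(oneRun(as.integer(initial)))
        } else {
            lapply(seq_len(restarts), function(r)
                oneRun(.balancedInit(n, K)))
        }
    })
    runs <- Filter(Negate(is.null), runs)
    if (!length(runs))
        stop("all K-means restarts failed (degenerate input?)",
             call. = FALSE)
    best <- runs[[which.min(vapply(runs, `[[`, numeric(1L), "objective"))]]
    new("ClusterAssignment", labels = best$labels, K = K,
        objective = best$objective, iterations = best$iterations,
        converged = best$converged, seed = seed,
        restartsUsed = length(runs), membership = matrix(0, 0, 0))
}

#' Fuzzy c-means baseline
#'
#' Soft clustering by the standard alternating membership/center updates:
#' centers are membership^fuzzifier weighted means, memberships follow the
#' inverse-distance rule
#' \eqn{u_{ik} = 1 / \sum_j (d_{ik}/d_{ij})^{2/(f-1)}}. A sample coincident
#' with a center receives full membership there (the usual singularity
#' rule). Iteration stops when no membership changes by more than
#' \code{epsilon}. Hard labels are the argmax memberships, ties to the
#' lower cluster index.
#'
#' @param samples an [UnlabeledSamples-class] or numeric matrix.
#' @param fuzzifier exponent f > 1 (default 2).
#' @inheritParams kernelKMeans
#' @return a [ClusterAssignment-class] whose \code{membership} slot holds
#'   the n x K soft memberships.
#' @export
fuzzyCMeans <- function(samples, K = 2L, fuzzifier = 2, seed,
                        epsilon = 1e-6, maxIter = 300L) {
    X <- .sampleMatrix(samples)
    n <- nrow(X)
    K <- as.integer(K)
    if (fuzzifier <= 1) stop("fuzzifier must exceed 1", call. = FALSE)
    if (K < 2L || K > n) stop("need 2 <= K <= n", call. = FALSE)
    if (missing(seed)) stop("a seed is required", call. = FALSE)
    seed <- as.integer(seed)

    U <- .withSeed(seed, {
        u <- matrix(runif(n * K), n, K)
        u / rowSums(u)
    })
    converged <- FALSE
    iter <- 0L
    expo <- 2 / (fuzzifier - 1)
    repeat {
        iter <- iter + 1L
        Um <- U^fuzzifier
        centers <- crossprod(Um, X) / colSums(Um)
        d2 <- vapply(seq_len(K), function(k)
            rowSums(sweep(X, 2L, centers[k, ])^2), numeric(n))
        d2 <- matrix(d2, n, K)
        Unew <- matrix(0, n, K)
        sing <- d2 < 1e-300
        hasSing <- rowSums(sing) > 0L
        if (any(hasSing)) {
            first <- apply(sing[hasSing, , drop = FALSE], 1L, which.max)
            Unew[cbind(which(hasSing), first)] <- 1
        }
        reg <- which(!hasSing)
        if (length(reg)) {
            dr <- d2[reg, , drop = FALSE]^(expo / 2)
            Unew[reg, ] <- (1 / dr) / rowSums(1 / dr)
        }
        delta <- max(abs(Unew - U))
        U <- Unew
        if (delta < epsilon) { converged <- TRUE; break }
        if (iter >= maxIter) break
    }
    labels <- max.col(U, ties.method = "first")
    # degenerate: keep every cluster nonempty for the assignment contract
    for (k in seq_len(K)) {
        if (!any(labels == k)) {
            cand <- which.max(U[, k] - U[cbind(seq_len(n), labels)])
            labels[cand] <- k
        }
    }
    Um <- U^fuzzifier
    centers <- crossprod(Um, X) / colSums(Um)
    d2 <- vapply(seq_len(K), function(k)
        rowSums(sweep(X, 2L, centers[k, ])^2), numeric(n))
    obj <- sum(Um * matrix(d2, n, K))
    new("ClusterAssignment", labels = as.integer(labels), K = K,
        objective = obj, iterations = iter, converged = converged,
        seed = seed, restartsUsed = 1L, membership = U)
}

#' Serialize a cluster assignment to TSV
#'
#' @param assignment a [ClusterAssignment-class].
#' @param sampleIDs sample identifiers, one per row.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAssignment <- function(assignment, sampleIDs, path) {
    df <- data.frame(sample_id = sampleIDs,
                     cluster = assignment@labels)
    if (nrow(assignment@membership) == length(sampleIDs)) {
        mem <- as.data.frame(assignment@membership)
        names(mem) <- sprintf("membership_%d", seq_len(ncol(mem)))
        df <- cbind(df, mem)
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
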