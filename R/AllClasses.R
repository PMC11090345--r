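#' Paired tumor/blood copy-number cohort for one chromosome
#'
#' Holds the two aligned copy-number matrices for a cohort of patients from
#' whom a tumor sample and a matched peripheral-blood sample were profiled.
#' Rows are patients, columns are ordered chromosomal loci; copy-number
#' values are continuous dosages with diploid baseline 2 (gains above 2,
#' deletions below 2, typical range about 1--3).
#'
#' @slot chromosome single chromosome identifier, e.g. \code{"1"}.
#' @slot patients character vector of n patient identifiers.
#' @slot loci integer vector of m strictly increasing 1-based locus ordinals.
#'   Loci are opaque ordered indices, not genomic coordinates.
#' @slot cancer n x m numeric matrix of tumor copy numbers.
#' @slot blood n x m numeric matrix of blood copy numbers, same patient and
#'   locus order.
#'
#' @seealso [readCohort()], [toUnlabeled()], [micProfile()]
#' @export
setClass("PairedCohort",
    representation(
        chromosome = "character",
        patients = "character",
        loci = "integer",
        cancer = "matrix",
        blood = "matrix"
    )
)

setValidity("PairedCohort", function(object) {
    msg <- character()
    n <- nrow(object@cancer)
    m <- ncol(object@cancer)
    if (length(object@chromosome) != 1L)
        msg <- c(msg, "'chromosome' must be a single string")
    if (!identical(dim(object@cancer), dim(object@blood)))
        msg <- c(msg, "cancer and blood matrices must have identical shape")
    if (is.null(n) || n < 2L)
        msg <- c(msg, "at least 2 patients are required")
    if (is.null(m) || m < 1L)
        msg <- c(msg, "at least 1 locus is required")
    if (length(object@patients) != n)
        msg <- c(msg, "length of 'patients' must equal nrow(cancer)")
    if (length(object@loci) != m)
        msg <- c(msg, "length of 'loci' must equal ncol(cancer)")
    if (m >= 1L && any(diff(object@loci) <= 0L))
        msg <- c(msg, "locus order must be strictly increasing")
    if (!all(is.finite(object@cancer)) || !all(is.finite(object@blood)))
        msg <- c(msg, "all copy-number values must be finite")
    else if (any(object@cancer < 0) || any(object@blood < 0))
        msg <- c(msg, "copy-number values must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' Unlabeled sample matrix for clustering
#'
#' The 2n x d matrix handed to the clustering stage: one row per sample
#' (tumor and blood interleaved per patient), one column per retained locus.
#' The true group labels travel alongside but are consulted only by the
#' evaluation functions, never by the clustering itself.
#'
#' @slot sampleIDs character vector of 2n sample identifiers.
#' @slot trueLabels character vector in \code{c("cancer", "blood")}; held
#'   out from clustering, used only for evaluation.
#' @slot values 2n x d numeric matrix.
#'
#' @export
setClass("UnlabeledSamples",
    representation(
        sampleIDs = "character",
        trueLabels = "character",
        values = "matrix"
    )
)

setValidity("UnlabeledSamples", function(object) {
    msg <- character()
    n2 <- nrow(object@values)
    if (length(object@sampleIDs) != n2)
        msg <- c(msg, "sampleIDs length must equal nrow(values)")
    if (length(object@trueLabels) != n2)
        msg <- c(msg, "trueLabels length must equal nrow(values)")
    bad <- setdiff(unique(object@trueLabels), c("cancer", "blood"))
    if (length(bad))
        msg <- c(msg, "trueLabels must be 'cancer' or 'blood'")
    if (length(msg)) msg else TRUE
})

#' Per-locus MIC profile of one chromosome
#'
#' @slot chromosome chromosome identifier.
#' @slot scores numeric vector of per-locus MIC values, each in [0, 1].
#' @slot n sample size (patient pairs) the scores were computed from.
#'
#' @export
setClass("MICProfile",
    representation(
        chromosome = "character",
        scores = "numeric",
        n = "integer"
    )
)

setValidity("MICProfile", function(object) {
    msg <- character()
    if (length(object@scores) < 1L)
        msg <- c(msg, "profile must contain at least one score")
    if (any(!is.finite(object@scores)) ||
        any(object@scores < 0) || any(object@scores > 1))
        msg <- c(msg, "all MIC scores must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Loci retained by MIC thresholding
#'
#' @slot chromosome chromosome identifier.
#' @slot gamma threshold; loci are retained when MIC is strictly greater.
#' @slot selected integer vector of retained locus indices, in locus order.
#' @slot m total locus count of the chromosome.
#'
#' @export
setClass("LocusSelection",
    representation(
        chromosome = "character",
        gamma = "numeric",
        selected = "integer",
        m = "integer"
    )
)

setValidity("LocusSelection", function(object) {
    msg <- character()
    if (object@gamma < 0 || object@gamma > 1)
        msg <- c(msg, "gamma must lie in [0, 1]")
    if (length(object@selected) > object@m)
        msg <- c(msg, "cannot select more loci than exist")
    if (length(object@selected) &&
        (min(object@selected) < 1L || max(object@selected) > object@m))
        msg <- c(msg, "selected indices out of range")
    if (length(msg)) msg else TRUE
})

#' Result of a clustering run
#'
#' @slot labels integer cluster index per sample, in 1..K.
#' @slot K number of clusters.
#' @slot objective final within-cluster distance sum (kernel-space for
#'   kernel K-means, input-space for the baselines).
#' @slot iterations iterations used by the winning restart.
#' @slot converged TRUE when the center-movement criterion was met before
#'   the iteration cap.
#' @slot seed seed that reproduces the run.
#' @slot restartsUsed number of restarts evaluated.
#' @slot membership soft membership matrix (fuzzy c-means only; otherwise a
#'   0 x 0 matrix).
#'
#' @export
setClass("ClusterAssignment",
    representation(
        labels = "integer",
        K = "integer",
        objective = "numeric",
        iterations = "integer",
        converged = "logical",
        seed = "integer",
        restartsUsed = "integer",
        membership = "matrix"
    )
)

setValidity("ClusterAssignment", function(object) {
    msg <- character()
    if (any(object@labels < 1L) || any(object@labels > object@K))
        msg <- c(msg, "labels must lie in 1..K")
    if (length(unique(object@labels)) < object@K)
        msg <- c(msg, "every cluster must be nonempty")
    if (length(msg)) msg else TRUE
})

#' Kernel matrix over the unlabeled samples
#'
#' @slot values symmetric positive-semidefinite matrix of pairwise kernel
#'   evaluations.
#' @slot bandwidth RBF bandwidth sigma, or NA for the linear kernel.
#'
#' @export
setClass("KernelMatrix",
    representation(values = "matrix", bandwidth = "numeric")
)

setValidity("KernelMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v))
        msg <- c(msg, "kernel matrix must be square")
    if (max(abs(v - t(v))) > 1e-10)
        msg <- c(msg, "kernel matrix must be symmetric (tol 1e-10)")
    if (!is.na(object@bandwidth) && max(abs(diag(v) - 1)) > 1e-10)
        msg <- c(msg, "RBF kernel must have unit diagonal")
    if (length(msg)) msg else TRUE
})
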