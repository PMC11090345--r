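# Seed-deterministic generator of paired tumor/blood copy-number cohorts.
#
# The generative model mirrors what the analysis assumes about real paired
# CN data: most loci are uninformative diploid noise; a small fraction of
# loci, arranged in contiguous segments (recurrent aberrations are locally
# correlated), carry (i) a latent per-patient copy-number aberration that
# enters BOTH the tumor and the blood sample -- producing the tumor-blood
# statistical dependence that MIC detects -- and (ii) a tumor-specific mean
# shift whose direction (gain or deletion) is a property of the segment, as
# recurrent somatic CNVs shift consistently across patients. All values are
# clipped to the conventional score range.

#' Study-shaped per-chromosome locus counts
#'
#' The 22 autosomal locus counts of the motivating 63-patient NSCLC cohort
#' (chromosome 1 through 22), used as the default chromosome sizes of the
#' synthetic generator.
#'
#' @return named integer vector of length 22.
#' @export
studyLociCounts <- function() {
    setNames(as.integer(c(
        19873, 22215, 18381, 19067, 17165, 17147, 13951, 14840,
        11941, 14279, 13307, 13061, 11118, 8181, 7014, 7024,
        4854, 8149, 2693, 5838, 3936, 2520)), as.character(1:22))
}

#' Simulation configuration
#'
#' Parameters of the synthetic paired-cohort generator; see
#' [generateCohort()] for the model. Defaults emulate the study geometry:
#' 63 patients, the 22 study-shaped chromosome sizes, 1% of loci carrying
#' tumor-blood dependence in segments of 25 loci, diploid baseline 2 with
#' values clipped to [1, 3].
#'
#' @param nPatients number of patients (pairs of samples).
#' @param chromosomes named integer vector of loci per chromosome.
#' @param sharedFraction fraction of loci with tumor-blood dependence.
#' @param dependence correlation-like strength rho in [0, 1] of the shared
#'   latent aberration; 0 makes shared loci indistinguishable from noise.
#' @param tumorShift mean tumor CN offset delta at shared loci (copy-number
#'   units); the sign (gain/deletion) is drawn per segment.
#' @param noiseSD per-locus Gaussian noise standard deviation.
#' @param baseline diploid copy number.
#' @param clipRange length-2 numeric; all emitted values are clipped into
#'   this interval.
#' @param segmentLength run length over which shared loci are contiguous.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return object of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nPatients = 63L,
                             chromosomes = studyLociCounts(),
                             sharedFraction = 0.01,
                             dependence = 0.3,
                             tumorShift = 0.15,
                             noiseSD = 0.15,
                             baseline = 2,
                             clipRange = c(1, 3),
                             segmentLength = 25L,
                             seed = 1L) {
    if (is.null(names(chromosomes)))
        names(chromosomes) <- as.character(seq_along(chromosomes))
    chromosomes <- setNames(as.integer(chromosomes), names(chromosomes))
    new("SimulationConfig",
        nPatients = as.integer(nPatients),
        chromosomes = chromosomes,
        sharedFraction = sharedFraction, dependence = dependence,
        tumorShift = tumorShift, noiseSD = noiseSD, baseline = baseline,
        clipRange = as.numeric(clipRange),
        segmentLength = as.integer(segmentLength), seed = as.integer(seed))
}

#' @rdname simulationConfig
#' @export
setClass("SimulationConfig",
    representation(
        nPatients = "integer", chromosomes = "integer",
        sharedFraction = "numeric", dependence = "numeric",
        tumorShift = "numeric", noiseSD = "numeric", baseline = "numeric",
        clipRange = "numeric", segmentLength = "integer", seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nPatients < 2L) msg <- c(msg, "nPatients must be >= 2")
    if (any(object@chromosomes < 2L))
        msg <- c(msg, "every chromosome needs at least 2 loci")
    if (object@sharedFraction < 0 || object@sharedFraction > 1)
        msg <- c(msg, "sharedFraction must lie in [0, 1]")
    if (object@dependence < 0 || object@dependence > 1)
        msg <- c(msg, "dependence must lie in [0, 1]")
    if (object@noiseSD <= 0) msg <- c(msg, "noiseSD must be positive")
    if (length(object@clipRange) != 2L ||
        object@clipRange[1L] >= object@clipRange[2L])
        msg <- c(msg, "clipRange must be an increasing length-2 interval")
    if (object@segmentLength < 1L)
        msg <- c(msg, "segmentLength must be >= 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig — %d patients, %d chromosome(s) (m = %d..%d)\n",
        object@nPatients, length(object@chromosomes),
        min(object@chromosomes), max(object@chromosomes)))
    cat(sprintf(
        "  sharedFraction %.3g, dependence %.2f, tumorShift %.2f, noiseSD %.2f, seed %d\n",
        object@sharedFraction, object@dependence, object@tumorShift,
        object@noiseSD, object@seed))
})

# place ceiling(nShared/L) non-overlapping segments on 1..m
.placeSegments <- function(m, nShared, L) {
    if (nShared == 0L) return(NULL)
    L <- min(L, nShared, m)
    nSeg <- ceiling(nShared / L)
    blockSize <- max(L, m %/% nSeg)
    nBlocks <- max(nSeg, m %/% blockSize)
    blocks <- sort(sample.int(nBlocks, nSeg))
    lens <- rep(L, nSeg)
    lens[nSeg] <- nShared - L * (nSeg - 1L)
    starts <- pmin((blocks - 1L) * blockSize + 1L, m - lens + 1L)
    data.frame(start = as.integer(starts),
               end = as.integer(starts + lens - 1L),
               direction = sample(c(-1L, 1L), nSeg, replace = TRUE))
}

.generateChromosome <- function(id, m, cfg) {
    n <- cfg@nPatients
    nShared <- round(cfg@sharedFraction * m)
    if (nShared > 0L && nShared < 2L)
        warning(sprintf(
            "chromosome %s: only %d shared locus; threshold learning with minLoci = 2 may be infeasible",
            id, nShared), call. = FALSE)
    seg <- .placeSegments(m, nShared, cfg@segmentLength)

    blood <- cfg@baseline + matrix(rnorm(n * m, sd = cfg@noiseSD), n, m)
    tumor <- cfg@baseline + matrix(rnorm(n * m, sd = cfg@noiseSD), n, m)

    sharedIdx <- integer(0)
    if (!is.null(seg)) {
        rho <- cfg@dependence
        for (g in seq_len(nrow(seg))) {
            cols <- seg$start[g]:seg$end[g]
            w <- length(cols)
            z <- matrix(rnorm(n * w), n, w) # latent aberration, shared
            e1 <- matrix(rnorm(n * w, sd = cfg@noiseSD), n, w)
            e2 <- matrix(rnorm(n * w, sd = cfg@noiseSD), n, w)
            blood[, cols] <- cfg@baseline + rho * z + sqrt(1 - rho^2) * e1
            tumor[, cols] <- cfg@baseline + rho * z + sqrt(1 - rho^2) * e2 +
                cfg@tumorShift * seg$direction[g]
            sharedIdx <- c(sharedIdx, cols)
        }
    }
    blood <- pmin(pmax(blood, cfg@clipRange[1L]), cfg@clipRange[2L])
    tumor <- pmin(pmax(tumor, cfg@clipRange[1L]), cfg@clipRange[2L])
    list(cohort = pairedCohort(tumor, blood, chromosome = id),
         truth = list(chromosome = id, sharedLoci = sort(sharedIdx),
                      segments = seg, delta = cfg@tumorShift,
                      rho = cfg@dependence))
}

#' Generate a synthetic paired cohort suite with ground truth
#'
#' For each configured chromosome, non-shared loci are independent
#' Gaussian noise around the diploid baseline in both samples. Shared loci
#' come in contiguous segments: a latent per-patient, per-locus aberration
#' \eqn{z \sim N(0, 1)} enters both samples weighted by the dependence
#' \eqn{\rho} (residual noise scaled by \eqn{\sqrt{1 - \rho^2}}), which
#' creates the tumor-blood association that MIC detects, and the tumor
#' additionally receives the mean shift \eqn{\pm\delta} whose sign is the
#' segment's aberration direction (gain or deletion). All values are
#' clipped to \code{clipRange}. Deterministic given \code{config@seed}.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{cohorts} (named list of
#'   [PairedCohort-class]) and \code{truth} (per-chromosome list of shared
#'   locus indices, segment table with gain/deletion direction, and the
#'   realized delta and rho).
#' @examples
#' sim <- generateCohort(simulationConfig(
#'     nPatients = 12, chromosomes = c(A = 50), seed = 7))
#' dim(cancerCN(sim$cohorts$A))
#' @export
generateCohort <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    .withSeed(config@seed, {
        res <- lapply(names(config@chromosomes), function(id)
            .generateChromosome(id, config@chromosomes[[id]], config))
        names(res) <- names(config@chromosomes)
        list(cohorts = lapply(res, `[[`, "cohort"),
             truth = c(lapply(res, `[[`, "truth"),
                       list(seed = config@seed)))
    })
}

#' Generate the full study-shaped suite
#'
#' Convenience wrapper: 22 chromosomes with the published per-chromosome
#' locus counts (see [studyLociCounts()]), 63 patients, default generator
#' parameters.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [simulationConfig()].
#' @return as [generateCohort()]; 22 cohorts.
#' @export
studyShapedSuite <- function(seed, ...) {
    generateCohort(simulationConfig(seed = seed, ...))
}
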