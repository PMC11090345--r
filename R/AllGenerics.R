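#' @name micnv-accessors
#' @title Accessors for micnv classes
#'
#' @description Small accessor generics for the package's S4 containers:
#' matrices, identifiers and counts are read through these rather than by
#' slot access.
#'
#' @param x an object of the documented class.
#' @return The requested component; see the individual methods.
NULL

#' @rdname micnv-accessors
#' @export
setGeneric("chromosome", function(x) standardGeneric("chromosome"))

#' @rdname micnv-accessors
#' @export
setGeneric("patientIDs", function(x) standardGeneric("patientIDs"))

#' @rdname micnv-accessors
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname micnv-accessors
#' @export
setGeneric("cancerCN", function(x) standardGeneric("cancerCN"))

#' @rdname micnv-accessors
#' @export
setGeneric("bloodCN", function(x) standardGeneric("bloodCN"))

#' @rdname micnv-accessors
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))

#' @rdname micnv-accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname micnv-accessors
#' @export
setGeneric("micScores", function(x) standardGeneric("micScores"))

#' @rdname micnv-accessors
#' @export
setGeneric("sampleValues", function(x) standardGeneric("sampleValues"))

#' @rdname micnv-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname micnv-accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' @rdname micnv-accessors
#' @export
setGeneric("selectedLoci", function(x) standardGeneric("selectedLoci"))

#' @rdname micnv-accessors
#' @export
setGeneric("nSelected", function(x) standardGeneric("nSelected"))

#' @rdname micnv-accessors
#' @export
setGeneric("gammaThreshold", function(x) standardGeneric("gammaThreshold"))

#' @rdname micnv-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname micnv-accessors
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname micnv-accessors
#' @export
setGeneric("membershipMatrix", function(x) standardGeneric("membershipMatrix"))

#' @rdname micnv-accessors
#' @export
setGeneric("kernelValues", function(x) standardGeneric("kernelValues"))

#' Convert a paired cohort to the unlabeled sample matrix
#'
#' @param cohort a [PairedCohort-class].
#' @return an [UnlabeledSamples-class]; see the method documentation.
#' @export
setGeneric("toUnlabeled", function(cohort) standardGeneric("toUnlabeled"))

#' Compute the per-locus MIC profile of a cohort
#'
#' @param cohort a [PairedCohort-class].
#' @param ... passed to methods.
#' @return a [MICProfile-class].
#' @export
setGeneric("micProfile", function(cohort, ...) standardGeneric("micProfile"))

# ---- accessor methods ------------------------------------------------------

#' @rdname micnv-accessors
setMethod("chromosome", "PairedCohort", function(x) x@chromosome)
#' @rdname micnv-accessors
setMethod("chromosome", "MICProfile", function(x) x@chromosome)
#' @rdname micnv-accessors
setMethod("chromosome", "LocusSelection", function(x) x@chromosome)
#' @rdname micnv-accessors
setMethod("patientIDs", "PairedCohort", function(x) x@patients)
#' @rdname micnv-accessors
setMethod("loci", "PairedCohort", function(x) x@loci)
#' @rdname micnv-accessors
setMethod("cancerCN", "PairedCohort", function(x) x@cancer)
#' @rdname micnv-accessors
setMethod("bloodCN", "PairedCohort", function(x) x@blood)
#' @rdname micnv-accessors
setMethod("nPatients", "PairedCohort", function(x) nrow(x@cancer))
#' @rdname micnv-accessors
setMethod("nLoci", "PairedCohort", function(x) ncol(x@cancer))
#' @rdname micnv-accessors
setMethod("nLoci", "MICProfile", function(x) length(x@scores))
#' @rdname micnv-accessors
setMethod("micScores", "MICProfile", function(x) x@scores)
#' @rdname micnv-accessors
setMethod("sampleValues", "UnlabeledSamples", function(x) x@values)
#' @rdname micnv-accessors
setMethod("sampleIDs", "UnlabeledSamples", function(x) x@sampleIDs)
#' @rdname micnv-accessors
setMethod("trueLabels", "UnlabeledSamples", function(x) x@trueLabels)
#' @rdname micnv-accessors
setMethod("selectedLoci", "LocusSelection", function(x) x@selected)
#' @rdname micnv-accessors
setMethod("nSelected", "LocusSelection", function(x) length(x@selected))
#' @rdname micnv-accessors
setMethod("nLoci", "LocusSelection", function(x) x@m)
#' @rdname micnv-accessors
setMethod("gammaThreshold", "LocusSelection", function(x) x@gamma)
#' @rdname micnv-accessors
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)
#' @rdname micnv-accessors
setMethod("objectiveValue", "ClusterAssignment", function(x) x@objective)
#' @rdname micnv-accessors
setMethod("membershipMatrix", "ClusterAssignment", function(x) x@membership)
#' @rdname micnv-accessors
setMethod("kernelValues", "KernelMatrix", function(x) x@values)

# ---- show methods ----------------------------------------------------------

setMethod("show", "PairedCohort", function(object) {
    cat("PairedCohort chromosome", object@chromosome, "—",
        nrow(object@cancer), "patients x", ncol(object@cancer), "loci\n")
    cat("  cancer CN range:",
        sprintf("[%.3g, %.3g]", min(object@cancer), max(object@cancer)),
        " blood CN range:",
        sprintf("[%.3g, %.3g]", min(object@blood), max(object@blood)), "\n")
})

setMethod("show", "UnlabeledSamples", function(object) {
    cat("UnlabeledSamples —", nrow(object@values), "samples x",
        ncol(object@values), "features",
        sprintf("(%d cancer / %d blood labels held out)\n",
                sum(object@trueLabels == "cancer"),
                sum(object@trueLabels == "blood")))
})

setMethod("show", "MICProfile", function(object) {
    cat("MICProfile chromosome", object@chromosome, "—",
        length(object@scores), "loci, n =", object@n, "\n")
    cat(sprintf("  MIC: min %.4f / median %.4f / max %.4f\n",
                min(object@scores), median(object@scores),
                max(object@scores)))
})

setMethod("show", "LocusSelection", function(object) {
    cat(sprintf(
        "LocusSelection chromosome %s — %d of %d loci with MIC > %.3g\n",
        object@chromosome, length(object@selected), object@m, object@gamma))
})

setMethod("show", "ClusterAssignment", function(object) {
    cat(sprintf(
        "ClusterAssignment — K = %d, n = %d, objective = %.6g, %s after %d iterations\n",
        object@K, length(object@labels), object@objective,
        if (object@converged) "converged" else "NOT converged",
        object@iterations))
})

setMethod("show", "KernelMatrix", function(object) {
    cat(sprintf("KernelMatrix — %d x %d, %s\n",
                nrow(object@values), ncol(object@values),
                if (is.na(object@bandwidth)) "linear"
                else sprintf("RBF (sigma = %.4g)", object@bandwidth)))
})
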