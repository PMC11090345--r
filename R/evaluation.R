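#' Best-map true rate of a two-group clustering
#'
#' Accuracy of the clustering against the held-out cancer/blood labels
#' under the better of the two possible cluster-to-label mappings. For two
#' balanced classes the floor is 0.5: whichever way a partition falls, one
#' of the two mappings gets at least half the samples right.
#'
#' @param assignment a [ClusterAssignment-class] with K = 2, or an integer
#'   vector of cluster labels in \{1, 2\}.
#' @param labels true group per sample (\code{"cancer"}/\code{"blood"}, or
#'   any two-level vector).
#' @return fraction in [0.5, 1].
#' @export
trueRate <- function(assignment, labels) {
    z <- if (is(assignment, "ClusterAssignment")) assignment@labels
         else as.integer(assignment)
    if (length(unique(z)) > 2L || any(z < 1L) || any(z > 2L))
        stop("true rate is defined for the two-cluster problem (K = 2)",
             call. = FALSE)
    lab <- as.character(labels)
    classes <- sort(unique(lab))
    if (length(classes) != 2L)
        stop("labels must have exactly two classes", call. = FALSE)
    stopifnot(length(z) == length(lab))
    mapA <- mean((z == 1L) == (lab == classes[1L]))
    max(mapA, 1 - mapA)
}

.entropyFromCounts <- function(cnt) {
    p <- cnt[cnt > 0] / sum(cnt)
    -sum(p * log(p))
}

#' Normalized mutual information between a clustering and the true groups
#'
#' \eqn{NMI = I(C; L) / g(H(C), H(L))} where the normalizer \eqn{g} is by
#' default the geometric mean \eqn{\sqrt{H(C) H(L)}}. The log base cancels.
#' If either partition has zero entropy (everything in one group) the NMI
#' is defined as 0. Symmetric in its two arguments and invariant under
#' relabeling either partition.
#'
#' @param assignment a [ClusterAssignment-class] or label vector.
#' @param labels true group per sample.
#' @param normalization \code{"sqrt"} (geometric mean, default),
#'   \code{"arithmetic"}, \code{"min"} or \code{"max"} of the two
#'   entropies.
#' @return value in [0, 1].
#' @export
nmiScore <- function(assignment, labels,
                     normalization = c("sqrt", "arithmetic", "min", "max")) {
    normalization <- match.arg(normalization)
    z <- if (is(assignment, "ClusterAssignment")) assignment@labels
         else assignment
    stopifnot(length(z) == length(labels), length(z) > 0L)
    tab <- table(z, labels)
    hz <- .entropyFromCounts(rowSums(tab))
    hl <- .entropyFromCounts(colSums(tab))
    if (hz == 0 || hl == 0) return(0)
    I <- hz + hl - .entropyFromCounts(tab)
    denom <- switch(normalization,
        sqrt = sqrt(hz * hl),
        arithmetic = (hz + hl) / 2,
        min = min(hz, hl),
        max = max(hz, hl))
    min(max(I / denom, 0), 1)
}

#' Performance difference between reduced and entire feature sets
#'
#' \code{(trRFS - trEFS) * 100}, in percentage points. Positive values mean
#' the reduced feature set clusters better than the entire feature set.
#'
#' @param trEFS true rate using the entire feature set, in [0, 1].
#' @param trRFS true rate using the reduced feature set, in [0, 1].
#' @return signed percent.
#' @examples
#' performanceDifference(0.524, 0.675) # +15.1
#' @export
performanceDifference <- function(trEFS, trRFS) {
    stopifnot(trEFS >= 0, trEFS <= 1, trRFS >= 0, trRFS <= 1)
    (trRFS - trEFS) * 100
}

#' Adjusted performance difference
#'
#' \code{(trRFS - trEFS) / trEFS * 100}: the performance difference
#' relative to the entire-feature-set baseline, as a signed percent.
#'
#' @inheritParams performanceDifference
#' @return signed percent.
#' @examples
#' adjustedPerformanceDifference(0.524, 0.675) # about +29
#' @export
adjustedPerformanceDifference <- function(trEFS, trRFS) {
    stopifnot(trEFS >= 0, trEFS <= 1, trRFS >= 0, trRFS <= 1)
    if (trEFS == 0)
        stop("adjusted performance difference is undefined for trEFS = 0",
             call. = FALSE)
    (trRFS - trEFS) / trEFS * 100
}

#' Proportional size of the reduced feature set
#'
#' \code{v / m * 100}, the retained fraction as a percent. \code{v = 0}
#' (nothing selected, the chromosome is reported as not clustered) yields
#' 0.
#'
#' @param v number of selected loci.
#' @param m total loci.
#' @return percent in [0, 100].
#' @examples
#' proportionalSize(5, 8149)    # about 0.06
#' proportionalSize(392, 22215) # about 1.76
#' @export
proportionalSize <- function(v, m) {
    stopifnot(m >= 1, v >= 0, v <= m)
    v / m * 100
}

#' One evaluation record
#'
#' The machine form of one report cell block: a chromosome under one
#' feature-set configuration with its feature count, NMI and true rate.
#' Configurations with zero features are flagged \code{clustered = FALSE}
#' and carry zero metrics.
#'
#' @param chromosome chromosome identifier.
#' @param configuration configuration label, e.g. \code{"EFS"} or
#'   \code{"MIC>0.65"}.
#' @param featureCount number of features used (v or m).
#' @param nmi,tr clustering scores; ignored (forced 0) when
#'   \code{featureCount} is 0.
#' @return one-row data.frame.
#' @export
evaluationRecord <- function(chromosome, configuration, featureCount,
                             nmi = 0, tr = 0) {
    clustered <- featureCount > 0L
    data.frame(chromosome = as.character(chromosome),
               configuration = as.character(configuration),
               features = as.integer(featureCount),
               nmi = if (clustered) nmi else 0,
               true_rate = if (clustered) tr else 0,
               clustered = clustered,
               stringsAsFactors = FALSE)
}

.chromOrder <- function(ids) {
    num <- suppressWarnings(as.numeric(ids))
    order(is.na(num), num, ids)
}

#' Build the per-chromosome clustering report
#'
#' Pivots evaluation records into one row per chromosome with a
#' (features, NMI, true rate) block per configuration, in the style of a
#' per-chromosome results table. Chromosomes a configuration could not
#' cluster (zero selected loci) render as a 0/0/0 block. When both an
#' \code{"EFS"} configuration and \code{rfsConfiguration} are present, a
#' comparison block with PD, APD and the proportional feature-set size is
#' appended.
#'
#' @param records data.frame of rows from [evaluationRecord()].
#' @param rfsConfiguration which configuration to treat as the reduced
#'   feature set in the comparison block (default \code{"MIC>0.52"}).
#' @return data.frame, one row per chromosome, sorted by chromosome
#'   number.
#' @export
buildReport <- function(records, rfsConfiguration = "MIC>0.52") {
    stopifnot(nrow(records) >= 1L)
    key <- paste(records$chromosome, records$configuration, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicate (chromosome, configuration) record(s): ",
             paste(unique(records$chromosome[duplicated(key)]),
                   collapse = ", "), call. = FALSE)
    chroms <- unique(records$chromosome)
    chroms <- chroms[.chromOrder(chroms)]
    configs <- unique(records$configuration)
    out <- data.frame(chromosome = chroms, stringsAsFactors = FALSE)
    for (cf in configs) {
        sub <- records[records$configuration == cf, ]
        idx <- match(chroms, sub$chromosome)
        safe <- gsub("[^0-9A-Za-z]+", "_", cf)
        out[[paste0(safe, "_features")]] <-
            ifelse(is.na(idx), 0L, sub$features[idx])
        out[[paste0(safe, "_nmi")]] <- ifelse(is.na(idx), 0, sub$nmi[idx])
        out[[paste0(safe, "_tr")]] <-
            ifelse(is.na(idx), 0, sub$true_rate[idx])
    }
    if ("EFS" %in% configs && rfsConfiguration %in% configs) {
        efs <- records[records$configuration == "EFS", ]
        rfs <- records[records$configuration == rfsConfiguration, ]
        ie <- match(chroms, efs$chromosome)
        ir <- match(chroms, rfs$chromosome)
        trE <- efs$true_rate[ie]
        trR <- rfs$true_rate[ir]
        ok <- !is.na(trE) & !is.na(trR) & efs$clustered[ie] &
            rfs$clustered[ir] & trE > 0
        out$pd <- ifelse(ok, (trR - trE) * 100, NA_real_)
        out$apd <- ifelse(ok, (trR - trE) / trE * 100, NA_real_)
        out$proportional_size <-
            ifelse(is.na(ir), NA_real_,
                   rfs$features[ir] / efs$features[ie] * 100)
    }
    out
}

#' Rank chromosomes by clustering improvement
#'
#' The improvement-ranking companion table: chromosomes where the reduced
#' feature set beat the entire feature set, sorted by decreasing APD.
#'
#' @inheritParams buildReport
#' @return data.frame with chromosome, feature counts, true rates and the
#'   rounded improvement percent.
#' @export
improvementTable <- function(records, rfsConfiguration = "MIC>0.52") {
    rep <- buildReport(records, rfsConfiguration)
    if (is.null(rep$apd)) stop("comparison block unavailable", call. = FALSE)
    keep <- !is.na(rep$apd) & rep$apd > 0
    sub <- rep[keep, , drop = FALSE]
    sub <- sub[order(-sub$apd), , drop = FALSE]
    safe <- gsub("[^0-9A-Za-z]+", "_", rfsConfiguration)
    data.frame(chromosome = sub$chromosome,
               efs_features = sub$EFS_features,
               efs_tr = sub$EFS_tr,
               rfs_features = sub[[paste0(safe, "_features")]],
               rfs_tr = sub[[paste0(safe, "_tr")]],
               improvement_pct = round(sub$apd),
               stringsAsFactors = FALSE)
}
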