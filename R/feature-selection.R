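#' Select loci whose MIC exceeds a threshold
#'
#' Retains the loci with MIC strictly greater than \code{gamma}, preserving
#' locus order. The inequality is strict: a score exactly equal to the
#' threshold is dropped.
#'
#' @param profile a [MICProfile-class].
#' @param gamma threshold in [0, 1].
#' @return a [LocusSelection-class].
#' @examples
#' p <- new("MICProfile", chromosome = "1",
#'          scores = c(0.7, 0.5, 0.66, 0.65), n = 63L)
#' selectedLoci(selectLoci(p, 0.65)) # 1 and 3; 0.65 itself is excluded
#' @export
selectLoci <- function(profile, gamma) {
    stopifnot(is(profile, "MICProfile"), gamma >= 0, gamma <= 1)
    new("LocusSelection", chromosome = profile@chromosome,
        gamma = as.numeric(gamma),
        selected = which(profile@scores > gamma),
        m = length(profile@scores))
}

#' Learn a common threshold keeping a minimum locus count per chromosome
#'
#' Searches a grid of candidate thresholds and returns the largest
#' \code{gamma} such that every profile retains at least \code{minLoci}
#' loci with MIC strictly above it. This formalizes the ad-hoc rule used to
#' pick a global threshold across chromosomes when a fixed high threshold
#' leaves some chromosomes with no usable locus.
#'
#' @param profiles list of [MICProfile-class] objects (one per chromosome).
#' @param minLoci minimum number of retained loci required on every
#'   chromosome (default 2, the smallest feature set a clustering can use
#'   meaningfully).
#' @param grid numeric vector of candidate thresholds; default
#'   \code{seq(0, 0.99, by = 0.01)}.
#' @return the learned threshold (a value of \code{grid}).
#' @export
learnThreshold <- function(profiles, minLoci = 2L,
                           grid = seq(0, 0.99, by = 0.01)) {
    stopifnot(length(profiles) >= 1L, minLoci >= 1L, length(grid) >= 1L)
    grid <- sort(grid)
    feasible <- function(g)
        all(vapply(profiles, function(p) sum(p@scores > g) >= minLoci,
                   logical(1L)))
    ok <- vapply(grid, feasible, logical(1L))
    if (!any(ok)) {
        counts <- vapply(profiles,
                         function(p) sum(p@scores > grid[1L]), integer(1L))
        lim <- which.min(counts)
        id <- if (!is.null(names(profiles)[lim]) &&
                  nzchar(names(profiles)[lim])) names(profiles)[lim]
              else profiles[[lim]]@chromosome
        stop(sprintf(
            "no feasible threshold on the grid: chromosome %s has only %d locus/loci above the smallest candidate %g (need %d)",
            id, counts[lim], grid[1L], minLoci), call. = FALSE)
    }
    grid[max(which(ok))]
}

#' Restrict an unlabeled sample matrix to selected loci
#'
#' @param samples an [UnlabeledSamples-class] whose d columns are the full
#'   locus set of the selection's chromosome.
#' @param selection a [LocusSelection-class].
#' @return an [UnlabeledSamples-class] with \code{d = v} columns; row order
#'   and labels are preserved.
#' @export
reduceMatrix <- function(samples, selection) {
    stopifnot(is(samples, "UnlabeledSamples"), is(selection, "LocusSelection"))
    sel <- selection@selected
    if (length(sel) == 0L)
        stop("clustering requires at least 1 feature: selection is empty",
             call. = FALSE)
    if (max(sel) > ncol(samples@values))
        stop("selection index out of range for the sample matrix",
             call. = FALSE)
    new("UnlabeledSamples", sampleIDs = samples@sampleIDs,
        trueLabels = samples@trueLabels,
        values = samples@values[, sel, drop = FALSE])
}

#' Serialize locus selections to TSV
#'
#' One row per selection: chromosome, gamma, v, m and the comma-joined
#' selected indices.
#'
#' @param selections list of [LocusSelection-class] objects.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSelections <- function(selections, path) {
    df <- do.call(rbind, lapply(selections, function(s) data.frame(
        chromosome = s@chromosome, gamma = s@gamma,
        v = length(s@selected), m = s@m,
        selected = paste(s@selected, collapse = ","))))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
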