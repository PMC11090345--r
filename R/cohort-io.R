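#' Construct a paired cohort
#'
#' @param cancer n x m numeric matrix of tumor copy numbers (patients in
#'   rows, loci in columns).
#' @param blood n x m numeric matrix of blood copy numbers, same order.
#' @param chromosome chromosome identifier.
#' @param patients optional patient identifiers; defaults to
#'   \code{"P001"...}.
#' @param loci optional strictly increasing locus ordinals; defaults to
#'   \code{1:m}.
#' @return a [PairedCohort-class].
#' @examples
#' co <- pairedCohort(matrix(2, 3, 4), matrix(2, 3, 4))
#' nPatients(co)
#' @export
pairedCohort <- function(cancer, blood, chromosome = "1",
                         patients = NULL, loci = NULL) {
    cancer <- as.matrix(cancer)
    blood <- as.matrix(blood)
    storage.mode(cancer) <- "double"
    storage.mode(blood) <- "double"
    if (is.null(patients))
        patients <- sprintf("P%03d", seq_len(nrow(cancer)))
    if (is.null(loci))
        loci <- seq_len(ncol(cancer))
    new("PairedCohort", chromosome = as.character(chromosome),
        patients = as.character(patients), loci = as.integer(loci),
        cancer = unname(cancer), blood = unname(blood))
}

.sniffSep <- function(path) {
    first <- readLines(path, n = 1L)
    if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

.parseNumericCells <- function(chr, path, rowOffset = 1L, colNames = NULL) {
    num <- suppressWarnings(apply(chr, 2L, as.numeric))
    if (is.null(dim(num))) num <- matrix(num, nrow = nrow(chr))
    if (anyNA(num)) {
        bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
        colname <- if (is.null(colNames)) bad[2L] else colNames[bad[2L]]
        stop(sprintf(
            "malformed numeric cell in '%s' at data row %d, column '%s'",
            path, bad[1L] + rowOffset - 1L, colname), call. = FALSE)
    }
    num
}

#' Read a paired copy-number cohort from a delimited text file
#'
#' Two rectangular layouts are supported. The \emph{interleaved} layout has
#' one row per sample with a group-label column and strict cancer/blood
#' alternation starting with cancer, so patient i occupies rows 2i-1 and 2i.
#' The \emph{paired} layout has one row per patient with two adjacent
#' columns (cancer, blood) per locus. The delimiter (tab or comma) is
#' sniffed from the header line.
#'
#' Expected columns, by layout:
#' \describe{
#'   \item{interleaved}{optional \code{patient}, \code{group}
#'     (cancer/blood, case-insensitive), then one numeric column per locus.}
#'   \item{paired}{optional \code{patient}, then
#'     \code{<locus>_cancer}, \code{<locus>_blood} column pairs.}
#' }
#'
#' @param path file to read.
#' @param layout \code{"interleaved"} or \code{"paired"}.
#' @param chromosome chromosome identifier to stamp on the cohort; defaults
#'   to the file name without extension.
#' @param warnRange numeric length-2 vector; values outside it trigger a
#'   warning (copy-number scores are conventionally in about [1, 3]).
#'   \code{NULL} disables the check.
#' @return a [PairedCohort-class].
#' @seealso [writeCohort()]
#' @export
readCohort <- function(path, layout = c("interleaved", "paired"),
                       chromosome = NULL, warnRange = c(1, 3)) {
    layout <- match.arg(layout)
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    if (is.null(chromosome))
        chromosome <- sub("^chr", "", sub("\\.[^.]*$", "", basename(path)))
    sep <- .sniffSep(path)
    tab <- read.table(path, header = TRUE, sep = sep,
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE)
    cols <- names(tab)
    hasPatient <- length(cols) && tolower(cols[1L]) == "patient"

    if (layout == "interleaved") {
        pid <- NULL
        if (hasPatient) { pid <- tab[[1L]]; tab <- tab[-1L]; cols <- cols[-1L] }
        if (!length(cols) || tolower(cols[1L]) != "group")
            stop("interleaved layout requires a 'group' column", call. = FALSE)
        grp <- tolower(tab[[1L]])
        tab <- tab[-1L]
        if (nrow(tab) %% 2L != 0L)
            stop(sprintf(
                "interleaved file '%s' has an odd number of data rows (%d)",
                path, nrow(tab)), call. = FALSE)
        bad <- setdiff(unique(grp), c("cancer", "blood"))
        if (length(bad))
            stop("unrecognized group label(s): ",
                 paste(bad, collapse = ", "), call. = FALSE)
        odd <- seq(1L, nrow(tab), by = 2L)
        if (!all(grp[odd] == "cancer") || !all(grp[odd + 1L] == "blood"))
            stop("interleaved layout requires strict cancer/blood ",
                 "alternation starting with cancer", call. = FALSE)
        vals <- .parseNumericCells(as.matrix(tab), path,
                                   colNames = names(tab))
        cancer <- vals[odd, , drop = FALSE]
        blood <- vals[odd + 1L, , drop = FALSE]
        patients <- if (is.null(pid)) NULL else pid[odd]
    } else {
        pid <- NULL
        if (hasPatient) { pid <- tab[[1L]]; tab <- tab[-1L]; cols <- cols[-1L] }
        isCancer <- grepl("_cancer$", cols)
        isBlood <- grepl("_blood$", cols)
        if (!any(isCancer) || sum(isCancer) != sum(isBlood))
            stop(sprintf(
                "paired layout of '%s' has mismatched locus counts between groups (%d cancer vs %d blood columns)",
                path, sum(isCancer), sum(isBlood)), call. = FALSE)
        base_c <- sub("_cancer$", "", cols[isCancer])
        base_b <- sub("_blood$", "", cols[isBlood])
        if (!identical(base_c, base_b))
            stop("paired layout: cancer/blood column pairs do not align",
                 call. = FALSE)
        vals <- .parseNumericCells(as.matrix(tab), path, colNames = cols)
        cancer <- vals[, isCancer, drop = FALSE]
        blood <- vals[, isBlood, drop = FALSE]
        patients <- pid
    }

    co <- pairedCohort(cancer, blood, chromosome = chromosome,
                       patients = patients)
    if (!is.null(warnRange)) {
        out <- sum(cancer < warnRange[1L] | cancer > warnRange[2L]) +
            sum(blood < warnRange[1L] | blood > warnRange[2L])
        if (out > 0L)
            warning(sprintf(
                "%d copy-number value(s) outside [%g, %g] in '%s'",
                out, warnRange[1L], warnRange[2L], path), call. = FALSE)
    }
    co
}

#' Write a paired cohort to a delimited text file
#'
#' Values are serialized at full double precision (17 significant digits),
#' so \code{readCohort(writeCohort(x))} reproduces the matrices bit-exactly.
#'
#' @param cohort a [PairedCohort-class].
#' @param path output file; the delimiter is a tab unless the file name
#'   ends in \code{.csv}.
#' @param layout \code{"interleaved"} or \code{"paired"}.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(cohort, path, layout = c("interleaved", "paired")) {
    layout <- match.arg(layout)
    stopifnot(is(cohort, "PairedCohort"))
    if (ncol(cohort@cancer) == 0L)
        stop("refusing to write a cohort with zero loci", call. = FALSE)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    n <- nrow(cohort@cancer)
    m <- ncol(cohort@cancer)
    fmt <- function(x) formatC(x, digits = 17, format = "g")
    lname <- sprintf("L%d", cohort@loci)

    if (layout == "interleaved") {
        vals <- matrix("", 2L * n, m)
        vals[seq(1L, 2L * n, by = 2L), ] <- fmt(cohort@cancer)
        vals[seq(2L, 2L * n, by = 2L), ] <- fmt(cohort@blood)
        df <- data.frame(
            patient = rep(cohort@patients, each = 2L),
            group = rep(c("cancer", "blood"), n),
            vals, check.names = FALSE, stringsAsFactors = FALSE)
        names(df) <- c("patient", "group", lname)
    } else {
        vals <- matrix("", n, 2L * m)
        vals[, seq(1L, 2L * m, by = 2L)] <- fmt(cohort@cancer)
        vals[, seq(2L, 2L * m, by = 2L)] <- fmt(cohort@blood)
        cn <- character(2L * m)
        cn[seq(1L, 2L * m, by = 2L)] <- paste0(lname, "_cancer")
        cn[seq(2L, 2L * m, by = 2L)] <- paste0(lname, "_blood")
        df <- data.frame(patient = cohort@patients, vals,
                         check.names = FALSE, stringsAsFactors = FALSE)
        names(df) <- c("patient", cn)
    }
    tryCatch(
        suppressWarnings(write.table(df, path, sep = sep, quote = FALSE,
                                     row.names = FALSE)),
        error = function(e) stop(sprintf("cannot write '%s': %s",
                                         path, conditionMessage(e)),
                                 call. = FALSE))
    invisible(path)
}

#' @describeIn toUnlabeled Interleave the cancer and blood rows of a cohort
#'   into the 2n x m matrix used for clustering. Row order is patient 1
#'   cancer, patient 1 blood, patient 2 cancer, ... and the true group
#'   labels are carried along for evaluation only.
#' @export
setMethod("toUnlabeled", "PairedCohort", function(cohort) {
    n <- nrow(cohort@cancer)
    m <- ncol(cohort@cancer)
    vals <- matrix(0, 2L * n, m)
    vals[seq(1L, 2L * n, by = 2L), ] <- cohort@cancer
    vals[seq(2L, 2L * n, by = 2L), ] <- cohort@blood
    new("UnlabeledSamples",
        sampleIDs = paste0(rep(cohort@patients, each = 2L),
                           rep(c(".cancer", ".blood"), n)),
        trueLabels = rep(c("cancer", "blood"), n),
        values = vals)
})
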