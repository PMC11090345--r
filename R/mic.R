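#' Mutual information of a contingency grid, in bits
#'
#' Computes \eqn{I = H(x) + H(y) - H(x, y)} from empirical cell and marginal
#' frequencies with base-2 logarithms; empty cells contribute zero
#' (\eqn{0 \log 0 := 0}).
#'
#' @param counts nonnegative integer matrix of joint bin occupancies.
#' @return mutual information in bits (nonnegative).
#' @examples
#' gridMutualInformation(matrix(c(5, 0, 0, 5), 2)) # 1 bit
#' @export
gridMutualInformation <- function(counts) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
    n <- sum(counts)
    if (n < 1) stop("total count must be at least 1", call. = FALSE)
    xlx <- function(v) { v <- v[v > 0]; sum(v * log2(v)) }
    I <- (xlx(counts) - xlx(rowSums(counts)) - xlx(colSums(counts))) / n +
        log2(n)
    max(I, 0)
}

#' Admissible grid shapes under the B(n) budget
#'
#' The MIC maximization searches all grid shapes \eqn{(n_x, n_y)} with
#' \eqn{n_x, n_y \ge 2} and \eqn{n_x n_y < B(n)} where \eqn{B(n) = n^{0.6}}.
#' The inequality is strict and \eqn{B(n)} is not rounded. At the study's
#' sample size n = 63, \eqn{B(63) \approx 11.99} and the admissible set is
#' the eight shapes up to 2x5 and 3x3.
#'
#' @param n sample size.
#' @return two-column integer matrix of shapes (columns \code{nx},
#'   \code{ny}), in lexicographic order.
#' @export
admissibleGridShapes <- function(n) {
    stopifnot(length(n) == 1L, n >= 1)
    out <- cpp_admissible_shapes(as.integer(n))
    colnames(out) <- c("nx", "ny")
    out
}

.micMode <- function(exhaustive = c("auto", "always", "never")) {
    match(match.arg(exhaustive), c("auto", "always", "never")) - 1L
}

#' Maximized grid mutual information at a fixed shape
#'
#' Maximizes [gridMutualInformation()] over axis partitions of the data at
#' grid shape \code{(nx, ny)}. Cut points are placed only between distinct
#' consecutive order statistics, so tied values never straddle a bin. With
#' \code{exhaustive = "always"} every legal cut placement is enumerated;
#' \code{"auto"} enumerates exhaustively for n <= 20 (all shapes) and for
#' 2x2 grids up to n = 200, and otherwise uses an equipartition +
#' dynamic-programming search evaluated in both axis orientations.
#'
#' @param x,y numeric vectors of equal length n.
#' @param nx,ny bin counts (each at least 2, at most n).
#' @param exhaustive search mode, see Details.
#' @return maximal mutual information in bits; at most
#'   \code{log2(min(nx, ny))}. Constant \code{x} or \code{y} yields 0.
#' @export
maxGridMI <- function(x, y, nx, ny,
                      exhaustive = c("auto", "always", "never")) {
    mode <- .micMode(exhaustive)
    n <- length(x)
    stopifnot(length(y) == n, nx >= 2, ny >= 2, n >= nx, n >= ny)
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("non-finite values in x or y", call. = FALSE)
    if (mode == 1L && n > 20L && !(nx == 2L && ny == 2L && n <= 200L))
        stop("exhaustive cut enumeration is limited to n <= 20 ",
             "(2x2 grids: n <= 200)", call. = FALSE)
    cpp_max_grid_mi(as.numeric(x), as.numeric(y),
                    as.integer(nx), as.integer(ny), mode)
}

#' Maximal information coefficient of two paired samples
#'
#' \deqn{MIC = \max \{ I(x, y) / \log_2 \min(n_x, n_y) \}} over all
#' admissible grid shapes (see [admissibleGridShapes()]). MIC lies in
#' [0, 1], is symmetric in its arguments, and — because all partitions are
#' rank-based — is invariant under strictly monotone transforms of either
#' axis. A sample constant on either axis scores exactly 0.
#'
#' The smallest supported n is 11: below that, \eqn{B(n) = n^{0.6} \le 4}
#' and no 2x2 grid is admissible.
#'
#' @inheritParams maxGridMI
#' @return MIC in [0, 1].
#' @examples
#' x <- seq_len(63)
#' micScore(x, x)          # 1: noiseless functional relationship
#' micScore(x, rep(2, 63)) # 0: constant axis
#' @seealso [micOracle()] for the brute-force verification oracle.
#' @export
micScore <- function(x, y, exhaustive = c("auto", "always", "never")) {
    mode <- .micMode(exhaustive)
    n <- length(x)
    stopifnot(length(y) == n)
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("non-finite values in x or y", call. = FALSE)
    if (n < 11L)
        stop(sprintf(
            "n = %d is too small: the grid budget B(n) = n^0.6 = %.3f admits no 2x2 grid (need n >= 11)",
            n, n^0.6), call. = FALSE)
    if (mode == 1L && n > 20L)
        stop("exhaustive mode is limited to n <= 20", call. = FALSE)
    cpp_mic_score(as.numeric(x), as.numeric(y), mode)
}

#' Brute-force MIC oracle
#'
#' Independent reference implementation of [micScore()] used for
#' verification: for every admissible grid shape it enumerates \emph{every}
#' placement of the \code{nx - 1} and \code{ny - 1} cut points between
#' distinct consecutive order statistics, evaluating each grid with
#' [gridMutualInformation()] on a plain contingency table. Deliberately
#' shares no code with the search used by [micScore()].
#'
#' @inheritParams maxGridMI
#' @return MIC in [0, 1].
#' @note Combinatorial: refused for n > 20.
#' @export
micOracle <- function(x, y) {
    n <- length(x)
    stopifnot(length(y) == n)
    if (n > 20L) stop("micOracle is refused for n > 20", call. = FALSE)
    if (n < 11L)
        stop("n >= 11 required (no admissible 2x2 grid below)", call. = FALSE)
    shapes <- admissibleGridShapes(n)
    cutsBetweenDistinct <- function(v) {
        s <- sort(v)
        # cut value between each pair of distinct consecutive order stats
        w <- which(diff(s) > 0)
        (s[w] + s[w + 1L]) / 2
    }
    cx <- cutsBetweenDistinct(x)
    cy <- cutsBetweenDistinct(y)
    best <- 0
    for (r in seq_len(nrow(shapes))) {
        nx <- shapes[r, 1L]
        ny <- shapes[r, 2L]
        if (length(cx) < nx - 1L || length(cy) < ny - 1L) next
        xcuts <- combn(cx, nx - 1L, simplify = FALSE)
        ycuts <- combn(cy, ny - 1L, simplify = FALSE)
        denom <- log2(min(nx, ny))
        for (a in xcuts) {
            xb <- findInterval(x, a)
            for (b in ycuts) {
                yb <- findInterval(y, b)
                I <- gridMutualInformation(
                    table(factor(xb, levels = 0:(nx - 1L)),
                          factor(yb, levels = 0:(ny - 1L))))
                if (I / denom > best) best <- I / denom
            }
        }
    }
    min(best, 1)
}

#' @describeIn micProfile Per-locus MIC between the blood and cancer
#'   copy-number columns of a cohort. Deterministic; permuting patients
#'   leaves the profile unchanged.
#' @param exhaustive search mode passed to the per-locus score; see
#'   [micScore()].
#' @export
setMethod("micProfile", "PairedCohort", function(cohort,
        exhaustive = c("auto", "always", "never")) {
    mode <- .micMode(exhaustive)
    n <- nrow(cohort@cancer)
    if (n < 11L)
        stop("micProfile requires at least 11 patients (B(n) budget)",
             call. = FALSE)
    if (mode == 1L && n > 20L)
        stop("exhaustive mode is limited to n <= 20", call. = FALSE)
    scores <- cpp_mic_profile(cohort@blood, cohort@cancer, mode)
    new("MICProfile", chromosome = cohort@chromosome,
        scores = as.numeric(scores), n = as.integer(n))
})

#' Write a MIC profile as a two-column TSV
#'
#' @param profile a [MICProfile-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMICProfile <- function(profile, path) {
    stopifnot(is(profile, "MICProfile"))
    df <- data.frame(locus_index = seq_along(profile@scores),
                     mic = profile@scores)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
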