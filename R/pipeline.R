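#' Run the per-chromosome MIC / feature-selection / clustering pipeline
#'
#' For every chromosome: compute the per-locus MIC profile, build the
#' entire-feature-set (EFS) configuration plus one reduced configuration
#' per fixed threshold (and, optionally, a threshold learned jointly across
#' chromosomes), cluster the 2n unlabeled samples under every configuration
#' with the requested algorithm(s), and score each clustering against the
#' held-out labels. Chromosomes are processed independently (no
#' cross-chromosome pooling, matching the per-chromosome analysis design);
#' a failure in one chromosome is logged and skipped without aborting the
#' run. A chromosome with no locus above a fixed threshold is reported as
#' not clustered for that configuration (a zero block in the report), not
#' as an error.
#'
#' @param cohorts one of: a named list of [PairedCohort-class] objects, a
#'   [simulationConfig()] (the cohorts are generated), or a directory
#'   containing per-chromosome \code{chr<k>.tsv} files in the interleaved
#'   layout.
#' @param thresholds numeric vector of fixed MIC thresholds (default
#'   \code{c(0.65, 0.52)}).
#' @param learnGamma also include a configuration whose threshold is
#'   learned across all chromosomes with [learnThreshold()].
#' @param minLoci minimum loci per chromosome for the learned threshold.
#' @param algorithms subset of \code{c("kernel-kmeans", "kmeans",
#'   "fuzzy-cmeans")}.
#' @param kernel \code{"rbf"} or \code{"linear"} (kernel K-means only).
#' @param bandwidth RBF bandwidth (\code{"median"} or a positive number).
#' @param restarts clustering restarts.
#' @param seed integer master seed; every stage derives its randomness
#'   from it, so reruns are identical.
#' @param epsilon convergence tolerance passed to the clusterers.
#' @param exhaustive MIC search mode, see [micScore()].
#' @param outDir optional output directory; when given, MIC profiles,
#'   selections, assignments and the two report tables are written as TSV
#'   with a \code{#} provenance header.
#' @return list with \code{records} (long evaluation data.frame),
#'   \code{reports} (one wide report per algorithm, see [buildReport()]),
#'   \code{improvement} (ranking table for the first algorithm, when
#'   available), \code{profiles}, \code{selections}, \code{assignments},
#'   and \code{gammaLearned} (NA unless \code{learnGamma}).
#' @export
runPipeline <- function(cohorts, thresholds = c(0.65, 0.52),
                        learnGamma = FALSE, minLoci = 2L,
                        algorithms = "kernel-kmeans",
                        kernel = c("rbf", "linear"), bandwidth = "median",
                        restarts = 10L, seed, epsilon = 1e-6,
                        exhaustive = c("auto", "always", "never"),
                        outDir = NULL) {
    kernel <- match.arg(kernel)
    exhaustive <- match.arg(exhaustive)
    algorithms <- match.arg(algorithms,
        c("kernel-kmeans", "kmeans", "fuzzy-cmeans"), several.ok = TRUE)
    if (missing(seed)) stop("a seed is required", call. = FALSE)
    seed <- as.integer(seed)

    if (is(cohorts, "SimulationConfig"))
        cohorts <- generateCohort(cohorts)$cohorts
    if (is.character(cohorts) && length(cohorts) == 1L) {
        files <- sort(list.files(cohorts, pattern = "^chr.*\\.(tsv|csv)$",
                                 full.names = TRUE))
        if (!length(files))
            stop("no chr*.tsv files found in ", cohorts, call. = FALSE)
        cohorts <- lapply(files, readCohort)
        names(cohorts) <- vapply(cohorts, chromosome, character(1L))
    }
    stopifnot(length(cohorts) >= 1L)
    if (is.null(names(cohorts)))
        names(cohorts) <- vapply(cohorts, chromosome, character(1L))

    log <- function(...) message("[micnv] ", sprintf(...))

    # stage 1: MIC profiles (per-chromosome isolation)
    profiles <- list()
    for (id in names(cohorts)) {
        t0 <- proc.time()[["elapsed"]]
        profiles[[id]] <- tryCatch(
            micProfile(cohorts[[id]], exhaustive = exhaustive),
            error = function(e) {
                log("chromosome %s: MIC stage failed (%s); skipping",
                    id, conditionMessage(e))
                NULL
            })
        if (!is.null(profiles[[id]]))
            log("chromosome %s: MIC profile over %d loci (%.2fs)", id,
                nLoci(profiles[[id]]), proc.time()[["elapsed"]] - t0)
    }
    profiles <- Filter(Negate(is.null), profiles)
    if (!length(profiles)) stop("all chromosomes failed", call. = FALSE)

    configs <- c(list(list(name = "EFS", gamma = NA_real_)),
                 lapply(thresholds, function(g)
                     list(name = sprintf("MIC>%.2f", g), gamma = g)))
    gammaLearned <- NA_real_
    if (learnGamma) {
        gammaLearned <- learnThreshold(profiles, minLoci = minLoci)
        log("learned threshold across %d chromosome(s): %.2f",
            length(profiles), gammaLearned)
        configs <- c(configs,
                     list(list(name = "learned", gamma = gammaLearned)))
    }

    clusterOnce <- function(algo, vals, runSeed) {
        switch(algo,
            "kernel-kmeans" = {
                kern <- if (kernel == "rbf") rbfKernel(vals, bandwidth)
                        else linearKernel(vals)
                kernelKMeans(kern, K = 2L, seed = runSeed,
                             epsilon = epsilon, restarts = restarts)
            },
            "kmeans" = lloydKMeans(vals, K = 2L, seed = runSeed,
                                   epsilon = epsilon, restarts = restarts),
            "fuzzy-cmeans" = fuzzyCMeans(vals, K = 2L, seed = runSeed,
                                         epsilon = epsilon))
    }

    records <- list()
    selections <- list()
    assignments <- list()
    for (ci in seq_along(profiles)) {
        id <- names(profiles)[ci]
        unl <- toUnlabeled(cohorts[[id]])
        for (gi in seq_along(configs)) {
            cfg <- configs[[gi]]
            if (is.na(cfg$gamma)) {
                sel <- NULL
                vals <- unl
                v <- nLoci(profiles[[id]])
            } else {
                sel <- selectLoci(profiles[[id]], cfg$gamma)
                selections[[paste(id, cfg$name)]] <- sel
                v <- nSelected(sel)
                if (v == 0L) {
                    log("chromosome %s: no locus with MIC > %.2f; reported as not clustered",
                        id, cfg$gamma)
                    for (algo in algorithms)
                        records[[length(records) + 1L]] <- cbind(
                            evaluationRecord(id, cfg$name, 0L),
                            algorithm = algo)
                    next
                }
                vals <- reduceMatrix(unl, sel)
            }
            for (ai in seq_along(algorithms)) {
                algo <- algorithms[ai]
                runSeed <- seed + 1000L * ci + 10L * gi + ai
                res <- tryCatch(clusterOnce(algo, vals, runSeed),
                    error = function(e) {
                        log("chromosome %s / %s / %s failed: %s", id,
                            cfg$name, algo, conditionMessage(e))
                        NULL
                    })
                if (is.null(res)) next
                assignments[[paste(id, cfg$name, algo)]] <- res
                records[[length(records) + 1L]] <- cbind(
                    evaluationRecord(id, cfg$name, v,
                                     nmi = nmiScore(res, trueLabels(unl)),
                                     tr = trueRate(res, trueLabels(unl))),
                    algorithm = algo)
            }
        }
    }
    records <- do.call(rbind, records)

    rfsName <- if (length(thresholds))
        sprintf("MIC>%.2f", thresholds[length(thresholds)])
    else if (learnGamma) "learned" else "EFS"
    reports <- lapply(algorithms, function(algo)
        buildReport(records[records$algorithm == algo,
                            setdiff(names(records), "algorithm")],
                    rfsConfiguration = rfsName))
    names(reports) <- algorithms
    improvement <- tryCatch(
        improvementTable(records[records$algorithm == algorithms[1L],
                                 setdiff(names(records), "algorithm")],
                         rfsConfiguration = rfsName),
        error = function(e) NULL)

    out <- list(records = records, reports = reports,
                improvement = improvement, profiles = profiles,
                selections = selections, assignments = assignments,
                gammaLearned = gammaLearned, seed = seed)
    if (!is.null(outDir)) .writeArtifacts(out, cohorts, outDir,
                                          thresholds, algorithms)
    out
}

# TSV artifacts with a '#'-prefixed provenance header
.writeArtifacts <- function(out, cohorts, outDir, thresholds, algorithms) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    header <- sprintf(
        "# micnv run: seed=%d thresholds=%s algorithms=%s",
        out$seed, paste(thresholds, collapse = ","),
        paste(algorithms, collapse = ","))
    writeTSV <- function(df, file) {
        path <- file.path(outDir, file)
        con <- file(path, "w")
        writeLines(header, con)
        close(con)
        suppressWarnings(
            write.table(df, path, sep = "\t", quote = FALSE,
                        row.names = FALSE, append = TRUE))
        path
    }
    for (id in names(out$profiles))
        writeMICProfile(out$profiles[[id]],
                        file.path(outDir, sprintf("mic_chr%s.tsv", id)))
    if (length(out$selections))
        writeSelections(out$selections, file.path(outDir, "selections.tsv"))
    for (nm in names(out$assignments)) {
        id <- strsplit(nm, " ")[[1L]][1L]
        writeAssignment(out$assignments[[nm]],
                        sampleIDs(toUnlabeled(cohorts[[id]])),
                        file.path(outDir, sprintf("assignment_%s.tsv",
                                                  gsub("[^0-9A-Za-z._-]+", "_", nm))))
    }
    for (algo in names(out$reports))
        writeTSV(out$reports[[algo]],
                 sprintf("report_%s.tsv", gsub("[^0-9A-Za-z._-]+", "_", algo)))
    if (!is.null(out$improvement))
        writeTSV(out$improvement, "improvement.tsv")
    invisible(outDir)
}
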