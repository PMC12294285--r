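## Top-level pipeline: simulate -> quantify -> analyze, with a run manifest.

#' Derive a per-stage child seed from the global seed
#'
#' One global seed fans out deterministically to named stages, so a stage can
#' be rerun alone and reproduce its in-pipeline draws. The derivation is a
#' fixed integer hash of the stage name folded into the seed, kept within the
#' 32-bit integer range.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer child seed.
#' @export
childSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
    as.integer((as.numeric(seed) * 48271 + h * 1000003) %% 2147483647)
}

#' Run the full simulate / quantify / analyze pipeline
#'
#' Simulates a cohort under \code{config}, writes the cohort TSV, re-validates
#' and re-quantifies the band profiles from the written file (so the analysis
#' stage consumes exactly what a user would load), rebuilds both published
#' result tables, renders the group box plots for mC and uCmC, and writes a
#' JSON run manifest. Any stage failure aborts with the stage name; reruns
#' with the same config and seed reproduce identical outputs.
#'
#' @param config A [CohortConfig-class].
#' @param seed Global integer seed.
#' @param outDir Output directory (created if absent).
#' @return The manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config = defaultCohortConfig(), seed = 1L,
                        outDir = ".") {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    cohortPath <- file.path(outDir, "cohort.tsv")
    coh <- stage("simulate", {
        coh <- sampleCohort(config, seed = childSeed(seed, "simulate"))
        writeCohort(coh, cohortPath)
        coh
    })
    tab <- stage("quantify", {
        tab <- validateCohortTable(cohortPath)
        est <- quantifyBands(tab[, c("pct_160", "pct_98", "pct_80", "pct_62")],
                             config@effectiveLengths)
        tab[, names(est)] <- est
        tab
    })
    stage("analyze", {
        t1 <- buildTable1(tab)
        t2 <- buildTable2(tab)
        write.table(t1, file.path(outDir, "table1.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(t2, file.path(outDir, "table2.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        plotGroupBoxes(tab, "mC", file.path(outDir, "boxplot_mC.png"))
        plotGroupBoxes(tab, "uCmC", file.path(outDir, "boxplot_uCmC.png"))
    })
    manifest <- stage("manifest", {
        cfgJson <- jsonlite::toJSON(list(
            nPatients = config@nPatients, nControls = config@nControls,
            sexRatio = config@sexRatio, noiseCV = config@noiseCV,
            effectiveLengths = config@effectiveLengths,
            latentCorrelation = config@latentCorrelation),
            digits = NA, auto_unbox = TRUE)
        tmp <- tempfile(); writeLines(cfgJson, tmp)
        m <- list(
            seed = seed,
            config_digest = unname(tools::md5sum(tmp)),
            package_version = as.character(utils::packageVersion("cobraline")),
            outputs = c("cohort.tsv", "table1.tsv", "table2.tsv",
                        "boxplot_mC.png", "boxplot_uCmC.png"),
            rows = list(cohort = nrow(tab),
                        table1 = nrow(buildTable1(tab)),
                        table2 = nrow(buildTable2(tab))))
        unlink(tmp)
        jsonlite::write_json(m, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        m
    })
    invisible(manifest)
}
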