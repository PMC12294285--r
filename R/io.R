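## TSV schemas and validation. All writers emit tab-separated UTF-8 with a
## header row and full-precision numbers; display rounding happens only in
## rendered tables.

cohortNumericCols <- c("age", "age_at_diagnosis", "duration", "sbp", "dbp",
                       "bmi", "glucose", "hba1c",
                       "f_mCmC", "f_uCmC", "f_mCuC", "f_uCuC",
                       "pct_160", "pct_98", "pct_80", "pct_62",
                       "mC", "mCmC", "uCmC", "mCuC", "uCuC")

#' Write a cohort table to TSV
#'
#' @param cohort A [CobraCohort-class] or subject data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(cohort, path) {
    tab <- if (methods::is(cohort, "CobraCohort")) subjectData(cohort) else cohort
    num <- intersect(cohortNumericCols, names(tab))
    tab[num] <- lapply(tab[num], function(x)
        ifelse(is.na(x), "NA", sprintf("%.17g", x)))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a cohort table from TSV
#'
#' @param path TSV written by [writeCohort()] (or matching its schema).
#' @return Subject data.frame.
#' @export
readCohort <- function(path) {
    validateCohortTable(path)
}

#' Read and validate a cohort TSV
#'
#' Schema-checks a cohort table: required columns present, rows not ragged,
#' group labels valid, band intensities nonnegative, pattern percentages
#' summing to ~100. Errors name the offending column or row.
#'
#' @param path TSV path.
#' @return The validated subject data.frame.
#' @export
validateCohortTable <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
    if (length(unique(nfield[nzchar(lines)])) > 1L)
        stop("ragged TSV: rows have differing field counts (first at line ",
             which(nfield != nfield[1])[1], ")")
    tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("subject_id", "group", "age", "sex", "glucose", "hba1c",
              "pct_160", "pct_98", "pct_80", "pct_62",
              "mC", "mCmC", "uCmC", "mCuC", "uCuC")
    missing <- setdiff(need, names(tab))
    if (length(missing))
        stop("missing column(s): ", paste(missing, collapse = ", "))
    if (!nrow(tab)) return(tab)
    badGroup <- which(!tab$group %in% c("patient", "control"))
    if (length(badGroup))
        stop("row ", badGroup[1], ": bad group label '",
             tab$group[badGroup[1]], "'")
    bands <- as.matrix(tab[, c("pct_160", "pct_98", "pct_80", "pct_62")])
    badBand <- which(apply(bands, 1L, function(r) any(!is.finite(r) | r < 0)))
    if (length(badBand))
        stop("row ", badBand[1], ": negative or non-finite band intensity")
    psum <- tab$mCmC + tab$uCmC + tab$mCuC + tab$uCuC
    badSum <- which(abs(psum - 100) > 0.5)
    if (length(badSum))
        stop("row ", badSum[1], ": pattern percentages sum to ",
             round(psum[badSum[1]], 2), ", expected ~100")
    tab
}
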