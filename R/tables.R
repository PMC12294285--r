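## Published-style result tables rebuilt from a cohort table.

#' Rebuild the subject-characteristics / methylation comparison table
#'
#' One row per variable in the published order: age, sex, systolic and
#' diastolic blood pressure, BMI, fasting glucose, HbA1c, then total
#' methylation mC and the four pattern percentages. Continuous rows carry the
#' per-group median (IQR) and the Mann-Whitney p-value; the sex row a
#' chi-squared test. Duplicate variable requests are collapsed.
#'
#' @param table A [CobraCohort-class] or subject data.frame.
#' @param variables Row variables, defaulting to the published set present in
#'   the table.
#' @return Data.frame of group comparisons (see [compareGroups()]).
#' @export
buildTable1 <- function(table,
                        variables = c("age", "sex", "sbp", "dbp", "bmi",
                                      "glucose", "hba1c",
                                      "mC", "mCmC", "uCmC", "mCuC", "uCuC")) {
    tab <- asSubjects(table)
    if (!any(tab$group == "patient") || !any(tab$group == "control"))
        stop("both groups must be nonempty")
    variables <- unique(variables)
    missing <- setdiff(variables, names(tab))
    if (length(missing))
        stop("missing columns: ", paste(missing, collapse = ", "))
    out <- do.call(rbind, lapply(variables, function(v) compareGroups(tab, v)))
    rownames(out) <- NULL
    out
}

#' Rebuild the methylation-correlates table
#'
#' Spearman correlations of each methylation measure (mC and the four
#' patterns) against subject characteristics, in the published row order. Age,
#' sex, fasting glucose and HbA1c are correlated across the pooled cohort;
#' age at diagnosis and disease duration within patients only (they exist only
#' there). Sex is coded as an indicator for female.
#'
#' @param table A [CobraCohort-class] or subject data.frame.
#' @param methylationVars Correlate columns.
#' @return Long data.frame of correlation rows (see [correlate()]).
#' @export
buildTable2 <- function(table,
                        methylationVars = c("mC", "mCuC", "uCmC",
                                            "uCuC", "mCmC")) {
    tab <- asSubjects(table)
    tab$sex_female <- as.numeric(tab$sex == "female")
    rows <- data.frame(
        variable = c("age", "age_at_diagnosis", "sex_female", "duration",
                     "glucose", "hba1c"),
        subset = c("all", "patients", "all", "patients", "all", "all"))
    out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
        do.call(rbind, lapply(methylationVars, function(m) {
            correlate(tab, rows$variable[i], m, subset = rows$subset[i])
        }))
    }))
    rownames(out) <- NULL
    out
}
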