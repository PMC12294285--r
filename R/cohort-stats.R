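## Nonparametric case-control battery: normality gate, Mann-Whitney /
## chi-squared group comparisons, Spearman correlations, published-style
## summary tables and a power-by-simulation utility. Two-sided tests
## throughout; no multiple-testing correction is applied (matching the
## original analysis; see the vignette for the caveat).

asSubjects <- function(x) {
    if (methods::is(x, "CobraCohort")) subjectData(x)
    else if (is.data.frame(x)) x
    else stop("expected a CobraCohort or a subject data.frame")
}

#' Median and interquartile range
#'
#' Empirical 25th/50th/75th percentiles with linear interpolation
#' (\code{quantile} type 7), the summary used for all non-normal variables.
#'
#' @param values Numeric vector (NAs dropped).
#' @return Named numeric vector \code{c(median, q1, q3)}.
#' @examples
#' summarizeMedianIQR(c(1, 2, 3, 4, 5))  # 3, 2, 4
#' @export
summarizeMedianIQR <- function(values) {
    values <- values[is.finite(values)]
    if (!length(values)) stop("no finite values to summarize")
    q <- quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
    c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Shapiro-Wilk normality gate
#'
#' Flags, per variable, whether the Shapiro-Wilk test rejects normality at
#' \code{alpha}. The pipeline reports the gate but always proceeds
#' nonparametrically, as the original analysis did.
#'
#' @param table A [CobraCohort-class] or subject data.frame.
#' @param variables Variables to test.
#' @param alpha Significance level of the gate.
#' @return Data.frame with columns \code{variable}, \code{W}, \code{p_value},
#'   \code{normal}.
#' @export
normalityGate <- function(table, variables, alpha = 0.05) {
    tab <- asSubjects(table)
    res <- lapply(variables, function(v) {
        x <- tab[[v]][is.finite(tab[[v]])]
        sw <- shapiro.test(x)
        data.frame(variable = v, W = unname(sw$statistic),
                   p_value = sw$p.value, normal = sw$p.value >= alpha)
    })
    do.call(rbind, res)
}

#' Compare a variable between patients and controls
#'
#' Continuous variables: two-sided Mann-Whitney U test, by default with the
#' tie-corrected normal approximation (\code{method = "exact"} switches to the
#' exact null distribution, available without ties, for small-sample
#' cross-checks). The reported statistic is U for patients vs controls.
#' Categorical variables: Pearson chi-squared on the group-by-level
#' contingency table (no continuity correction); a variable with a single
#' observed level yields statistic 0 and p = 1.
#'
#' @param table A [CobraCohort-class] or subject data.frame with a
#'   \code{group} column.
#' @param variable Column to compare.
#' @param type \code{"continuous"} or \code{"categorical"} (guessed from the
#'   column type by default).
#' @param method P-value method for the Mann-Whitney test.
#' @return A one-row data.frame: \code{variable},
#'   \code{median_iqr_patients}, \code{median_iqr_controls}, \code{test},
#'   \code{statistic}, \code{p_value}.
#' @export
compareGroups <- function(table, variable,
                          type = c("auto", "continuous", "categorical"),
                          method = c("normal", "exact")) {
    tab <- asSubjects(table)
    type <- match.arg(type)
    method <- match.arg(method)
    x <- tab[[variable]]
    if (is.null(x)) stop("no column '", variable, "'")
    g <- tab$group
    if (!any(g == "patient") || !any(g == "control"))
        stop("both groups must be nonempty")
    if (type == "auto")
        type <- if (is.numeric(x)) "continuous" else "categorical"
    fmt <- function(q) sprintf("%.1f (%.1f-%.1f)", q[1], q[2], q[3])
    if (type == "continuous") {
        xp <- x[g == "patient"]; xc <- x[g == "control"]
        ht <- suppressWarnings(wilcox.test(xp, xc, exact = method == "exact",
                                           correct = method == "normal"))
        data.frame(variable = variable,
                   median_iqr_patients = fmt(summarizeMedianIQR(xp)),
                   median_iqr_controls = fmt(summarizeMedianIQR(xc)),
                   test = "mann-whitney",
                   statistic = unname(ht$statistic), p_value = ht$p.value)
    } else {
        keep <- !is.na(x)
        ct <- table(factor(g[keep], levels = c("patient", "control")), x[keep])
        if (ncol(ct) < 2L) {
            stat <- 0; p <- 1
        } else {
            ht <- suppressWarnings(chisq.test(ct, correct = FALSE))
            stat <- unname(ht$statistic); p <- ht$p.value
        }
        pctLevel <- function(gr) {
            xs <- x[keep & g == gr]
            paste(sprintf("%s %.1f%%", names(table(xs)),
                          100 * prop.table(table(xs))), collapse = "/")
        }
        data.frame(variable = variable,
                   median_iqr_patients = pctLevel("patient"),
                   median_iqr_controls = pctLevel("control"),
                   test = "chi-squared", statistic = stat, p_value = p)
    }
}

#' Spearman rank correlation between two variables
#'
#' Spearman's rho with average ranks for ties and the t-approximation
#' p-value, on all subjects or one group.
#'
#' @param table A [CobraCohort-class] or subject data.frame.
#' @param varX,varY Column names.
#' @param subset \code{"all"}, \code{"patients"} or \code{"controls"}.
#' @return One-row data.frame: \code{var_x}, \code{var_y}, \code{subset},
#'   \code{n}, \code{rho}, \code{p_value}.
#' @export
correlate <- function(table, varX, varY,
                      subset = c("all", "patients", "controls")) {
    tab <- asSubjects(table)
    subset <- match.arg(subset)
    if (subset != "all")
        tab <- tab[tab$group == sub("s$", "", subset), ]
    x <- tab[[varX]]; y <- tab[[varY]]
    if (is.character(x) || is.factor(x)) x <- as.numeric(factor(x))
    if (is.character(y) || is.factor(y)) y <- as.numeric(factor(y))
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) stop("need at least 3 paired finite observations")
    if (sd(x) == 0 || sd(y) == 0)
        stop("Spearman correlation undefined for a constant variable")
    ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    data.frame(var_x = varX, var_y = varY, subset = subset, n = length(x),
               rho = unname(ht$estimate), p_value = ht$p.value)
}

#' Monte-Carlo power of the two-group comparison
#'
#' Simulates two normal groups, \code{N(0, sd)} vs \code{N(delta, sd)}, and
#' reports the proportion of replicates in which the group test rejects at
#' \code{alpha}. The default rejection test is the Mann-Whitney U test (the
#' design's test); \code{test = "t"} uses Welch's t-test for comparison with
#' the closed-form normal-theory power.
#'
#' @param nPerGroup Subjects per group.
#' @param delta True group difference (percentage points).
#' @param sd Common standard deviation.
#' @param alpha Significance level.
#' @param nReplicates Monte-Carlo replicates.
#' @param seed Seed.
#' @param test \code{"mann-whitney"} or \code{"t"}.
#' @return One-row data.frame: \code{n_per_group}, \code{delta}, \code{sd},
#'   \code{alpha}, \code{power}, \code{n_replicates}, \code{test}.
#' @examples
#' estimatePower(25, delta = 1, sd = 1.8, nReplicates = 500, seed = 1)
#' @export
estimatePower <- function(nPerGroup, delta, sd, alpha = 0.05,
                          nReplicates = 2000L, seed = 1L,
                          test = c("mann-whitney", "t")) {
    stopifnot(nPerGroup >= 2, sd > 0, alpha > 0, alpha < 1, nReplicates >= 1)
    test <- match.arg(test)
    set.seed(as.integer(seed))
    reject <- vapply(seq_len(nReplicates), function(i) {
        x <- rnorm(nPerGroup, 0, sd)
        y <- rnorm(nPerGroup, delta, sd)
        p <- if (test == "mann-whitney")
            suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
        else t.test(x, y)$p.value
        p < alpha
    }, logical(1))
    data.frame(n_per_group = nPerGroup, delta = delta, sd = sd, alpha = alpha,
               power = mean(reject), n_replicates = nReplicates, test = test)
}

#' Group box plot of a variable
#'
#' Patient/control box plots drawn the way the study figure defines them: the
#' box spans the interquartile range, the line marks the median, and the
#' whiskers extend to the minimum and maximum (not 1.5 IQR).
#'
#' @param table A [CobraCohort-class] or subject data.frame.
#' @param variable Column to plot.
#' @param path Output file (extension selects the device, e.g. .png, .svg,
#'   .pdf). If \code{NULL}, the ggplot object is returned unrendered.
#' @param width,height Device size in inches.
#' @return The plot object, invisibly if written to \code{path}.
#' @export
plotGroupBoxes <- function(table, variable, path = NULL,
                           width = 4, height = 4) {
    tab <- asSubjects(table)
    grp <- factor(tab$group, levels = c("patient", "control"),
                  labels = c("T1D patients", "Controls"))
    x <- tab[[variable]]
    ## five-number summary per group, whiskers at the observed extremes
    stats <- do.call(rbind, lapply(levels(grp), function(g) {
        v <- x[grp == g & is.finite(x)]
        q <- summarizeMedianIQR(v)
        data.frame(group = g, ymin = min(v), lower = q["q1"],
                   middle = q["median"], upper = q["q3"], ymax = max(v))
    }))
    stats$group <- factor(stats$group, levels = levels(grp))
    p <- ggplot2::ggplot(stats,
            ggplot2::aes(x = group, ymin = ymin, lower = lower,
                         middle = middle, upper = upper, ymax = ymax)) +
        ggplot2::geom_boxplot(stat = "identity", fill = "grey85",
                              width = 0.5) +
        ggplot2::labs(x = NULL, y = paste0(variable, " (%)")) +
        ggplot2::theme_classic()
    if (is.null(path)) return(p)
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
    invisible(p)
}
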