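test_that("median/IQR summary uses interpolated percentiles", {
    expect_equal(unname(summarizeMedianIQR(c(1, 2, 3, 4, 5))), c(3, 2, 4))
    expect_equal(unname(summarizeMedianIQR(5)), c(5, 5, 5))
    s <- summarizeMedianIQR(c(1, 1, 1, 100))
    expect_equal(unname(s["median"]), 1)
    expect_equal(unname(s), unname(quantile(c(1, 1, 1, 100), c(.5, .25, .75))))
    expect_error(summarizeMedianIQR(numeric()), "finite")
})

test_that("group comparison handles identical, separated and constant inputs", {
    tab <- data.frame(
        group = rep(c("patient", "control"), each = 10),
        val = rep(1:10, 2),
        sep = c(11:20, 1:10),
        cat = rep("x", 20))
    same <- compareGroups(tab, "val")
    expect_equal(same$p_value, 1, tolerance = 0.05)
    expect_equal(same$statistic, 50)  # U at its null mean n1*n2/2
    sep <- compareGroups(tab, "sep")
    expect_equal(sep$statistic, 100)  # complete separation: U = n1*n2
    expect_lt(sep$p_value, 0.001)
    con <- compareGroups(tab, "cat")
    expect_identical(con$test, "chi-squared")
    expect_equal(con$statistic, 0)
    expect_equal(con$p_value, 1)
    expect_error(compareGroups(tab[tab$group == "patient", ], "val"),
                 "nonempty")
})

test_that("exact Mann-Whitney p-values match complete enumeration", {
    set.seed(21)
    for (i in 1:5) {
        x <- round(rnorm(6, 0, 4), 2)
        y <- round(rnorm(7, 1, 4), 2)
        tab <- data.frame(group = rep(c("patient", "control"), c(6, 7)),
                          v = c(x, y))
        pExact <- compareGroups(tab, "v", method = "exact")$p_value
        pEnum <- enumerateMannWhitneyP(x, y)
        expect_equal(pExact, pEnum, tolerance = 1e-10)
        ## the tie-corrected normal approximation agrees to modest tolerance
        pNorm <- compareGroups(tab, "v", method = "normal")$p_value
        expect_equal(pNorm, pEnum, tolerance = 0.06)
    }
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
    set.seed(8)
    tab <- data.frame(group = rep(c("patient", "control"), c(15, 12)),
                      v = c(rnorm(15, 1), rnorm(12)))
    p0 <- compareGroups(tab, "v")$p_value
    tab$v <- exp(tab$v)
    expect_equal(compareGroups(tab, "v")$p_value, p0, tolerance = 1e-12)
})

test_that("Spearman correlation matches the rank formula and is monotone-invariant", {
    tab <- data.frame(group = "patient", x = 1:4, y = c(1, 2, 4, 3))
    r <- correlate(tab, "x", "y")
    expect_equal(r$rho, 0.8)               # 1 - 6*2/(4*15)
    tab$y2 <- tab$x
    expect_equal(correlate(tab, "x", "y2")$rho, 1)
    tab$y3 <- -tab$x
    expect_equal(correlate(tab, "x", "y3")$rho, -1)
    expect_error(correlate(tab, "x", "group"), "constant")
    set.seed(13)
    big <- data.frame(group = "patient", x = rnorm(40), y = rnorm(40))
    r0 <- correlate(big, "x", "y")
    big$x <- qlogis(pnorm(big$x)); big$y <- big$y^3
    r1 <- correlate(big, "x", "y")
    expect_equal(r1$rho, r0$rho, tolerance = 1e-12)
    expect_equal(r1$p_value, r0$p_value, tolerance = 1e-12)
})

test_that("result tables have the published row structure", {
    coh <- sampleCohort(smallCohortConfig(), seed = 2)
    t1 <- buildTable1(coh)
    expect_identical(nrow(t1), 12L)
    expect_identical(t1$variable,
                     c("age", "sex", "sbp", "dbp", "bmi", "glucose", "hba1c",
                       "mC", "mCmC", "uCmC", "mCuC", "uCuC"))
    expect_identical(t1$test[t1$variable == "sex"], "chi-squared")
    expect_true(all(t1$p_value >= 0 & t1$p_value <= 1))
    ## duplicate variable requests collapse to one row
    expect_identical(nrow(buildTable1(coh, variables = c("mC", "mC"))), 1L)
    ## a cohort with one group only is refused
    solo <- subjectData(coh)
    expect_error(buildTable1(solo[solo$group == "control", ]), "nonempty")
    t2 <- buildTable2(coh)
    expect_identical(nrow(t2), 30L)
    expect_identical(unique(t2$subset[t2$var_x == "duration"]), "patients")
    expect_identical(unique(t2$subset[t2$var_x == "glucose"]), "all")
    expect_true(all(t2$n[t2$subset == "patients"] == 12L))
    expect_true(all(t2$n[t2$subset == "all"] == 22L))
})

test_that("the normality gate reports Shapiro-Wilk per variable", {
    coh <- sampleCohort(smallCohortConfig(), seed = 6)
    g <- normalityGate(coh, c("mC", "glucose"))
    expect_identical(g$variable, c("mC", "glucose"))
    expect_true(all(g$p_value >= 0 & g$p_value <= 1))
    expect_type(g$normal, "logical")
})

test_that("power simulation is calibrated at the null and monotone in n", {
    p0 <- estimatePower(25, delta = 0, sd = 1.8, nReplicates = 2000, seed = 3)
    expect_lt(abs(p0$power - 0.05), 0.02)
    pSmall <- estimatePower(10, delta = 1, sd = 1.8, nReplicates = 1500, seed = 3)
    pBig <- estimatePower(80, delta = 1, sd = 1.8, nReplicates = 1500, seed = 3)
    expect_gt(pBig$power, pSmall$power)
    ## t-test power tracks the closed-form normal-theory value
    n <- 40; delta <- 1; sd <- 1.8
    analytic <- pnorm(delta * sqrt(n / 2) / sd - qnorm(0.975))
    pt <- estimatePower(n, delta, sd, nReplicates = 4000, seed = 9, test = "t")
    expect_lt(abs(pt$power - analytic), 0.04)
})

test_that("group box plots render with min-max whiskers", {
    coh <- sampleCohort(smallCohortConfig(), seed = 10)
    f <- tempfile(fileext = ".png")
    plotGroupBoxes(coh, "mC", f)
    expect_true(file.exists(f) && file.size(f) > 0)
    ## whiskers span the full range, not 1.5 IQR
    p <- plotGroupBoxes(coh, "mC")
    built <- ggplot2::ggplot_build(p)$data[[1]]
    tab <- subjectData(coh)
    expect_equal(sort(built$ymin),
                 sort(tapply(tab$mC, tab$group, min)), ignore_attr = TRUE)
    expect_equal(sort(built$ymax),
                 sort(tapply(tab$mC, tab$group, max)), ignore_attr = TRUE)
    ## degenerate single-value group still renders
    tiny <- data.frame(group = c("patient", "patient", "control"),
                       mC = c(47, 47, 46))
    f2 <- tempfile(fileext = ".png")
    plotGroupBoxes(tiny, "mC", f2)
    expect_true(file.exists(f2) && file.size(f2) > 0)
})
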