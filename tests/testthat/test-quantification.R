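test_that("length normalization uses the published divisors", {
    ab <- normalizeBands(c(100, 0, 0, 0))
    expect_equal(unname(ab[1, ]), c(100 / 160, 0, 0, 0))
    ab <- normalizeBands(c(0, 0, 0, 100))
    expect_equal(unname(ab[1, "D"]), 100 / 62)
    ## equal-mixture lane: divisors 94 and 78, not the nominal band lengths
    ab <- normalizeBands(c(26.1438, 15.3595, 38.2353, 20.2614))
    expect_equal(unname(ab[1, ]),
                 c(26.1438 / 160, 15.3595 / 94, 38.2353 / 78, 20.2614 / 62),
                 tolerance = 1e-12)
    expect_equal(unname(ab[1, ]), c(0.16340, 0.16340, 0.49020, 0.32680),
                 tolerance = 1e-4)
    expect_error(normalizeBands(c(-1, 50, 30, 21)), "nonnegative")
    expect_error(normalizeBands(c(NA, 50, 30, 21)), "finite")
})

test_that("total methylation is 100(C+A)/(C+2A+B+D) with the pure-lane values", {
    pure <- function(f) forwardBandProfile(f)
    expect_equal(totalMethylation(normalizeBands(pure(
        c(f_mCmC = 1, f_uCmC = 0, f_mCuC = 0, f_uCuC = 0)))), 100)
    expect_equal(totalMethylation(normalizeBands(pure(
        c(f_mCmC = 0, f_uCmC = 0, f_mCuC = 0, f_uCuC = 1)))), 0)
    expect_equal(totalMethylation(normalizeBands(pure(
        c(f_mCmC = 0, f_uCmC = 0, f_mCuC = 1, f_uCuC = 0)))), 50)
    expect_equal(totalMethylation(normalizeBands(pure(
        c(f_mCmC = 0, f_uCmC = 1, f_mCuC = 0, f_uCuC = 0)))), 50)
    expect_error(totalMethylation(c(A = 0, B = 0, C = 0, D = 0)), "zero")
})

test_that("pattern percentages solve the fragment-counting system", {
    ## pure uCuC lane: B = D, A = C = 0
    p <- patternPercentages(normalizeBands(forwardBandProfile(
        c(f_mCmC = 0, f_uCmC = 0, f_mCuC = 0, f_uCuC = 1))))
    expect_equal(unname(p[1, ]), c(0, 0, 0, 100), tolerance = 1e-9)
    ## pure uCmC lane: C = D, A = B = 0
    p <- patternPercentages(normalizeBands(forwardBandProfile(
        c(f_mCmC = 0, f_uCmC = 1, f_mCuC = 0, f_uCuC = 0))))
    expect_equal(unname(p[1, ]), c(0, 100, 0, 0), tolerance = 1e-9)
    ## equal mixture recovers 25/25/25/25
    p <- patternPercentages(normalizeBands(c(26.1438, 15.3595, 38.2353, 20.2614)))
    expect_equal(unname(p[1, ]), c(25, 25, 25, 25), tolerance = 1e-4)
    ## noisy lane outside the simplex is clipped with a warning, still sums to 100
    expect_warning(p <- patternPercentages(
        normalizeBands(c(10, 60, 2, 28))), "clipped")
    expect_equal(sum(p), 100)
    expect_true(all(p >= 0))
    expect_error(patternPercentages(c(A = 0, B = 1, C = -2, D = 1)), "denominator")
})

test_that("quantification matches the published lane examples", {
    est <- quantifyBands(c(100, 0, 0, 0))
    expect_equal(est$mC, 50)
    expect_equal(unlist(est[1, c("mCmC", "uCmC", "mCuC", "uCuC")],
                        use.names = FALSE), c(0, 0, 100, 0))
    ## fully unmethylated lane: bands at 98 and 62 bp weighted 94:62
    pb <- forwardBandProfile(c(f_mCmC = 0, f_uCmC = 0, f_mCuC = 0, f_uCuC = 1))
    expect_equal(unname(pb[1, ]), c(0, 100 * 94 / 156, 0, 100 * 62 / 156),
                 tolerance = 1e-9)
    expect_equal(unname(pb[1, c("pct_98", "pct_62")]), c(60.256, 39.744),
                 tolerance = 1e-4)
    est <- quantifyBands(pb)
    expect_equal(est$mC, 0)
    expect_equal(est$uCuC, 100)
})

test_that("forward model reproduces the hand-computed mixtures", {
    pb <- forwardBandProfile(c(f_mCmC = 0, f_uCmC = 0, f_mCuC = 1, f_uCuC = 0))
    expect_equal(unname(pb[1, ]), c(100, 0, 0, 0))
    pb <- forwardBandProfile(c(f_mCmC = .25, f_uCmC = .25, f_mCuC = .25,
                               f_uCuC = .25))
    expect_equal(unname(pb[1, ]), c(26.1438, 15.3595, 38.2353, 20.2614),
                 tolerance = 1e-4)
    expect_error(forwardBandProfile(c(f_mCmC = .5, f_uCmC = .2, f_mCuC = .2,
                                      f_uCuC = .2)), "sum to 1")
})

test_that("quantify inverts the forward model on a simplex grid", {
    f <- simplexGrid(8)
    est <- quantifyBands(forwardBandProfile(f))
    expect_equal(est$mCmC, 100 * f[, "f_mCmC"], tolerance = 1e-9)
    expect_equal(est$uCmC, 100 * f[, "f_uCmC"], tolerance = 1e-9)
    expect_equal(est$mCuC, 100 * f[, "f_mCuC"], tolerance = 1e-9)
    expect_equal(est$uCuC, 100 * f[, "f_uCuC"], tolerance = 1e-9)
    expect_equal(est$mC,
                 100 * (2 * f[, "f_mCmC"] + f[, "f_uCmC"] + f[, "f_mCuC"]) / 2,
                 tolerance = 1e-9)
})

test_that("pattern percentages always sum to 100 and satisfy the mC identity", {
    lanes <- randomLanes(200, seed = 11)
    est <- suppressWarnings(quantifyBands(lanes))
    expect_equal(rowSums(est[, c("mCmC", "uCmC", "mCuC", "uCuC")]),
                 rep(100, nrow(est)), tolerance = 1e-9)
    ## identity holds whenever no clipping occurred (lane inside the simplex)
    ab <- normalizeBands(lanes)
    inside <- ab[, "C"] - ab[, "D"] + ab[, "B"] >= 0 & ab[, "D"] >= ab[, "B"]
    ident <- (2 * est$mCmC + est$uCmC + est$mCuC) / 2
    expect_equal(est$mC[inside], ident[inside], tolerance = 1e-9)
})

test_that("shifting signal from the 98 bp to the 80 bp band never lowers mC", {
    set.seed(3)
    for (i in 1:30) {
        base <- randomLanes(1, seed = 100 + i)
        shift <- min(base[1, "pct_98"], 10) * runif(1)
        shifted <- base
        shifted[1, "pct_98"] <- base[1, "pct_98"] - shift
        shifted[1, "pct_80"] <- base[1, "pct_80"] + shift
        m0 <- totalMethylation(normalizeBands(base))
        m1 <- totalMethylation(normalizeBands(shifted))
        expect_gte(m1, m0 - 1e-12)
    }
})

test_that("quantification recovers exact proportions from molecule counts", {
    set.seed(5)
    for (i in 1:20) {
        counts <- sample(0:10000, 4)
        if (sum(counts) == 0) counts[1] <- 1
        lane <- moleculeLane(counts[1], counts[2], counts[3], counts[4])
        est <- quantifyBands(lane)
        expect_equal(
            unlist(est[1, c("mCmC", "uCmC", "mCuC", "uCuC")], use.names = FALSE),
            100 * counts / sum(counts), tolerance = 1e-9)
    }
})

test_that("nominal band lengths can be substituted to study the induced bias", {
    eff <- c(`160` = 160, `98` = 98, `80` = 80, `62` = 62)
    f <- c(f_mCmC = .25, f_uCmC = .25, f_mCuC = .25, f_uCuC = .25)
    est <- quantifyBands(forwardBandProfile(f, eff), eff)
    expect_equal(unlist(est[1, c("mCmC", "uCmC", "mCuC", "uCuC")],
                        use.names = FALSE), rep(25, 4), tolerance = 1e-9)
})
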