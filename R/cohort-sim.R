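## Gaussian-copula synthetic cohort generator.
##
## Per group, a latent multivariate normal with unit variances is pushed
## through the probability integral transform onto marginals pinned to the
## published median/IQR summaries. Pattern percentages are generated by
## sampling mC, uCmC and mCuC and deriving
##   mCmC = mC - (uCmC + mCuC)/2,   uCuC = 100 - mC - (uCmC + mCuC)/2,
## which preserves the deconvolution identity mC = (2 mCmC + uCmC + mCuC)/2
## and matches the published medians of mC and uCmC exactly (the five
## published methylation summaries are not jointly consistent with that
## identity, so the two widest patterns absorb the slack). Band profiles are
## produced by the forward densitometry model plus multiplicative lognormal
## noise, and re-quantified to give per-subject estimates.

#' Spearman-to-Pearson latent correlation conversion
#'
#' For a Gaussian copula, a latent Pearson correlation \code{r} induces a
#' Spearman rank correlation \code{rho = (6/pi) asin(r/2)} between any
#' continuous marginals. This is the exact inverse, \code{r = 2 sin(pi rho/6)},
#' used to seed latent correlations from target rank correlations.
#'
#' @param rho Spearman rank correlation(s) in (-1, 1).
#' @return Latent Pearson correlation(s).
#' @export
spearmanToPearson <- function(rho) 2 * sin(pi * rho / 6)

## Build a correlation matrix over `vars` from a data.frame of pairs
## (columns x, y, r); unspecified pairs are 0. Repaired to the nearest
## positive-definite correlation matrix if needed.
corrFromPairs <- function(vars, pairs) {
    R <- diag(length(vars))
    dimnames(R) <- list(vars, vars)
    if (!is.null(pairs) && nrow(pairs)) {
        for (i in seq_len(nrow(pairs))) {
            x <- pairs$x[i]; y <- pairs$y[i]
            if (!x %in% vars || !y %in% vars) next
            R[x, y] <- R[y, x] <- pairs$r[i]
        }
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) {
        R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
        dimnames(R) <- list(vars, vars)
    }
    R
}

## Default latent-correlation pair tables. The cross-group pairs carry
## within-group latent correlations calibrated by Monte Carlo (see
## calibrateCohortConfig) so the POOLED empirical Spearman correlations hit
## the published glucose/HbA1c vs mC/uCmC values; the patient-only pairs are
## calibrated against the published patients-only correlations.
defaultLatentPairs <- function() {
    shared <- data.frame(
        x = c("glucose", "glucose", "hba1c", "glucose", "hba1c"),
        y = c("hba1c",   "mC",      "mC",    "uCmC",    "uCmC"),
        r = c(0.5,       0.3467,    0.1936, -0.3382,   -0.1129))
    patient <- rbind(shared, data.frame(
        x = c("mC",   "age_at_diagnosis", "duration"),
        y = c("uCmC", "uCmC",             "uCmC"),
        r = c(-0.377, -0.3085,             0.4274)))
    control <- shared
    list(patient = patient, control = control)
}

defaultMarginals <- function() {
    list(
        patient = list(
            age_at_diagnosis = marginalSpec(14, 9, 21, "truncnorm", lower = 0, upper = 69),
            duration = marginalSpec(12, 4, 20.5, "truncnorm", lower = 1, upper = 69),
            sbp = marginalSpec(125, 110, 130, "splitnorm"),
            dbp = marginalSpec(75, 70, 85, "splitnorm"),
            bmi = marginalSpec(23, 21, 24, "splitnorm"),
            glucose = marginalSpec(113, 94, 146, "splitnorm"),
            hba1c = marginalSpec(7.3, 6.8, 7.9, "splitnorm"),
            mC = marginalSpec(47.3, 46.6, 47.8, "splitnorm"),
            uCmC = marginalSpec(28.4, 24.7, 33.3, "splitnorm"),
            mCuC = marginalSpec(16.4, 11.3, 25.1, "splitnorm")),
        control = list(
            age = marginalSpec(28, 20, 31.5, "truncnorm", lower = 18, upper = 70),
            sbp = marginalSpec(115, 100, 125, "splitnorm"),
            dbp = marginalSpec(70, 65, 80, "splitnorm"),
            bmi = marginalSpec(22, 21, 23, "splitnorm"),
            glucose = marginalSpec(79.5, 75.5, 89, "splitnorm"),
            hba1c = marginalSpec(4.9, 4.7, 5.2, "splitnorm"),
            mC = marginalSpec(46.5, 44.7, 47.3, "splitnorm"),
            uCmC = marginalSpec(33.1, 27.8, 37.9, "splitnorm"),
            mCuC = marginalSpec(15.9, 12.3, 19.4, "splitnorm")))
}

#' Default calibrated cohort configuration
#'
#' The packaged study conditions: 35 patients and 28 controls, marginals pinned
#' to the published per-group median/IQR summaries (clinical covariates, total
#' methylation mC and the uCmC/mCuC patterns; patients additionally age at
#' diagnosis and disease duration), a 56.7\% male proportion in both groups,
#' and latent Gaussian-copula correlations calibrated so that the pooled
#' empirical Spearman correlations of glucose/HbA1c with mC and uCmC, and the
#' patients-only correlations of age at diagnosis and duration with uCmC,
#' reproduce the published values. Band-intensity noise is multiplicative
#' lognormal with a 3\% coefficient of variation by default.
#'
#' @param nPatients,nControls Group sizes.
#' @param noiseCV Coefficient of variation of band noise.
#' @param sexRatio Proportion male.
#' @param latentPairs Optional named list (\code{patient}, \code{control}) of
#'   latent-correlation pair tables (columns \code{x}, \code{y}, \code{r})
#'   overriding the calibrated defaults.
#' @return A [CohortConfig-class].
#' @export
defaultCohortConfig <- function(nPatients = 35L, nControls = 28L,
                                noiseCV = 0.03, sexRatio = 0.567,
                                latentPairs = defaultLatentPairs()) {
    marg <- defaultMarginals()
    new("CohortConfig",
        nPatients = as.integer(nPatients), nControls = as.integer(nControls),
        marginals = marg,
        latentCorrelation = list(
            patient = corrFromPairs(names(marg$patient), latentPairs$patient),
            control = corrFromPairs(names(marg$control), latentPairs$control)),
        sexRatio = sexRatio, noiseCV = noiseCV,
        effectiveLengths = cobraEffectiveLengths())
}

## Sample one group's covariates and true methylation variables.
sampleGroup <- function(config, group, n) {
    marg <- config@marginals[[group]]
    R <- config@latentCorrelation[[group]]
    vars <- names(marg)
    params <- lapply(marg, solveMarginal)
    Z <- matrix(rnorm(n * length(vars)), n) %*% chol(R)
    U <- pnorm(Z)
    X <- vapply(seq_along(vars),
                function(j) quantileMarginal(params[[j]], U[, j]),
                numeric(n))
    colnames(X) <- vars
    as.data.frame(X)
}

## Derive the full four-pattern simplex from sampled mC, uCmC, mCuC (percent).
deriveFractions <- function(mC, uCmC, mCuC) {
    half <- (uCmC + mCuC) / 2
    pat <- cbind(f_mCmC = mC - half, f_uCmC = uCmC, f_mCuC = mCuC,
                 f_uCuC = 100 - mC - half)
    violations <- rowSums(pat < 0) > 0
    if (mean(violations) > 0.20)
        stop("marginals are inconsistent: >20% of subjects fall off the simplex")
    pat[pat < 0] <- 0
    pat / rowSums(pat)
}

#' Simulate a COBRA LINE-1 case-control cohort
#'
#' Draws a cohort under a [CohortConfig-class]: group-specific copula samples
#' of clinical covariates and true methylation variables, derivation of the
#' four-pattern simplex, forward densitometry with multiplicative lognormal
#' band noise, and re-quantification through the published deconvolution.
#' Patients' age is the sum of age at diagnosis and disease duration
#' (adjusted, preserving duration, into the study's 18-70 year inclusion
#' window); controls' age is sampled directly. Identical \code{config} and
#' \code{seed} reproduce the cohort exactly.
#'
#' @param config A [CohortConfig-class], default [defaultCohortConfig()].
#' @param seed Integer seed.
#' @return A [CobraCohort-class]. The subject table has one row per subject
#'   with columns \code{subject_id}, \code{group}, \code{age}, \code{sex},
#'   \code{age_at_diagnosis}, \code{duration} (patients; NA for controls),
#'   \code{sbp}, \code{dbp}, \code{bmi}, \code{glucose}, \code{hba1c}, the
#'   true pattern fractions \code{f_mCmC}, \code{f_uCmC}, \code{f_mCuC},
#'   \code{f_uCuC}, the noisy band profile \code{pct_160}, \code{pct_98},
#'   \code{pct_80}, \code{pct_62}, and the quantified estimates \code{mC},
#'   \code{mCmC}, \code{uCmC}, \code{mCuC}, \code{uCuC}.
#' @examples
#' coh <- sampleCohort(defaultCohortConfig(), seed = 1)
#' head(subjectData(coh))
#' @export
sampleCohort <- function(config = defaultCohortConfig(), seed = 1L) {
    validObject(config)
    seed <- as.integer(seed)
    set.seed(seed)
    groups <- list(patient = config@nPatients, control = config@nControls)
    rows <- lapply(names(groups), function(grp) {
        n <- groups[[grp]]
        X <- sampleGroup(config, grp, n)
        if (grp == "patient") {
            age <- X$age_at_diagnosis + X$duration
            low <- age < 18
            X$age_at_diagnosis[low] <- 18 - X$duration[low]
            high <- (X$age_at_diagnosis + X$duration) > 70
            X$duration[high] <- pmax(1, 70 - X$age_at_diagnosis[high])
            X$age <- X$age_at_diagnosis + X$duration
        } else {
            X$age_at_diagnosis <- NA_real_
            X$duration <- NA_real_
        }
        sex <- ifelse(rbinom(n, 1L, config@sexRatio) == 1L, "male", "female")
        fr <- deriveFractions(X$mC, X$uCmC, X$mCuC)
        pct <- forwardBandProfile(fr, config@effectiveLengths)
        if (config@noiseCV > 0) {
            s2 <- log(1 + config@noiseCV^2)
            noise <- exp(matrix(rnorm(n * 4, -s2 / 2, sqrt(s2)), n))
            I <- pct * noise
            pct <- 100 * I / rowSums(I)
        }
        est <- quantifyBands(pct, config@effectiveLengths)
        data.frame(
            subject_id = sprintf("%s%03d", if (grp == "patient") "P" else "C",
                                 seq_len(n)),
            group = grp, age = X$age, sex = sex,
            age_at_diagnosis = X$age_at_diagnosis, duration = X$duration,
            sbp = X$sbp, dbp = X$dbp, bmi = X$bmi,
            glucose = X$glucose, hba1c = X$hba1c,
            fr, pct, est)
    })
    new("CobraCohort", subjects = do.call(rbind, rows), config = config,
        seed = seed)
}

#' Calibrate latent correlations against target Spearman correlations
#'
#' Iterative Monte-Carlo calibration of the generator's latent correlation
#' entries: at each iteration a large synthetic cohort is drawn through the
#' full pipeline (copula, simplex derivation, band noise, quantification), the
#' empirical Spearman correlations of the targeted pairs are measured on the
#' quantified estimates, and each latent entry is moved by the residual. This
#' accounts for everything the analytic \code{2 sin(pi rho / 6)} conversion
#' cannot see: the case/control mixture in pooled correlations, truncated
#' marginals, simplex clipping and measurement noise. The packaged defaults in
#' [defaultLatentPairs()] were produced by this routine.
#'
#' @param config Starting [CohortConfig-class].
#' @param targets Data.frame with columns \code{x}, \code{y}, \code{rho}
#'   (target Spearman) and \code{scope} (\code{"pooled"} or
#'   \code{"patient"}).
#' @param nSim Subjects per group per iteration.
#' @param iterations Number of update sweeps.
#' @param seed Seed for the calibration draws.
#' @return The configuration with updated latent correlation matrices, with an
#'   attribute \code{"achieved"}: the measured Spearman correlations at the
#'   last iteration.
#' @export
calibrateCohortConfig <- function(config = defaultCohortConfig(),
                                  targets = defaultRhoTargets(),
                                  nSim = 20000L, iterations = 4L, seed = 1L) {
    wP <- config@nPatients / (config@nPatients + config@nControls)
    cfg <- config
    achieved <- numeric(nrow(targets))
    for (it in seq_len(iterations)) {
        big <- cfg
        big@nPatients <- as.integer(round(nSim * wP))
        big@nControls <- as.integer(nSim - big@nPatients)
        coh <- subjectData(sampleCohort(big, seed = seed + it))
        for (i in seq_len(nrow(targets))) {
            sub <- if (targets$scope[i] == "patient")
                coh[coh$group == "patient", ] else coh
            obs <- cor(sub[[targets$x[i]]], sub[[targets$y[i]]],
                       method = "spearman", use = "complete.obs")
            achieved[i] <- obs
            for (grp in c("patient", "control")) {
                R <- cfg@latentCorrelation[[grp]]
                if (targets$scope[i] == "patient" && grp != "patient") next
                if (!all(c(targets$x[i], targets$y[i]) %in% rownames(R))) next
                r <- R[targets$x[i], targets$y[i]] + (targets$rho[i] - obs)
                R[targets$x[i], targets$y[i]] <-
                    R[targets$y[i], targets$x[i]] <- max(-0.99, min(0.99, r))
                ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
                if (min(ev) < 1e-8)
                    R <- as.matrix(Matrix::nearPD(R, corr = TRUE,
                                                  keepDiag = TRUE)$mat)
                cfg@latentCorrelation[[grp]] <- R
            }
        }
    }
    names(achieved) <- paste(targets$x, targets$y, sep = "~")
    attr(cfg, "achieved") <- achieved
    cfg
}

#' Published rank-correlation targets for the generator
#'
#' The Spearman correlations the calibrated generator reproduces: pooled
#' (both groups, n = 63) correlations of fasting glucose and HbA1c with total
#' methylation mC and the uCmC pattern, and patients-only correlations of age
#' at diagnosis and disease duration with uCmC.
#'
#' @return Data.frame with columns \code{x}, \code{y}, \code{rho},
#'   \code{scope}.
#' @export
defaultRhoTargets <- function() {
    data.frame(
        x = c("glucose", "hba1c", "glucose", "hba1c",
              "age_at_diagnosis", "duration"),
        y = c("mC", "mC", "uCmC", "uCmC", "uCmC", "uCmC"),
        rho = c(0.380, 0.342, -0.383, -0.270, -0.341, 0.388),
        scope = c("pooled", "pooled", "pooled", "pooled",
                  "patient", "patient"))
}
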