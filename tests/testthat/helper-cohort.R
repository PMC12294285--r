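## Shared test fixtures, built in code.

## A reduced cohort configuration for fast structural tests (the calibrated
## defaults at full size are exercised in the acceptance suite).
smallCohortConfig <- function(noiseCV = 0.03) {
    defaultCohortConfig(nPatients = 12L, nControls = 10L, noiseCV = noiseCV)
}

## Random valid band profiles (rows summing to 100) for property tests.
randomLanes <- function(n, seed = 1) {
    set.seed(seed)
    m <- matrix(rexp(4 * n), ncol = 4)
    pct <- 100 * m / rowSums(m)
    colnames(pct) <- c("pct_160", "pct_98", "pct_80", "pct_62")
    pct
}

## Lattice grid over the 4-simplex: all nonnegative integer compositions of
## `resolution` into 4 parts, scaled to fractions.
simplexGrid <- function(resolution) {
    idx <- expand.grid(i = 0:resolution, j = 0:resolution, k = 0:resolution)
    idx <- idx[idx$i + idx$j + idx$k <= resolution, ]
    f <- cbind(idx$i, idx$j, idx$k, resolution - idx$i - idx$j - idx$k) /
        resolution
    colnames(f) <- c("f_mCmC", "f_uCmC", "f_mCuC", "f_uCuC")
    f
}

## Molecule-count forward model used as an independent oracle: given integer
## molecule counts per pattern, count restriction fragments per the published
## fragment mapping, weight by effective length, and return percent band
## intensities. Deliberately written as explicit per-band bookkeeping, not via
## forwardBandProfile().
moleculeLane <- function(nMCMC, nUCMC, nMCUC, nUCUC,
                         eff = c(`160` = 160, `98` = 94, `80` = 78, `62` = 62)) {
    count160 <- nMCUC                # mCuC: uncut molecule
    count98 <- nUCUC                 # uCuC: 98 bp piece
    count80 <- 2 * nMCMC + nUCMC     # mCmC: two 80s; uCmC: one 80
    count62 <- nUCUC + nUCMC         # uCuC and uCmC each shed one 62
    signal <- c(count160 * eff["160"], count98 * eff["98"],
                count80 * eff["80"], count62 * eff["62"])
    pct <- 100 * signal / sum(signal)
    names(pct) <- c("pct_160", "pct_98", "pct_80", "pct_62")
    pct
}

## Exact two-sided Mann-Whitney p-value by complete enumeration of group
## assignments (no ties), for small samples.
enumerateMannWhitneyP <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x)
    uFor <- function(idx) {
        a <- pooled[idx]; b <- pooled[-idx]
        sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    }
    uObs <- uFor(seq_len(n1))
    uAll <- combn(length(pooled), n1, uFor)
    pl <- mean(uAll <= uObs + 1e-12)
    pg <- mean(uAll >= uObs - 1e-12)
    min(1, 2 * min(pl, pg))
}
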