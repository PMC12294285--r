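## Densitometry deconvolution for the COBRA LINE-1 assay.
##
## Band intensities (percent of quantified lane signal at 160/98/80/62 bp) are
## divided by effective lengths to give relative molar abundances
##   A = %160/160, B = %98/94, C = %80/78, D = %62/62
## (divisors 94 and 78 as published, not the nominal band lengths), from which
##   mC    = 100 (C + A) / (C + 2A + B + D)
##   mCmC  = 100 ((C - D + B)/2) / S      uCmC = 100 (D - B) / S
##   uCuC  = 100 B / S                    mCuC = 100 A / S
## with S = (C - D + B)/2 + A + D. The four patterns sum to 100 by
## construction and mC == (2 mCmC + uCmC + mCuC)/2 identically.

#' Effective band lengths of the COBRA LINE-1 assay
#'
#' The published length divisors used to convert percent band intensity to
#' relative molar abundance: 160, 94, 78 and 62 for the 160/98/80/62 bp bands.
#' The 98 and 80 bp bands are divided by 94 and 78 (not their nominal
#' lengths), as in the original assay description; pass
#' \code{c(`160` = 160, `98` = 98, `80` = 80, `62` = 62)} to study the bias
#' induced by using nominal lengths instead.
#'
#' @return Named numeric vector with names \code{"160", "98", "80", "62"}.
#' @export
cobraEffectiveLengths <- function() c(`160` = 160, `98` = 94, `80` = 78, `62` = 62)

## Coerce a band profile (vector of 4, matrix, or data.frame with pct_* or
## bare band-name columns) to an n x 4 matrix with columns 160/98/80/62.
bandMatrix <- function(bands) {
    cn <- c("pct_160", "pct_98", "pct_80", "pct_62")
    if (is.data.frame(bands)) {
        have <- if (all(cn %in% names(bands))) cn
                else if (all(c("160", "98", "80", "62") %in% names(bands)))
                    c("160", "98", "80", "62")
                else stop("band table needs columns pct_160, pct_98, pct_80, pct_62")
        bands <- as.matrix(bands[, have])
    } else if (is.null(dim(bands))) {
        if (length(bands) != 4L)
            stop("a single band profile must have 4 values (160, 98, 80, 62 bp)")
        bands <- matrix(bands, nrow = 1L)
    }
    if (ncol(bands) != 4L) stop("band matrix must have 4 columns")
    if (any(!is.finite(bands))) stop("band intensities must be finite")
    if (any(bands < 0)) stop("band intensities must be nonnegative")
    colnames(bands) <- c("160", "98", "80", "62")
    bands
}

#' Length-normalize band intensities
#'
#' Divides each band's percent intensity by its effective length, yielding the
#' relative molar abundances A (160 bp), B (98 bp), C (80 bp), D (62 bp).
#'
#' @param bands A band profile: numeric vector \code{c(pct_160, pct_98,
#'   pct_80, pct_62)}, or a matrix/data.frame with those columns (one row per
#'   lane).
#' @param effectiveLengths Length divisors, default [cobraEffectiveLengths()].
#' @return A matrix with columns \code{A}, \code{B}, \code{C}, \code{D}.
#' @examples
#' normalizeBands(c(100, 0, 0, 0))            # A = 0.625
#' @export
normalizeBands <- function(bands, effectiveLengths = cobraEffectiveLengths()) {
    m <- bandMatrix(bands)
    stopifnot(all(effectiveLengths > 0))
    ab <- sweep(m, 2L, effectiveLengths[colnames(m)], "/")
    colnames(ab) <- c("A", "B", "C", "D")
    ab
}

abMatrix <- function(ab) {
    if (is.null(dim(ab))) ab <- matrix(ab, nrow = 1L,
                                       dimnames = list(NULL, names(ab)))
    if (!all(c("A", "B", "C", "D") %in% colnames(ab)))
        stop("normalized abundances need columns A, B, C, D")
    ab[, c("A", "B", "C", "D"), drop = FALSE]
}

#' Total methylation from normalized abundances
#'
#' \code{mC = 100 (C + A) / (C + 2A + B + D)}: the fraction of methylated CpG
#' loci among the two interrogated loci per molecule.
#'
#' @param ab Normalized abundances from [normalizeBands()] (vector with names
#'   A, B, C, D, or a matrix).
#' @return Numeric vector of mC percentages in \code{[0, 100]}.
#' @export
totalMethylation <- function(ab) {
    ab <- abMatrix(ab)
    denom <- ab[, "C"] + 2 * ab[, "A"] + ab[, "B"] + ab[, "D"]
    if (any(denom <= 0))
        stop("total methylation undefined: all normalized abundances are zero")
    unname(100 * (ab[, "C"] + ab[, "A"]) / denom)
}

#' Methylation-pattern percentages from normalized abundances
#'
#' Solves the linear fragment-counting system for the four pattern
#' percentages. With \code{S = (C - D + B)/2 + A + D}:
#' mCmC = 100((C-D+B)/2)/S, uCmC = 100(D-B)/S, mCuC = 100 A/S,
#' uCuC = 100 B/S. Inferred numerators that are negative beyond numerical
#' tolerance (possible for noisy lanes, since the inverse can leave the
#' simplex) are clipped to zero with a warning and the four percentages
#' renormalized.
#'
#' @inheritParams totalMethylation
#' @return Matrix with columns \code{mCmC}, \code{uCmC}, \code{mCuC},
#'   \code{uCuC}, rows summing to 100.
#' @export
patternPercentages <- function(ab) {
    ab <- abMatrix(ab)
    A <- ab[, "A"]; B <- ab[, "B"]; C <- ab[, "C"]; D <- ab[, "D"]
    half <- (C - D + B) / 2
    S <- half + A + D
    if (any(S <= 0))
        stop("pattern percentages undefined: shared denominator is not positive")
    num <- cbind(mCmC = half, uCmC = D - B, mCuC = A, uCuC = B)
    tol <- 1e-9 * S
    below <- num < -tol
    if (any(below)) {
        warning("negative inferred pattern abundance clipped to zero (",
                sum(below), " value(s)); lane is outside the feasible simplex")
    }
    num[num < 0] <- 0
    100 * num / rowSums(num)
}

#' Quantify a band profile into a methylation estimate
#'
#' Composition of [normalizeBands()], [totalMethylation()] and
#' [patternPercentages()]: the full published deconvolution from a gel lane to
#' total methylation and the four pattern percentages.
#'
#' @inheritParams normalizeBands
#' @return A data.frame with columns \code{mC}, \code{mCmC}, \code{uCmC},
#'   \code{mCuC}, \code{uCuC} (one row per lane).
#' @examples
#' quantifyBands(c(100, 0, 0, 0))    # pure mCuC lane: mC = 50
#' @export
quantifyBands <- function(bands, effectiveLengths = cobraEffectiveLengths()) {
    ab <- normalizeBands(bands, effectiveLengths)
    data.frame(mC = totalMethylation(ab), patternPercentages(ab),
               row.names = NULL)
}

#' Forward densitometry model: pattern fractions to a band profile
#'
#' The generative counterpart of the deconvolution. Per molecule, the patterns
#' contribute fragments per the digest model (mCuC: one 160; uCuC: one 98 and
#' one 62; mCmC: two 80; uCmC: one 80 and one 62, the 18 bp piece being
#' unquantified), so molar band abundances are \code{q160 = f_mCuC},
#' \code{q98 = f_uCuC}, \code{q80 = 2 f_mCmC + f_uCmC},
#' \code{q62 = f_uCuC + f_uCmC}. Stain signal is modeled as proportional to
#' molarity times effective length (mass-proportional), then expressed as
#' percent of the quantified lane total. With the default effective lengths,
#' [quantifyBands()] inverts this map exactly.
#'
#' @param fractions Pattern fractions summing to 1: numeric vector or matrix
#'   with names/columns \code{f_mCmC}, \code{f_uCmC}, \code{f_mCuC},
#'   \code{f_uCuC} (bare pattern names also accepted).
#' @param effectiveLengths Band length weights, default
#'   [cobraEffectiveLengths()].
#' @return Matrix with columns \code{pct_160}, \code{pct_98}, \code{pct_80},
#'   \code{pct_62}, rows summing to 100.
#' @examples
#' forwardBandProfile(c(f_mCmC = .25, f_uCmC = .25, f_mCuC = .25, f_uCuC = .25))
#' @export
forwardBandProfile <- function(fractions,
                               effectiveLengths = cobraEffectiveLengths()) {
    if (is.null(dim(fractions)))
        fractions <- matrix(fractions, nrow = 1L,
                            dimnames = list(NULL, names(fractions)))
    fractions <- as.matrix(fractions)
    want <- c("f_mCmC", "f_uCmC", "f_mCuC", "f_uCuC")
    if (!all(want %in% colnames(fractions))) {
        if (all(methylationPatterns() %in% colnames(fractions)))
            colnames(fractions) <- paste0("f_", colnames(fractions))
        else stop("fractions need names f_mCmC, f_uCmC, f_mCuC, f_uCuC")
    }
    f <- fractions[, want, drop = FALSE]
    if (any(f < 0) || any(abs(rowSums(f) - 1) > 1e-6))
        stop("pattern fractions must be nonnegative and sum to 1")
    q <- cbind(`160` = f[, "f_mCuC"],
               `98`  = f[, "f_uCuC"],
               `80`  = 2 * f[, "f_mCmC"] + f[, "f_uCmC"],
               `62`  = f[, "f_uCuC"] + f[, "f_uCmC"])
    intensity <- sweep(q, 2L, effectiveLengths[colnames(q)], "*")
    pct <- 100 * intensity / rowSums(intensity)
    dimnames(pct) <- list(NULL, c("pct_160", "pct_98", "pct_80", "pct_62"))
    pct
}
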