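#' @import methods
#' @importClassesFrom Biostrings DNAString
NULL

#' Restriction enzyme model
#'
#' A minimal model of a type II restriction enzyme: its recognition site on the
#' top strand and where, within the site, the top strand is cut. The cut offset
#' counts the recognition-site bases left of the cut, so an offset of 0 cuts
#' immediately before the site (MluCI, ^AATT) and an offset of 1 cuts after the
#' first base (TaqI, T^CGA).
#'
#' @slot name Enzyme name.
#' @slot recognitionSite Recognition sequence on the top strand (DNA alphabet).
#' @slot cutOffset Integer in \code{[0, nchar(recognitionSite)]}: number of
#'   site bases left of the cut.
#'
#' @seealso [TaqI], [MluCI], [digestSequence()]
#' @exportClass RestrictionEnzyme
setClass("RestrictionEnzyme",
    representation(
        name = "character",
        recognitionSite = "character",
        cutOffset = "integer"
    )
)

setValidity("RestrictionEnzyme", function(object) {
    msg <- character()
    if (length(object@recognitionSite) != 1L || nchar(object@recognitionSite) < 1L)
        msg <- c(msg, "'recognitionSite' must be a single non-empty string")
    if (length(object@cutOffset) != 1L || is.na(object@cutOffset) ||
        object@cutOffset < 0L || object@cutOffset > nchar(object@recognitionSite))
        msg <- c(msg, "'cutOffset' must lie in [0, nchar(recognitionSite)]")
    if (length(object@recognitionSite) == 1L &&
        grepl("[^ACGT]", object@recognitionSite))
        msg <- c(msg, "'recognitionSite' must use the unambiguous DNA alphabet")
    if (length(msg)) msg else TRUE
})

#' Amplicon specification for a COBRA assay
#'
#' Describes a bisulfite-PCR amplicon interrogated by COBRA: its (synthetic or
#' real) sequence, the 1-based positions of the cytosines of the interrogated
#' CpG dinucleotides, and the PCR primers as metadata. Primer strings may use
#' IUPAC ambiguity codes (the published LINE-1 reverse primer contains R);
#' they are carried as annotation only and never searched against the sequence.
#'
#' @slot sequence A [Biostrings::DNAString] with the amplicon top strand.
#' @slot cpgPositions Strictly increasing 1-based positions of interrogated
#'   CpG cytosines.
#' @slot lengthBp Amplicon length in bp (160 for the LINE-1 assay).
#' @slot forwardPrimer,reversePrimer Primer sequences (metadata).
#'
#' @seealso [line1Amplicon()], [simulateAmpliconDigest()]
#' @exportClass AmpliconSpec
setClass("AmpliconSpec",
    representation(
        sequence = "DNAString",
        cpgPositions = "integer",
        lengthBp = "integer",
        forwardPrimer = "character",
        reversePrimer = "character"
    )
)

setValidity("AmpliconSpec", function(object) {
    msg <- character()
    if (length(object@lengthBp) != 1L || object@lengthBp < 1L)
        msg <- c(msg, "'lengthBp' must be a positive integer")
    if (length(object@sequence) > 0L && length(object@lengthBp) == 1L &&
        object@lengthBp != length(object@sequence))
        msg <- c(msg, "'lengthBp' must equal the sequence length")
    if (length(object@cpgPositions) && is.unsorted(object@cpgPositions, strictly = TRUE))
        msg <- c(msg, "'cpgPositions' must be strictly increasing")
    if (length(object@cpgPositions) && length(object@sequence) > 0L) {
        s <- as.character(object@sequence)
        ok <- vapply(object@cpgPositions, function(p) {
            p >= 1L && p < nchar(s) &&
                substr(s, p, p) == "C" && substr(s, p + 1L, p + 1L) == "G"
        }, logical(1))
        if (!all(ok))
            msg <- c(msg, "every 'cpgPositions' entry must point at the C of a CpG")
    }
    if (length(msg)) msg else TRUE
})

#' Restriction fragment set
#'
#' The multiset of fragment lengths produced by digesting one amplicon
#' molecule, together with the subset retained for densitometry. In the
#' LINE-1 assay the quantified bands are 160, 98, 80 and 62 bp; the 18 bp
#' product of the uCmC pattern runs off the quantified window and is excluded.
#'
#' @slot lengths Integer fragment lengths (bp), sorted ascending.
#' @slot quantifiedLengths The sublist of \code{lengths} retained for
#'   densitometry.
#'
#' @seealso [fragmentsForPattern()], [digestSequence()]
#' @exportClass FragmentSet
setClass("FragmentSet",
    representation(
        lengths = "integer",
        quantifiedLengths = "integer"
    )
)

setValidity("FragmentSet", function(object) {
    msg <- character()
    if (any(object@lengths <= 0L))
        msg <- c(msg, "fragment lengths must be positive")
    if (is.unsorted(object@lengths))
        msg <- c(msg, "'lengths' must be sorted ascending")
    tab_all <- table(object@lengths)
    tab_q <- table(object@quantifiedLengths)
    if (!all(names(tab_q) %in% names(tab_all)) ||
        any(tab_q > tab_all[names(tab_q)]))
        msg <- c(msg, "'quantifiedLengths' must be a sub-multiset of 'lengths'")
    if (length(msg)) msg else TRUE
})

#' Marginal distribution specification
#'
#' A low-parameter marginal pinned to a printed median and interquartile range,
#' the summary format of the study tables. Families: \code{"normal"} (location =
#' median, scale = IQR/1.349), \code{"splitnorm"} (two-piece normal whose
#' 25th/50th/75th percentiles match all three printed quartiles exactly,
#' capturing their asymmetry), \code{"truncnorm"} (normal truncated to
#' \code{[lower, upper]}, location/scale solved so the truncated median and IQR
#' match exactly) and \code{"logitnormal"} (normal on the logit of value/100,
#' for percentages near the boundary).
#'
#' @slot median,q1,q3 Printed median and quartiles; \code{q1 < median < q3}.
#' @slot family One of \code{"normal"}, \code{"splitnorm"}, \code{"truncnorm"},
#'   \code{"logitnormal"}.
#' @slot lower,upper Support bounds (used by \code{"truncnorm"}).
#'
#' @seealso [marginalSpec()], [solveMarginal()]
#' @exportClass MarginalSpec
setClass("MarginalSpec",
    representation(
        median = "numeric",
        q1 = "numeric",
        q3 = "numeric",
        family = "character",
        lower = "numeric",
        upper = "numeric"
    ),
    prototype(lower = -Inf, upper = Inf, family = "normal")
)

setValidity("MarginalSpec", function(object) {
    msg <- character()
    if (!(object@q1 < object@median && object@median < object@q3))
        msg <- c(msg, "require q1 < median < q3")
    if (!object@family %in% c("normal", "splitnorm", "truncnorm", "logitnormal"))
        msg <- c(msg, "unknown marginal family")
    if (object@lower >= object@upper)
        msg <- c(msg, "require lower < upper")
    if (object@family == "truncnorm" &&
        (object@q1 < object@lower || object@q3 > object@upper))
        msg <- c(msg, "quartiles must lie inside the truncation bounds")
    if (length(msg)) msg else TRUE
})

#' Cohort generator configuration
#'
#' Everything the synthetic-cohort generator needs: group sizes, per-group
#' marginal specifications (clinical covariates and the methylation variables),
#' per-group latent Gaussian-copula correlation matrices, the male proportion,
#' and the coefficient of variation of the multiplicative band-intensity noise.
#'
#' @slot nPatients,nControls Group sizes (defaults 35 and 28).
#' @slot marginals Named list with elements \code{patient} and \code{control},
#'   each a named list of [MarginalSpec] objects.
#' @slot latentCorrelation Named list with elements \code{patient} and
#'   \code{control}, each a symmetric latent correlation matrix whose
#'   dimnames match the group's marginal names.
#' @slot sexRatio Proportion of males in each group.
#' @slot noiseCV Coefficient of variation of the lognormal band noise.
#' @slot effectiveLengths Band length divisors used by the forward densitometry
#'   model (named by band).
#'
#' @seealso [defaultCohortConfig()], [sampleCohort()]
#' @exportClass CohortConfig
setClass("CohortConfig",
    representation(
        nPatients = "integer",
        nControls = "integer",
        marginals = "list",
        latentCorrelation = "list",
        sexRatio = "numeric",
        noiseCV = "numeric",
        effectiveLengths = "numeric"
    )
)

setValidity("CohortConfig", function(object) {
    msg <- character()
    if (object@nPatients < 2L || object@nControls < 2L)
        msg <- c(msg, "group sizes must be at least 2")
    if (!all(c("patient", "control") %in% names(object@marginals)))
        msg <- c(msg, "'marginals' needs elements 'patient' and 'control'")
    if (!all(c("patient", "control") %in% names(object@latentCorrelation)))
        msg <- c(msg, "'latentCorrelation' needs elements 'patient' and 'control'")
    if (object@sexRatio <= 0 || object@sexRatio >= 1)
        msg <- c(msg, "'sexRatio' must be in (0, 1)")
    if (object@noiseCV < 0)
        msg <- c(msg, "'noiseCV' must be nonnegative")
    for (grp in intersect(c("patient", "control"), names(object@latentCorrelation))) {
        R <- object@latentCorrelation[[grp]]
        vars <- names(object@marginals[[grp]])
        if (!is.matrix(R) || !identical(rownames(R), vars) ||
            !identical(colnames(R), vars)) {
            msg <- c(msg, sprintf(
                "latent correlation for '%s' must be a matrix with dimnames matching its marginals", grp))
            next
        }
        if (max(abs(R - t(R))) > 1e-8 || any(abs(R[row(R) != col(R)]) >= 1))
            msg <- c(msg, sprintf("latent correlation for '%s' must be symmetric with off-diagonals in (-1, 1)", grp))
    }
    if (length(msg)) msg else TRUE
})

#' A simulated COBRA LINE-1 cohort
#'
#' Container for one simulated case-control cohort: a per-subject table holding
#' clinical covariates, ground-truth pattern fractions, the simulated band
#' profile and the quantified methylation estimates, along with the generating
#' configuration and seed.
#'
#' @slot subjects A data.frame, one row per subject (see [sampleCohort()] for
#'   the column schema).
#' @slot config The [CohortConfig] used.
#' @slot seed Integer seed the cohort was drawn under.
#'
#' @seealso [sampleCohort()], [subjectData()]
#' @exportClass CobraCohort
setClass("CobraCohort",
    representation(
        subjects = "data.frame",
        config = "CohortConfig",
        seed = "integer"
    )
)

setValidity("CobraCohort", function(object) {
    msg <- character()
    need <- c("subject_id", "group", "age", "sex", "glucose", "hba1c",
              "pct_160", "pct_98", "pct_80", "pct_62",
              "mC", "mCmC", "uCmC", "mCuC", "uCuC")
    missing <- setdiff(need, names(object@subjects))
    if (length(missing))
        msg <- c(msg, paste("missing subject columns:", paste(missing, collapse = ", ")))
    if (!length(msg) && nrow(object@subjects)) {
        if (!all(object@subjects$group %in% c("patient", "control")))
            msg <- c(msg, "'group' must be 'patient' or 'control'")
        pat <- object@subjects$group == "patient"
        if (any(pat)) {
            d <- object@subjects$duration[pat]
            a <- object@subjects$age[pat]
            adx <- object@subjects$age_at_diagnosis[pat]
            if (any(is.na(d)) || any(d < 1 - 1e-9))
                msg <- c(msg, "patient disease duration must be at least 1 year")
            if (any(abs(a - adx - d) > 1e-6))
                msg <- c(msg, "duration must equal age - age_at_diagnosis")
        }
        if (any(object@subjects$age < 18 - 1e-9 | object@subjects$age > 70 + 1e-9))
            msg <- c(msg, "age must lie in [18, 70]")
        psum <- with(object@subjects, mCmC + uCmC + mCuC + uCuC)
        if (any(abs(psum - 100) > 1e-6))
            msg <- c(msg, "pattern percentages must sum to 100")
    }
    if (length(msg)) msg else TRUE
})
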