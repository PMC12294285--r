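#' Create a restriction enzyme
#'
#' @param name Enzyme name.
#' @param recognitionSite Top-strand recognition sequence.
#' @param cutOffset Number of site bases left of the cut (see
#'   [RestrictionEnzyme-class]).
#' @return A [RestrictionEnzyme-class] object.
#' @examples
#' RestrictionEnzyme("TaqI", "TCGA", 1L)
#' @export
RestrictionEnzyme <- function(name, recognitionSite, cutOffset) {
    new("RestrictionEnzyme", name = as.character(name),
        recognitionSite = toupper(as.character(recognitionSite)),
        cutOffset = as.integer(cutOffset))
}

#' TaqI restriction enzyme (T^CGA)
#'
#' TaqI retains its TCGA site after bisulfite conversion only when the site's
#' internal CpG cytosine was methylated (unmethylated C converts to T, giving
#' TTGA). It therefore reports the methylated state of its CpG.
#' @format A [RestrictionEnzyme-class] object.
#' @export
TaqI <- new("RestrictionEnzyme", name = "TaqI",
            recognitionSite = "TCGA", cutOffset = 1L)

#' MluCI restriction enzyme (^AATT)
#'
#' In the COBRA LINE-1 design an MluCI site appears after bisulfite conversion
#' only when its CpG cytosine was unmethylated (the converted C supplies the
#' final T of AATT). It therefore reports the unmethylated state of its CpG.
#' @format A [RestrictionEnzyme-class] object.
#' @export
MluCI <- new("RestrictionEnzyme", name = "MluCI",
             recognitionSite = "AATT", cutOffset = 0L)

#' Create an amplicon specification
#'
#' @param sequence Amplicon top strand, as a character string or
#'   [Biostrings::DNAString].
#' @param cpgPositions 1-based positions of the interrogated CpG cytosines.
#' @param forwardPrimer,reversePrimer Primer metadata strings.
#' @return An [AmpliconSpec-class] object.
#' @export
AmpliconSpec <- function(sequence, cpgPositions = integer(),
                         forwardPrimer = NA_character_,
                         reversePrimer = NA_character_) {
    if (is.character(sequence))
        sequence <- Biostrings::DNAString(toupper(sequence))
    new("AmpliconSpec", sequence = sequence,
        cpgPositions = as.integer(cpgPositions),
        lengthBp = length(sequence),
        forwardPrimer = forwardPrimer, reversePrimer = reversePrimer)
}

#' Create a fragment set
#'
#' @param lengths Fragment lengths in bp.
#' @param quantifiedBands Band lengths retained for densitometry; fragments with
#'   other lengths (such as the 18 bp uCmC product) are excluded from
#'   \code{quantifiedLengths}.
#' @return A [FragmentSet-class] object.
#' @export
FragmentSet <- function(lengths, quantifiedBands = c(62L, 80L, 98L, 160L)) {
    lengths <- sort(as.integer(lengths))
    new("FragmentSet", lengths = lengths,
        quantifiedLengths = lengths[lengths %in% as.integer(quantifiedBands)])
}

#' Create a marginal specification
#'
#' @param median,q1,q3 Median and quartiles to pin.
#' @param family \code{"normal"}, \code{"truncnorm"} or \code{"logitnormal"}.
#' @param lower,upper Truncation bounds for \code{"truncnorm"}.
#' @return A [MarginalSpec-class] object.
#' @examples
#' marginalSpec(46.5, 44.7, 47.3)
#' @export
marginalSpec <- function(median, q1, q3, family = "normal",
                         lower = -Inf, upper = Inf) {
    new("MarginalSpec", median = median, q1 = q1, q3 = q3,
        family = family, lower = lower, upper = upper)
}

#' The four two-CpG methylation patterns
#'
#' Joint methylation states of the MluCI-interrogated (first) and
#' TaqI-interrogated (second) CpG sites, in the assay's naming order.
#' @return \code{c("mCmC", "uCmC", "mCuC", "uCuC")}
#' @export
methylationPatterns <- function() c("mCmC", "uCmC", "mCuC", "uCuC")

## --- show methods -----------------------------------------------------------

setMethod("show", "RestrictionEnzyme", function(object) {
    site <- object@recognitionSite
    cut <- paste0(substr(site, 1, object@cutOffset), "^",
                  substr(site, object@cutOffset + 1L, nchar(site)))
    cat("RestrictionEnzyme", object@name, ":", cut, "\n")
})

setMethod("show", "AmpliconSpec", function(object) {
    cat("AmpliconSpec of", object@lengthBp, "bp with",
        length(object@cpgPositions), "interrogated CpG site(s) at",
        paste(object@cpgPositions, collapse = ", "), "\n")
})

setMethod("show", "FragmentSet", function(object) {
    cat("FragmentSet:", paste(object@lengths, collapse = " + "), "bp",
        "(quantified:", paste(object@quantifiedLengths, collapse = ", "), ")\n")
})

setMethod("show", "MarginalSpec", function(object) {
    cat(sprintf("MarginalSpec [%s]: median %.3g (IQR %.3g-%.3g)\n",
                object@family, object@median, object@q1, object@q3))
})

setMethod("show", "CohortConfig", function(object) {
    cat("CohortConfig:", object@nPatients, "patients /", object@nControls,
        "controls; band noise CV", object@noiseCV, "\n")
})

setMethod("show", "CobraCohort", function(object) {
    tb <- table(object@subjects$group)
    cat("CobraCohort with", nrow(object@subjects), "subjects (",
        tb[["patient"]], "patients,", tb[["control"]], "controls ), seed",
        object@seed, "\n")
})

## --- accessors --------------------------------------------------------------

#' Accessors for package classes
#'
#' Small accessor functions returning slot contents: enzyme name, recognition
#' site and cut offset; amplicon sequence and CpG positions; fragment lengths
#' and the quantified sublist; the subject table, configuration and seed of a
#' simulated cohort.
#'
#' @param x The object to access.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
enzymeName <- function(x) x@name

#' @rdname accessors
#' @export
recognitionSite <- function(x) x@recognitionSite

#' @rdname accessors
#' @export
cutOffset <- function(x) x@cutOffset

#' @rdname accessors
#' @export
ampliconSequence <- function(x) x@sequence

#' @rdname accessors
#' @export
cpgPositions <- function(x) x@cpgPositions

#' @rdname accessors
#' @export
fragmentLengths <- function(x) x@lengths

#' @rdname accessors
#' @export
quantifiedLengths <- function(x) x@quantifiedLengths

#' @rdname accessors
#' @export
subjectData <- function(x) x@subjects

#' @rdname accessors
#' @export
cohortConfig <- function(x) x@config

#' @rdname accessors
#' @export
cohortSeed <- function(x) x@seed
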