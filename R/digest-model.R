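## Restriction-fragment model for the COBRA LINE-1 assay.
##
## The 160 bp bisulfite-PCR amplicon carries two interrogated CpG sites. After
## conversion, MluCI (^AATT) gains its site at the first CpG only when that CpG
## was unmethylated, and TaqI (T^CGA) keeps its site at the second CpG only
## when that CpG was methylated. Complete digestion therefore cuts at 62 bp
## (MluCI, first CpG unmethylated) and/or 80 bp (TaqI, second CpG methylated):
##   mCmC -> 80 + 80        uCuC -> 62 + 98
##   uCmC -> 18 + 62 + 80   mCuC -> 160 (uncut)
## The 18 bp piece of uCmC falls outside the quantified window.

#' Restriction fragments implied by a methylation pattern
#'
#' Maps each of the four two-CpG methylation patterns of the 160 bp LINE-1
#' amplicon to the fragment lengths produced by complete MluCI + TaqI
#' digestion. The 18 bp fragment of the uCmC pattern is excluded from the
#' quantified lengths.
#'
#' @param pattern One of \code{"mCmC"}, \code{"uCmC"}, \code{"mCuC"},
#'   \code{"uCuC"} (see [methylationPatterns()]).
#' @return A [FragmentSet-class].
#' @examples
#' fragmentsForPattern("uCmC")   # 18 + 62 + 80, quantified 62 + 80
#' @export
fragmentsForPattern <- function(pattern) {
    pattern <- match.arg(pattern, methylationPatterns())
    lengths <- switch(pattern,
        mCmC = c(80L, 80L),
        uCuC = c(62L, 98L),
        uCmC = c(18L, 62L, 80L),
        mCuC = 160L)
    FragmentSet(lengths)
}

#' In-silico bisulfite conversion
#'
#' Converts every cytosine to thymine except the cytosines listed as
#' methylated, which must sit on a CpG dinucleotide (5-methylcytosine resists
#' conversion). Operates on the top strand; length is preserved.
#'
#' @param sequence Character string or [Biostrings::DNAString].
#' @param methylated 1-based positions of methylated CpG cytosines.
#' @return Converted sequence, same class as the input.
#' @examples
#' bisulfiteConvert("ACGA", methylated = 2)  # "ACGA"
#' bisulfiteConvert("ACGA")                  # "ATGA"
#' @export
bisulfiteConvert <- function(sequence, methylated = integer()) {
    asDNAString <- methods::is(sequence, "DNAString")
    s <- if (asDNAString) as.character(sequence) else toupper(sequence)
    stopifnot(length(s) == 1L)
    methylated <- as.integer(methylated)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- methylated[methylated < 1L | methylated >= length(chars) |
                      chars[pmin(methylated, length(chars))] != "C" |
                      chars[pmin(methylated + 1L, length(chars))] != "G"]
    if (length(bad))
        stop("methylated offset(s) ", paste(bad, collapse = ", "),
             " do not point at the C of a CpG dinucleotide")
    convert <- chars == "C" & !(seq_along(chars) %in% methylated)
    chars[convert] <- "T"
    out <- paste(chars, collapse = "")
    if (asDNAString) Biostrings::DNAString(out) else out
}

#' Digest a sequence with restriction enzymes
#'
#' Scans the top strand left to right for every occurrence of every enzyme's
#' recognition site (overlapping occurrences included), cuts at
#' \code{match start + cutOffset} (counted in between-base coordinates), and
#' returns the resulting fragment lengths. Digestion is modeled as complete;
#' zero-length fragments (cuts at either end) are discarded as unobservable.
#' The result does not depend on the order of the enzyme list.
#'
#' @param sequence Character string or [Biostrings::DNAString].
#' @param enzymes A [RestrictionEnzyme-class] or list of them.
#' @param quantifiedBands Passed to [FragmentSet()].
#' @return A [FragmentSet-class]; fragment lengths sum to the input length.
#' @examples
#' fragmentLengths(digestSequence("AAATCGAAA", TaqI))    # 4, 5
#' fragmentLengths(digestSequence("AATTAATT", MluCI))    # 4, 4
#' @export
digestSequence <- function(sequence, enzymes,
                           quantifiedBands = c(62L, 80L, 98L, 160L)) {
    if (methods::is(enzymes, "RestrictionEnzyme")) enzymes <- list(enzymes)
    s <- if (methods::is(sequence, "DNAString")) sequence
         else Biostrings::DNAString(toupper(sequence))
    L <- length(s)
    stopifnot(L > 0L)
    cuts <- integer()
    for (enz in enzymes) {
        m <- Biostrings::matchPattern(enz@recognitionSite, s)
        if (length(m))
            cuts <- c(cuts, Biostrings::start(m) - 1L + enz@cutOffset)
    }
    cuts <- sort(unique(cuts[cuts > 0L & cuts < L]))
    lens <- diff(c(0L, cuts, L))
    FragmentSet(lens, quantifiedBands = quantifiedBands)
}

#' Simulate the COBRA digest of an amplicon under a methylation pattern
#'
#' Composes [bisulfiteConvert()] and [digestSequence()]: sets the methylation
#' state of the amplicon's two interrogated CpG sites according to
#' \code{pattern}, converts, digests with MluCI and TaqI, and returns the
#' fragment set. On the packaged synthetic amplicon ([line1Amplicon()]) this
#' reproduces [fragmentsForPattern()] for all four patterns.
#'
#' @param amplicon An [AmpliconSpec-class] with two interrogated CpG sites.
#' @param pattern A methylation pattern name.
#' @param enzymes Enzymes to digest with (default MluCI and TaqI).
#' @return A [FragmentSet-class].
#' @examples
#' simulateAmpliconDigest(line1Amplicon(), "uCmC")
#' @export
simulateAmpliconDigest <- function(amplicon, pattern,
                                   enzymes = list(MluCI, TaqI)) {
    pattern <- match.arg(pattern, methylationPatterns())
    stopifnot(methods::is(amplicon, "AmpliconSpec"),
              length(amplicon@cpgPositions) == 2L)
    states <- c(substr(pattern, 1, 2), substr(pattern, 3, 4)) == "mC"
    conv <- bisulfiteConvert(amplicon@sequence,
                             methylated = amplicon@cpgPositions[states])
    digestSequence(conv, enzymes)
}

#' The packaged synthetic 160 bp LINE-1-like amplicon
#'
#' The study never printed its amplicon sequence, so the package ships a
#' synthetic 160 bp stand-in engineered to reproduce the published fragment
#' geometry: the first interrogated CpG sits at position 66 inside AATCG, so
#' conversion of an unmethylated C creates the MluCI site AATT cutting at
#' 62 bp; the second CpG sits at position 81 inside TCGA, so a methylated C
#' preserves the TaqI site cutting at 80 bp. The backbone contains no other
#' cytosine and no other AA dinucleotide, so no spurious site can arise in any
#' conversion state. The published PCR primers are attached as metadata only.
#'
#' @return An [AmpliconSpec-class] of length 160 with CpG positions 66 and 81.
#' @examples
#' fragmentLengths(simulateAmpliconDigest(line1Amplicon(), "mCmC"))  # 80 80
#' @export
line1Amplicon <- function() {
    filler <- function(n) substr(strrep("TGGAT", ceiling(n / 5)), 1, n)
    seq <- paste0(
        filler(62),    # positions 1..62
        "AATCGG",      # 63..68: CpG1 C at 66; unmethylated -> AATT, cut at 62
        filler(11),    # 69..79
        "TCGA",        # 80..83: CpG2 C at 81; methylated -> TaqI cut at 80
        filler(77))    # 84..160
    AmpliconSpec(seq, cpgPositions = c(66L, 81L),
                 forwardPrimer = "CCGTAAGGGGTTAGGGAGTTTTT",
                 reversePrimer = "RTAAAACCCTCCRAACCAAATATAAA")
}

#' Read an amplicon from a FASTA file
#'
#' Reads a single-record FASTA (uppercased) into an [AmpliconSpec-class].
#'
#' @param path FASTA file with exactly one record.
#' @param cpgPositions 1-based interrogated CpG cytosine positions.
#' @return An [AmpliconSpec-class].
#' @export
readAmpliconFasta <- function(path, cpgPositions = integer()) {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) != 1L)
        stop("expected exactly one FASTA record, found ", length(set))
    AmpliconSpec(toupper(as.character(set[[1]])), cpgPositions = cpgPositions)
}
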