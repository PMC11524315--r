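#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment (via \pkg{Biostrings}) returning the
#' summary statistics the family-assignment and duplication stages need:
#' the raw score, the aligned spans in both sequences, the identity of the
#' aligned region (matches / aligned columns, gap columns included) and the
#' coverage of the longer sequence (aligned length within the longer
#' sequence / its full length).
#'
#' @param a,b Character strings or \code{XString} objects of the same
#'   alphabet.
#' @param alphabet \code{"dna"} or \code{"protein"}.
#' @param match,mismatch DNA scoring (ignored for protein).
#' @param gapOpening,gapExtension Gap penalties (positive costs).
#' @param substitutionMatrix Protein substitution matrix name
#'   (default \code{"BLOSUM62"}; ignored for DNA).
#' @return A list with \code{score}, \code{span_a}, \code{span_b}
#'   (integer \code{c(start, end)}, 1-based inclusive), \code{identity} and
#'   \code{coverage_longer}.
#' @export
#' @examples
#' alignLocal("ACGTACGT", "ACGTTCGT")$identity  # 7/8
alignLocal <- function(a, b, alphabet = c("dna", "protein"),
                       match = 1, mismatch = -1,
                       gapOpening = 0, gapExtension = 2,
                       substitutionMatrix = "BLOSUM62") {
    alphabet <- match.arg(alphabet)
    a <- as.character(a); b <- as.character(b)
    if (!nzchar(a) || !nzchar(b))
        stop("cannot align empty sequences")
    if (alphabet == "dna") {
        sm <- Biostrings::nucleotideSubstitutionMatrix(
            match = match, mismatch = mismatch, baseOnly = FALSE)
        pat <- Biostrings::DNAString(a); sub <- Biostrings::DNAString(b)
    } else {
        sm <- substitutionMatrix
        pat <- Biostrings::AAString(a); sub <- Biostrings::AAString(b)
    }
    al <- Biostrings::pairwiseAlignment(
        pat, sub, type = "local", substitutionMatrix = sm,
        gapOpening = gapOpening, gapExtension = gapExtension)
    ncolAln <- Biostrings::nchar(al)
    nid <- Biostrings::nmatch(al)
    pr <- al@pattern@range
    sr <- al@subject@range
    spanA <- c(BiocGenerics::start(pr), BiocGenerics::end(pr))
    spanB <- c(BiocGenerics::start(sr), BiocGenerics::end(sr))
    lenA <- nchar(a); lenB <- nchar(b)
    alignedInLonger <- if (lenA >= lenB) diff(spanA) + 1L else diff(spanB) + 1L
    list(score = BiocGenerics::score(al),
         span_a = spanA,
         span_b = spanB,
         identity = nid / ncolAln,
         coverage_longer = alignedInLonger / max(lenA, lenB))
}

## Vectorized local-alignment statistics: one subject, many patterns.
## Same scoring as alignLocal(); returns one row per pattern.
.alignStatsSet <- function(patterns, subject, alphabet = c("dna", "protein"),
                           match = 1, mismatch = -1,
                           gapOpening = 0, gapExtension = 2,
                           substitutionMatrix = "BLOSUM62") {
    alphabet <- match.arg(alphabet)
    if (alphabet == "dna") {
        sm <- Biostrings::nucleotideSubstitutionMatrix(
            match = match, mismatch = mismatch, baseOnly = FALSE)
        if (!methods::is(patterns, "DNAStringSet"))
            patterns <- Biostrings::DNAStringSet(patterns)
        subject <- Biostrings::DNAString(as.character(subject))
    } else {
        sm <- substitutionMatrix
        if (!methods::is(patterns, "AAStringSet"))
            patterns <- Biostrings::AAStringSet(patterns)
        subject <- Biostrings::AAString(as.character(subject))
    }
    al <- Biostrings::pairwiseAlignment(
        patterns, subject, type = "local", substitutionMatrix = sm,
        gapOpening = gapOpening, gapExtension = gapExtension)
    lenP <- Biostrings::width(patterns)
    lenS <- length(subject)
    wP <- BiocGenerics::width(al@pattern@range)
    wS <- BiocGenerics::width(al@subject@range)
    alignedInLonger <- ifelse(lenP >= lenS, wP, wS)
    data.frame(score = BiocGenerics::score(al),
               identity = Biostrings::nmatch(al) / Biostrings::nchar(al),
               coverage_longer = alignedInLonger / pmax(lenP, lenS))
}
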