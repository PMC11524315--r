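#' Extract promoter sequences upstream of gene starts
#'
#' For a plus-strand gene the promoter is the \code{length} bases immediately
#' upstream of the annotated gene start (bases \code{[start - length,
#' start - 1]}, 1-based inclusive); for a minus-strand gene it is bases
#' \code{[end + 1, end + length]} reverse-complemented. Promoters running off
#' a chromosome edge are truncated (the shorter sequence is returned). The
#' annotated gene start stands in for the start codon, since the catalogue
#' model carries gene spans only.
#'
#' @param catalog A \code{\link{GeneCatalog}}.
#' @param chromSeqs Named \code{DNAStringSet} of chromosome sequences.
#' @param length Promoter length in bp (> 0), default 2000.
#' @return A \code{DNAStringSet} named by gene id (widths may be < length at
#'   chromosome edges; empty promoters are dropped).
#' @export
extractPromoter <- function(catalog, chromSeqs, length = 2000) {
    if (length <= 0) stop("promoter length must be > 0")
    df <- as.data.frame(catalog)
    miss <- setdiff(unique(df$chromosome), names(chromSeqs))
    if (base::length(miss))
        stop("missing chromosome sequence(s): ", paste(miss, collapse = ", "))
    proms <- lapply(seq_len(nrow(df)), function(k) {
        chrom <- chromSeqs[[df$chromosome[k]]]
        chrLen <- Biostrings::nchar(chrom)
        if (df$strand[k] == "+") {
            from <- max(1L, df$start[k] - length)
            to <- df$start[k] - 1L
            if (to < from) return(Biostrings::DNAString(""))
            Biostrings::subseq(chrom, from, to)
        } else {
            from <- df$end[k] + 1L
            to <- min(chrLen, df$end[k] + length)
            if (to < from) return(Biostrings::DNAString(""))
            Biostrings::reverseComplement(Biostrings::subseq(chrom, from, to))
        }
    })
    out <- Biostrings::DNAStringSet(proms)
    names(out) <- df$gene_id
    out[Biostrings::width(out) > 0]
}

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

.checkIupac <- function(motifs) {
    bad <- vapply(motifs, function(m)
        !grepl("^[ACGTRYSWKMBDHVN]+$", toupper(m)), NA)
    if (any(bad))
        stop("invalid IUPAC letter in motif(s): ",
             paste(motifs[bad], collapse = ", "))
}

#' Scan promoters for exact IUPAC motif occurrences
#'
#' Reports every position where a motif matches the promoter under IUPAC
#' degeneracy on the plus strand, and every position where its reverse
#' complement matches (reported as a minus-strand hit at the position of the
#' match on the plus-strand sequence). Overlapping occurrences are all
#' reported. An \code{N} in the promoter matches nothing.
#'
#' @param promoters Named \code{DNAStringSet} (or a single character
#'   string/\code{DNAString}).
#' @param motifs Named character vector (or motif-table data.frame from
#'   \code{\link{readMotifTable}}) of IUPAC DNA motifs.
#' @return data.frame with \code{gene_id}, \code{motif_id}, \code{motif},
#'   \code{offset} (0-based within the promoter) and \code{strand}.
#' @export
#' @examples
#' scanMotifs(c(p1 = "AAACGTAAA"), c(m = "ACGT"))
scanMotifs <- function(promoters, motifs) {
    if (is.data.frame(motifs))
        motifs <- stats::setNames(motifs$sequence, motifs$motif_id)
    if (is.null(names(motifs)))
        names(motifs) <- paste0("motif", seq_along(motifs))
    motifs <- toupper(motifs)
    .checkIupac(motifs)
    if (!methods::is(promoters, "DNAStringSet")) {
        nms <- names(promoters)
        promoters <- Biostrings::DNAStringSet(as.character(promoters))
        names(promoters) <- if (is.null(nms))
            paste0("seq", seq_along(promoters)) else nms
    }
    hits <- list()
    addHits <- function(gene, prom, motifId, motifSeq, pattern, strand) {
        if (nchar(pattern) > Biostrings::nchar(prom)) return()
        m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), prom,
                                      fixed = FALSE)
        if (base::length(m) == 0L) return()
        starts <- BiocGenerics::start(m)
        matched <- as.character(Biostrings::extractAt(
            prom, IRanges::IRanges(starts, width = nchar(pattern))))
        ok <- !grepl("[^ACGT]", matched)
        for (s in starts[ok])
            hits[[base::length(hits) + 1L]] <<- data.frame(
                gene_id = gene, motif_id = motifId, motif = motifSeq,
                offset = s - 1L, strand = strand, stringsAsFactors = FALSE)
    }
    for (g in seq_along(promoters)) {
        prom <- promoters[[g]]
        gene <- names(promoters)[g]
        for (k in seq_along(motifs)) {
            fwd <- motifs[[k]]
            rev <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(fwd)))
            addHits(gene, prom, names(motifs)[k], fwd, fwd, "+")
            addHits(gene, prom, names(motifs)[k], fwd, rev, "-")
        }
    }
    res <- if (base::length(hits)) do.call(rbind, hits)
           else data.frame(gene_id = character(), motif_id = character(),
                           motif = character(), offset = integer(),
                           strand = character(), stringsAsFactors = FALSE)
    res[order(res$gene_id, res$motif_id, res$offset, res$strand,
              method = "radix"), , drop = FALSE]
}

#' Motif frequency matrix by gene or family
#'
#' Aggregates motif hits into a count matrix with one row per gene (or per
#' family) and one column per motif. When a xylem-specific gene subset is
#' supplied, a second matrix restricted to those genes is returned as well.
#'
#' @param hits data.frame from \code{\link{scanMotifs}}.
#' @param grouping \code{"gene"} or \code{"family"}.
#' @param familyOf Named character vector gene id -> family (required for
#'   family grouping; also defines the full gene universe for zero rows).
#' @param xylemSubset Optional character vector of gene ids (must be a subset
#'   of the known genes).
#' @param motifIds Optional character vector fixing the column set (defaults
#'   to the motifs present in \code{hits}).
#' @return A count matrix, or (with \code{xylemSubset}) a list with
#'   \code{all} and \code{xylem} matrices.
#' @export
frequencyMatrix <- function(hits, grouping = c("gene", "family"),
                            familyOf = NULL, xylemSubset = NULL,
                            motifIds = NULL) {
    grouping <- match.arg(grouping)
    if (grouping == "family" && is.null(familyOf))
        stop("family grouping requires familyOf")
    genes <- if (!is.null(familyOf)) names(familyOf) else unique(hits$gene_id)
    if (!is.null(xylemSubset)) {
        unknown <- setdiff(xylemSubset, genes)
        if (length(unknown))
            stop("unknown gene id(s) in xylem subset: ",
                 paste(unknown, collapse = ", "))
    }
    if (is.null(motifIds)) motifIds <- sort(unique(hits$motif_id))
    build <- function(h) {
        rows <- if (grouping == "gene") factor(h$gene_id, levels = genes)
                else factor(familyOf[h$gene_id],
                            levels = sort(unique(familyOf)))
        m <- table(rows, factor(h$motif_id, levels = motifIds))
        matrix(as.integer(m), nrow = nrow(m),
               dimnames = list(rownames(m), colnames(m)))
    }
    out <- build(hits)
    if (is.null(xylemSubset)) return(out)
    list(all = out,
         xylem = build(hits[hits$gene_id %in% xylemSubset, , drop = FALSE]))
}
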