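#' Detect duplicated gene pairs by the 80/80 rule
#'
#' Every unordered pair of catalogue genes is locally aligned at the CDS
#' level (optionally protein) and kept when the aligned region covers
#' strictly more than \code{coverageThreshold} of the longer gene's sequence
#' AND the identity of the aligned region is strictly greater than
#' \code{identityThreshold}. Both inequalities are strict, so a pair sitting
#' exactly at 0.80 is rejected.
#'
#' @param catalog A \code{\link{GeneCatalog}}.
#' @param cds Named \code{DNAStringSet} (or \code{AAStringSet} with
#'   \code{alphabet = "protein"}) holding one sequence per catalogue gene.
#' @param identityThreshold,coverageThreshold Strict lower bounds,
#'   default 0.80.
#' @param withinFamily Only compare genes sharing a family label (the
#'   biological case; duplicates arise within families). Set \code{FALSE}
#'   to evaluate all pairs.
#' @param alphabet Alignment alphabet.
#' @return data.frame with columns \code{gene_a}, \code{gene_b}
#'   (\code{gene_a < gene_b} lexicographically), \code{identity},
#'   \code{coverage_longer}, \code{tandem} (initialised \code{NA}; see
#'   \code{\link{classifyTandem}}), sorted by \code{(gene_a, gene_b)}.
#' @export
detectDuplicates <- function(catalog, cds,
                             identityThreshold = 0.80,
                             coverageThreshold = 0.80,
                             withinFamily = TRUE,
                             alphabet = c("dna", "protein")) {
    alphabet <- match.arg(alphabet)
    ids <- geneIds(catalog)
    missing <- setdiff(ids, names(cds))
    if (length(missing))
        stop("missing sequence for gene(s): ", paste(missing, collapse = ", "))
    fam <- familyOf(catalog)
    out <- list()
    if (length(ids) >= 2L) {
        for (i in seq_len(length(ids) - 1L)) {
            later <- ids[seq(i + 1L, length(ids))]
            if (withinFamily) later <- later[fam[later] == fam[[ids[i]]]]
            if (!length(later)) next
            st <- .alignStatsSet(cds[later], cds[[ids[i]]],
                                 alphabet = alphabet)
            hit <- which(st$identity > identityThreshold &
                         st$coverage_longer > coverageThreshold)
            for (k in hit) {
                pair <- sort(c(ids[i], later[k]))
                out[[length(out) + 1L]] <- data.frame(
                    gene_a = pair[1], gene_b = pair[2],
                    identity = st$identity[k],
                    coverage_longer = st$coverage_longer[k],
                    tandem = NA, stringsAsFactors = FALSE)
            }
        }
    }
    res <- if (length(out)) do.call(rbind, out)
           else data.frame(gene_a = character(), gene_b = character(),
                           identity = numeric(), coverage_longer = numeric(),
                           tandem = logical(), stringsAsFactors = FALSE)
    res <- res[order(res$gene_a, res$gene_b), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Flag tandem duplicates
#'
#' A duplicated pair is tandem when both genes lie on the same chromosome
#' and the gap between them (end of the upstream gene to start of the
#' downstream gene) is at most \code{maxSeparationBp}. The threshold is a
#' package choice, exposed for tuning; 100 kb by default.
#'
#' @param pairs data.frame from \code{\link{detectDuplicates}}.
#' @param catalog The \code{\link{GeneCatalog}} providing coordinates.
#' @param maxSeparationBp Maximum allowed gap in bp.
#' @return \code{pairs} with the \code{tandem} column filled in.
#' @export
classifyTandem <- function(pairs, catalog, maxSeparationBp = 100000) {
    df <- as.data.frame(catalog)
    rownames(df) <- df$gene_id
    pairs$tandem <- vapply(seq_len(nrow(pairs)), function(k) {
        a <- df[pairs$gene_a[k], ]; b <- df[pairs$gene_b[k], ]
        if (a$chromosome != b$chromosome) return(FALSE)
        gap <- max(0, max(a$start, b$start) - min(a$end, b$end) - 1L)
        gap <= maxSeparationBp
    }, NA)
    pairs
}

.hotspotSpan <- function(starts, ends, i, j) {
    max(ends[i:j]) - starts[i] + 1
}

#' Scan chromosomes for lignin-gene hotspots
#'
#' A hotspot is a chromosomal region holding at least \code{minGenes}
#' family-assigned genes within a genomic span strictly under
#' \code{windowBp}. Per chromosome, genes are sorted by start and every
#' maximal run of consecutive genes satisfying both conditions is reported
#' (maximal: extending the run in either direction breaks the span bound).
#' The span runs from the first gene's start to the largest gene end in the
#' run. Reported regions are never nested, though distinct maximal runs may
#' overlap.
#'
#' @param catalog A \code{\link{GeneCatalog}}; unassigned genes are ignored.
#' @param minGenes Minimum genes per hotspot (default 5).
#' @param windowBp Strict upper bound on the region span in bp (default 5 Mb).
#' @return data.frame with \code{chromosome}, \code{start}, \code{end},
#'   \code{n_genes}, \code{members} (comma-separated gene ids sorted by
#'   start), ordered by chromosome then start.
#' @export
findHotspots <- function(catalog, minGenes = 5, windowBp = 5e6) {
    df <- as.data.frame(catalog)
    df <- df[df$family != "unassigned", , drop = FALSE]
    out <- list()
    for (chrom in sort(unique(df$chromosome))) {
        d <- df[df$chromosome == chrom, , drop = FALSE]
        d <- d[order(d$start, d$end, d$gene_id), , drop = FALSE]
        n <- nrow(d)
        if (n < minGenes) next
        runs <- list()
        for (i in seq_len(n - minGenes + 1L)) {
            jmax <- NA_integer_
            for (j in seq(i + minGenes - 1L, n)) {
                if (.hotspotSpan(d$start, d$end, i, j) < windowBp) jmax <- j
                else break
            }
            if (!is.na(jmax)) runs[[length(runs) + 1L]] <- c(i, jmax)
        }
        if (!length(runs)) next
        keep <- vapply(seq_along(runs), function(k) {
            !any(vapply(seq_along(runs), function(l) {
                l != k && runs[[l]][1] <= runs[[k]][1] &&
                    runs[[k]][2] <= runs[[l]][2]
            }, NA))
        }, NA)
        for (r in runs[keep]) {
            i <- r[1]; j <- r[2]
            out[[length(out) + 1L]] <- data.frame(
                chromosome = chrom,
                start = d$start[i],
                end = max(d$end[i:j]),
                n_genes = j - i + 1L,
                members = paste(d$gene_id[i:j], collapse = ","),
                stringsAsFactors = FALSE)
        }
    }
    res <- if (length(out)) do.call(rbind, out)
           else data.frame(chromosome = character(), start = integer(),
                           end = integer(), n_genes = integer(),
                           members = character(), stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res[order(res$chromosome, res$start), , drop = FALSE]
}
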