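#' Compute FPKM from raw counts
#'
#' FPKM normalises a fragment count for transcript length and sequencing
#' depth: \code{fpkm[g,s] = counts[g,s] * 1e9 / (length[g] * libsize[s])}
#' where \code{libsize[s]} is the total count of sample \code{s}.
#'
#' @param counts Non-negative integer gene x sample matrix with rownames.
#' @param geneLengths Numeric vector (bp), one per gene, recycled by name
#'   when named.
#' @param samples Sample sheet data.frame (\code{sample_id}, \code{genotype},
#'   \code{replicate}, \code{height_class}); rows match columns of
#'   \code{counts}.
#' @return An \code{\link{FPKMExperiment}} with \code{counts} and \code{fpkm}
#'   assays.
#' @export
computeFpkm <- function(counts, geneLengths, samples) {
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    if (!is.null(names(geneLengths)))
        geneLengths <- geneLengths[rownames(counts)]
    if (any(geneLengths <= 0) || anyNA(geneLengths))
        stop("gene lengths must be > 0 for every gene")
    lib <- colSums(counts)
    if (any(lib == 0)) stop("zero library size in sample(s): ",
                            paste(colnames(counts)[lib == 0], collapse = ", "))
    f <- sweep(counts * 1e9 / geneLengths, 2, lib, "/")
    FPKMExperiment(fpkm = f, geneLengths = unname(geneLengths),
                   samples = samples, counts = counts)
}

#' Filter to expressed genes
#'
#' A gene is kept when its FPKM is strictly greater than \code{minFpkm} in at
#' least one sample (one biological replicate suffices). The filter is
#' idempotent.
#'
#' @param x An \code{\link{FPKMExperiment}}.
#' @param minFpkm Strict threshold, default 1.0.
#' @return The row-subset \code{FPKMExperiment}.
#' @export
filterExpressed <- function(x, minFpkm = 1.0) {
    keep <- apply(fpkm(x), 1, max) > minFpkm
    x[keep, ]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: after sorting ascending,
#' \code{q_(i) = min over j >= i of p_(j) * m / j}, capped at 1, with the
#' original order restored.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values in the input order.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes between tall and short genotypes
#'
#' Per gene, a two-sided Welch t-test on \code{log2(FPKM + 1)} compares the
#' tall and short sample groups; the fold change is computed on shifted
#' group-mean FPKM, \code{log2fc = log2((mean_tall + 1) / (mean_short + 1))};
#' p-values are BH-adjusted. A gene is a DEG when \code{|log2fc| >=
#' log2(fcThreshold)} and \code{q < fdr}. Genes with identical values in both
#' groups get p = 1. The per-gene test is pluggable via \code{testFun}.
#'
#' @param x An \code{\link{FPKMExperiment}}, usually pre-filtered with
#'   \code{\link{filterExpressed}}.
#' @param fcThreshold Fold-change threshold on the natural scale (default 2).
#' @param fdr FDR level (default 0.05).
#' @param testFun Function \code{(tallValues, shortValues) -> p} applied to
#'   the log2(FPKM+1) values; defaults to the Welch t-test.
#' @return data.frame with \code{gene_id}, \code{mean_fpkm_tall},
#'   \code{mean_fpkm_short}, \code{log2fc}, \code{p_value}, \code{q_value},
#'   \code{is_deg}, \code{direction}.
#' @export
callDegs <- function(x, fcThreshold = 2, fdr = 0.05, testFun = NULL) {
    hc <- heightClass(x)
    tall <- which(hc == "tall"); short <- which(hc == "short")
    if (length(tall) < 2L || length(short) < 2L)
        stop("need at least 2 samples per height class")
    if (is.null(testFun))
        testFun <- function(a, b) {
            if (stats::sd(c(a, b)) < 1e-12 ||
                (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12 &&
                 abs(mean(a) - mean(b)) < 1e-12)) return(1)
            tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
        }
    f <- fpkm(x)
    lf <- log2(f + 1)
    meanTall <- rowMeans(f[, tall, drop = FALSE])
    meanShort <- rowMeans(f[, short, drop = FALSE])
    p <- vapply(seq_len(nrow(f)), function(g)
        testFun(lf[g, tall], lf[g, short]), 0)
    q <- bhAdjust(p)
    log2fc <- log2((meanTall + 1) / (meanShort + 1))
    isDeg <- abs(log2fc) >= log2(fcThreshold) & q < fdr
    data.frame(
        gene_id = rownames(f),
        mean_fpkm_tall = meanTall,
        mean_fpkm_short = meanShort,
        log2fc = log2fc,
        p_value = p,
        q_value = q,
        is_deg = isDeg,
        direction = ifelse(log2fc >= 0, "up_in_tall", "up_in_short"),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Heat table of log2(FPKM + 1)
#'
#' @param x An \code{\link{FPKMExperiment}}.
#' @return Numeric gene x sample matrix of \code{log2(fpkm + 1)}.
#' @export
expressionHeatTable <- function(x) log2(fpkm(x) + 1)

#' Format a DEG fraction the way results are reported
#'
#' @param nDeg Number of DEGs.
#' @param nTested Number of genes tested.
#' @return List with \code{percent} (numeric, 2 dp) and \code{text}
#'   (e.g. \code{"23 of 117 (19.66\%)"}).
#' @export
#' @examples
#' degFraction(23, 117)$text
degFraction <- function(nDeg, nTested) {
    pct <- round(100 * nDeg / nTested, 2)
    list(percent = pct,
         text = sprintf("%d of %d (%.2f%%)", nDeg, nTested, pct))
}
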