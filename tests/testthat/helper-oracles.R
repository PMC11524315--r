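## Independent oracles used across the suite. Each re-derives the quantity
## with the most literal method available (textbook DP, exhaustive
## enumeration, hand formulas) and never calls the implementation it checks.

## Textbook Smith-Waterman, pure R: best local-alignment score under
## match/mismatch scoring with a linear gap penalty.
swScoreOracle <- function(a, b, match = 1, mismatch = -1, gap = 2) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    H <- matrix(0, n + 1, m + 1)
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            s <- if (a[i] == b[j]) match else mismatch
            H[i + 1, j + 1] <- max(0,
                                   H[i, j] + s,
                                   H[i, j + 1] - gap,
                                   H[i + 1, j] - gap)
        }
    }
    max(H)
}

## Step-up FDR adjustment written straight from the definition.
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m))
        q[i] <- min(1, min(ps[i:m] * m / (i:m)))
    out <- numeric(m)
    out[o] <- q
    out
}

## Brute-force hotspot finder: enumerate every subinterval of the
## position-sorted gene list, keep qualifying ones, drop nested ones.
hotspotOracle <- function(df, minGenes = 5, windowBp = 5e6) {
    df <- df[df$family != "unassigned", , drop = FALSE]
    out <- list()
    for (chrom in unique(df$chromosome)) {
        d <- df[df$chromosome == chrom, , drop = FALSE]
        d <- d[order(d$start, d$end, d$gene_id), , drop = FALSE]
        n <- nrow(d)
        cand <- list()
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if (j - i + 1 < minGenes) next
            span <- max(d$end[i:j]) - d$start[i] + 1
            if (span < windowBp) cand[[length(cand) + 1]] <- c(i, j)
        }
        if (!length(cand)) next
        maximal <- Filter(function(r) {
            !any(vapply(cand, function(s)
                !identical(s, r) && s[1] <= r[1] && r[2] <= s[2], NA))
        }, cand)
        for (r in maximal)
            out[[length(out) + 1]] <- data.frame(
                chromosome = chrom, start = d$start[r[1]],
                end = max(d$end[r[1]:r[2]]), n_genes = r[2] - r[1] + 1,
                members = paste(d$gene_id[r[1]:r[2]], collapse = ","),
                stringsAsFactors = FALSE)
    }
    res <- if (length(out)) do.call(rbind, out)
           else data.frame(chromosome = character(), start = integer(),
                           end = integer(), n_genes = integer(),
                           members = character(), stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res[order(res$chromosome, res$start), , drop = FALSE]
}

## Position-by-position IUPAC scan with explicit base-set comparison.
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

revcompIupac <- function(motif) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
              S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
              D = "H", H = "D", N = "N")
    paste(rev(comp[strsplit(motif, "")[[1]]]), collapse = "")
}

naiveScanOracle <- function(prom, motif) {
    promB <- strsplit(prom, "")[[1]]
    matchAt <- function(pat, off) {
        patB <- strsplit(pat, "")[[1]]
        all(vapply(seq_along(patB), function(k) {
            b <- promB[off + k]
            b %in% IUPAC_SETS[[patB[k]]]  # N in promoter matches nothing
        }, NA))
    }
    hits <- list()
    w <- nchar(motif)
    if (w <= length(promB)) {
        rc <- revcompIupac(motif)
        for (off in 0:(length(promB) - w)) {
            if (matchAt(motif, off))
                hits[[length(hits) + 1]] <- data.frame(offset = off,
                                                       strand = "+")
            if (matchAt(rc, off))
                hits[[length(hits) + 1]] <- data.frame(offset = off,
                                                       strand = "-")
        }
    }
    if (length(hits)) do.call(rbind, hits)
    else data.frame(offset = integer(), strand = character())
}

## Monophyly via rooting at an outside leaf (independent of the package's
## bipartition machinery).
monophylyOracle <- function(tree, leaves) {
    outside <- setdiff(tree$tip.label, leaves)
    if (!length(outside) || !length(leaves)) return(TRUE)
    if (length(leaves) == 1) return(TRUE)
    rooted <- ape::root(tree, outgroup = outside[1], resolve.root = TRUE)
    ape::is.monophyletic(rooted, leaves)
}

classifyOracle <- function(tree, groupOf) {
    groups <- groupOf[tree$tip.label]
    mono <- function(g) {
        tips <- tree$tip.label[groups == g]
        length(tips) > 0 && monophylyOracle(tree, tips)
    }
    if (mono("monocot") && mono("herb_dicot") && mono("woody")) return("Ib")
    if (mono("monocot")) return("Ia")
    "II"
}

## Random CDS-like sequence and controlled-identity copies for duplication
## boundary tests: substitutions every floor(L/m) positions, flanks intact,
## so the full-length local alignment has identity exactly (L - m) / L.
randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

mutateExact <- function(seq, nSub, flank = 5) {
    b <- strsplit(seq, "")[[1]]
    L <- length(b)
    pos <- round(seq(flank + 1, L - flank, length.out = nSub))
    stopifnot(!anyDuplicated(pos))
    for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
    paste(b, collapse = "")
}

## Tiny catalogue builder for layout-level tests (no sequences needed).
toyCatalog <- function(starts, lens = 1000, chrom = "A01",
                       family = "PAL", strand = "+") {
    n <- length(starts)
    GeneCatalog(data.frame(
        gene_id = sprintf("g%02d", seq_len(n)),
        chromosome = rep_len(chrom, n),
        start = starts,
        end = starts + rep_len(lens, n) - 1,
        strand = rep_len(strand, n),
        family = rep_len(family, n),
        stringsAsFactors = FALSE))
}
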