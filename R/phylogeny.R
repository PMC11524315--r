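## Distance-based family phylogenies: Poisson-corrected pairwise-deletion
## distances, neighbor joining, column-resampling bootstrap, and family-class
## calling from group monophyly on the unrooted topology.

.msaMatrix <- function(msa) {
    if (methods::is(msa, "XStringSet")) {
        if (length(unique(Biostrings::width(msa))) != 1L)
            stop("alignment rows must all have the same length")
        m <- do.call(rbind, strsplit(as.character(msa), ""))
        rownames(m) <- names(msa)
    } else if (is.matrix(msa)) {
        m <- msa
    } else {
        if (length(unique(nchar(msa))) != 1L)
            stop("alignment rows must all have the same length")
        m <- do.call(rbind, strsplit(as.character(msa), ""))
        rownames(m) <- names(msa)
    }
    toupper(m)
}

#' Pairwise distances under pairwise deletion
#'
#' For each sequence pair, alignment columns where either sequence has a gap
#' (\code{-}) are excluded (pairwise deletion), \code{p} is the fraction of
#' differing sites among the remaining columns, and the Poisson-corrected
#' distance is \code{d = -ln(1 - p)} (the \code{"p"} model returns \code{p}
#' itself). The Poisson correction accounts for multiple substitutions at a
#' site under a uniform-rate model.
#'
#' @param msa Aligned sequences: a named character vector, a character
#'   matrix (rows = sequences), or an \code{XStringSet} of equal widths.
#' @param model \code{"poisson"} (default) or \code{"p"}.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = sequence
#'   ids.
#' @export
#' @examples
#' pairwiseDistance(c(a = "AC-T", b = "AG-T"), model = "p")["a", "b"]  # 1/3
pairwiseDistance <- function(msa, model = c("poisson", "p")) {
    model <- match.arg(model)
    m <- .msaMatrix(msa)
    n <- nrow(m)
    if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(n))
    D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
            ok <- m[i, ] != "-" & m[j, ] != "-"
            if (!any(ok))
                stop("no comparable sites for pair (", rownames(m)[i], ", ",
                     rownames(m)[j], ")")
            p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
            if (model == "poisson") {
                if (p >= 1)
                    stop("Poisson correction undefined (p >= 1) for pair (",
                         rownames(m)[i], ", ", rownames(m)[j], ")")
                d <- -log(1 - p)
            } else d <- p
            D[i, j] <- D[j, i] <- d
        }
    }
    D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \code{\link[ape]{nj}}). For an
#' additive distance matrix the generating unrooted topology is recovered
#' exactly.
#'
#' @param D Symmetric numeric matrix, zero diagonal, n >= 3, with dimnames.
#' @return An unrooted \code{phylo} tree.
#' @export
njTree <- function(D) {
    D <- as.matrix(D)
    if (anyNA(D)) stop("distance matrix contains NA/NaN")
    if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
        stop("distance matrix must be symmetric")
    if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
    if (nrow(D) < 3L) stop("need at least 3 taxa")
    ape::nj(D)
}

## Normalized bipartition keys of a tree: one key per node side (descendant
## leaf set), normalized so that the side not containing the first leaf (in
## sorted label order) represents the split.
.splitKeys <- function(tree, internalOnly = FALSE) {
    labels <- sort(tree$tip.label)
    anchor <- labels[1]
    pp <- ape::prop.part(tree)
    tips <- attr(pp, "labels")
    sides <- lapply(pp, function(idx) tips[idx])
    if (!internalOnly)
        sides <- c(sides, as.list(tree$tip.label))
    keys <- vapply(sides, function(side) {
        if (anchor %in% side) side <- setdiff(labels, side)
        paste(sort(side), collapse = "\r")
    }, "")
    unique(keys[nzchar(keys)])
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement \code{nReps} times; for
#' each replicate a Poisson-NJ tree is rebuilt and the support of each
#' internal edge of the reference tree is the percentage of replicate trees
#' containing the same bipartition. Deterministic given \code{seed}.
#'
#' @param msa Aligned sequences (see \code{\link{pairwiseDistance}}).
#' @param nReps Number of bootstrap replicates (>= 1); 1000 is conventional.
#' @param seed Integer RNG seed (required).
#' @param model Distance model passed to \code{\link{pairwiseDistance}}.
#' @return List with \code{tree} (the reference \code{phylo}) and
#'   \code{support}: a data.frame of internal-edge bipartitions (leaf set of
#'   one side, \code{|}-separated) and their support in [0, 100].
#' @export
bootstrapSupport <- function(msa, nReps = 1000, seed, model = "poisson") {
    if (missing(seed)) stop("a seed is required")
    if (nReps < 1) stop("nReps must be >= 1")
    m <- .msaMatrix(msa)
    tree <- njTree(pairwiseDistance(m, model = model))
    refKeys <- .splitKeys(tree, internalOnly = TRUE)
    ## internal (non-trivial) splits only: drop singleton and (n-1) sides
    n <- nrow(m)
    sizeOf <- function(key) length(strsplit(key, "\r", fixed = TRUE)[[1]])
    refKeys <- refKeys[vapply(refKeys, sizeOf, 0L) >= 2 &
                       vapply(refKeys, sizeOf, 0L) <= n - 2]
    hits <- stats::setNames(numeric(length(refKeys)), refKeys)
    set.seed(seed)
    for (r in seq_len(nReps)) {
        cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
        repTree <- njTree(pairwiseDistance(m[, cols, drop = FALSE],
                                           model = model))
        repKeys <- .splitKeys(repTree, internalOnly = TRUE)
        hits[refKeys %in% repKeys] <- hits[refKeys %in% repKeys] + 1
    }
    support <- data.frame(
        bipartition = vapply(refKeys, function(k)
            gsub("\r", "|", k, fixed = TRUE), ""),
        support = 100 * hits / nReps,
        row.names = NULL, stringsAsFactors = FALSE)
    list(tree = tree, support = support)
}

#' Is a leaf group monophyletic on an unrooted tree?
#'
#' True when the group's leaves form one side of some bipartition of the
#' tree (equivalently, the group is a clade under some rooting).
#'
#' @param tree A \code{phylo} tree.
#' @param leaves Character vector of tip labels.
#' @return Logical.
#' @export
isMonophyletic <- function(tree, leaves) {
    leaves <- unique(leaves)
    if (!all(leaves %in% tree$tip.label))
        stop("unknown tip label(s): ",
             paste(setdiff(leaves, tree$tip.label), collapse = ", "))
    if (length(leaves) <= 1L || length(leaves) >= length(tree$tip.label))
        return(TRUE)
    labels <- sort(tree$tip.label)
    side <- if (labels[1] %in% leaves) setdiff(labels, leaves) else leaves
    key <- paste(sort(side), collapse = "\r")
    key %in% .splitKeys(tree, internalOnly = FALSE)
}

#' Classify a family tree into Class Ia, Ib or II
#'
#' The nine species fall into three groups: herbaceous monocots
#' (\code{"monocot"}), herbaceous dicots (\code{"herb_dicot"}) and woody
#' plants (\code{"woody"}). A family is Class Ib when all three groups are
#' simultaneously monophyletic (the tree resolves into three pure lineages);
#' Class Ia when the monocots are monophyletic but the herbaceous dicots
#' group with the woody sequences rather than forming their own lineage;
#' and Class II (an expanded family) when the groups interleave. The call is
#' a function of the unrooted topology only, so it is invariant to leaf
#' order and re-rooting.
#'
#' @param tree A \code{phylo} tree.
#' @param groupOf Named character vector mapping every tip label to
#'   \code{"monocot"}, \code{"herb_dicot"} or \code{"woody"}.
#' @return \code{"Ia"}, \code{"Ib"} or \code{"II"}.
#' @export
classifyFamily <- function(tree, groupOf) {
    miss <- setdiff(tree$tip.label, names(groupOf))
    if (length(miss))
        stop("leaf without group label: ", paste(miss, collapse = ", "))
    groups <- groupOf[tree$tip.label]
    bad <- setdiff(unique(groups), c("monocot", "herb_dicot", "woody"))
    if (length(bad))
        stop("unknown group label(s): ", paste(bad, collapse = ", "))
    mono <- function(g) {
        tips <- tree$tip.label[groups == g]
        length(tips) > 0L && isMonophyletic(tree, tips)
    }
    if (mono("monocot") && mono("herb_dicot") && mono("woody")) return("Ib")
    if (mono("monocot")) return("Ia")
    "II"
}
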