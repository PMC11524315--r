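#' Reference set for one gene family
#'
#' Bundles the known member sequences of a family with the short protein
#' patterns that act as a required-domain gate (presence/absence of an
#' essential domain, checked by exact substring match).
#'
#' @param family Family label (one of \code{\link{monolignolFamilies}()}).
#' @param members Named \code{AAStringSet} (or \code{DNAStringSet}) of
#'   reference member sequences; at least one.
#' @param requiredMotifs Character vector of non-empty patterns; at least one.
#' @return A \code{FamilyReference} (a validated list).
#' @export
familyReference <- function(family, members, requiredMotifs) {
    if (!family %in% monolignolFamilies())
        stop("unknown family label: ", family)
    if (length(members) < 1L) stop("family ", family, " needs >= 1 member")
    if (length(requiredMotifs) < 1L || any(!nzchar(requiredMotifs)))
        stop("family ", family, " needs non-empty required motifs")
    structure(list(family = family, members = members,
                   required_motifs = requiredMotifs),
              class = "FamilyReference")
}

#' Assign a query sequence to a monolignol family
#'
#' The query is locally aligned against every member of every reference
#' family; the winning family is the one holding the best-scoring member
#' alignment, provided that score reaches \code{minScore}. Ties on score are
#' broken by higher identity, then by lexicographic family label. When
#' \code{requireDomain} is \code{TRUE} the query must additionally contain at
#' least one of the winning family's required motifs as an exact substring,
#' otherwise \code{"unassigned"} is returned.
#'
#' @param query Character string or \code{XString}: the candidate sequence.
#' @param refs List of \code{\link{familyReference}} objects covering the
#'   families to score against.
#' @param minScore Minimum raw alignment score for any assignment.
#' @param requireDomain Gate assignments on required-motif presence.
#' @param alphabet \code{"protein"} (default) or \code{"dna"}.
#' @return A family label, or \code{"unassigned"}.
#' @export
assignFamily <- function(query, refs, minScore = 100,
                         requireDomain = TRUE,
                         alphabet = c("protein", "dna")) {
    alphabet <- match.arg(alphabet)
    query <- as.character(query)
    best <- data.frame(family = character(), score = numeric(),
                       identity = numeric(), stringsAsFactors = FALSE)
    for (ref in refs) {
        st <- .alignStatsSet(ref$members, query, alphabet = alphabet)
        k <- which.max(st$score)
        best <- rbind(best, data.frame(family = ref$family,
                                       score = st$score[k],
                                       identity = st$identity[k],
                                       stringsAsFactors = FALSE))
    }
    best <- best[best$score >= minScore, , drop = FALSE]
    if (nrow(best) == 0L) return("unassigned")
    best <- best[order(-best$score, -best$identity, best$family), , drop = FALSE]
    winner <- best[1, ]
    if (requireDomain) {
        motifs <- refs[[which(vapply(refs, `[[`, "", "family") == winner$family)]]$required_motifs
        if (!any(vapply(motifs, function(m) grepl(m, query, fixed = TRUE), NA)))
            return("unassigned")
    }
    winner$family
}

#' Family count table by species or sub-genome
#'
#' Tabulates assigned genes per (group, family), mirroring the layout of a
#' per-species family count table: one row per group, one column per family,
#' plus a \code{Total} column. Genes labelled \code{"unassigned"} are not
#' counted (they belong to no family); any other unknown label is an error.
#'
#' @param catalog A \code{\link{GeneCatalog}}, or a data.frame with
#'   \code{family} plus \code{species}/\code{subgenome} columns.
#' @param groupBy \code{"subgenome"} or \code{"species"}.
#' @param species Species label used for every record when the catalogue
#'   carries none (single-species catalogues).
#' @return data.frame: group rows, 11 family columns, \code{Total}.
#' @export
countTable <- function(catalog, groupBy = c("subgenome", "species"),
                       species = "catalogue") {
    groupBy <- match.arg(groupBy)
    df <- if (methods::is(catalog, "GeneCatalog")) as.data.frame(catalog)
          else catalog
    bad <- setdiff(unique(df$family), .validFamilyLabels())
    if (length(bad))
        stop("unknown family label(s): ", paste(bad, collapse = ", "))
    if (groupBy == "species" && !"species" %in% colnames(df))
        df$species <- species
    df <- df[df$family != "unassigned", , drop = FALSE]
    groups <- df[[groupBy]]
    fams <- monolignolFamilies()
    tab <- table(factor(groups, levels = sort(unique(groups))),
                 factor(df$family, levels = fams))
    out <- as.data.frame.matrix(tab)
    out <- cbind(data.frame(group = rownames(out), stringsAsFactors = FALSE),
                 out)
    rownames(out) <- NULL
    out$Total <- rowSums(out[, fams, drop = FALSE])
    out
}

#' Row totals of a family count table
#'
#' Sums the 11 family columns per row of a count table such as
#' \code{\link{referenceFamilyCounts}()}.
#'
#' @param tab data.frame whose columns include the 11 family labels and a
#'   row-identifier column (\code{species} or \code{group}).
#' @return Named numeric vector of per-row totals.
#' @export
familyCountTotals <- function(tab) {
    fams <- monolignolFamilies()
    miss <- setdiff(fams, colnames(tab))
    if (length(miss))
        stop("count table missing family column(s): ", paste(miss, collapse = ", "))
    labcol <- intersect(c("species", "group"), colnames(tab))[1]
    stats::setNames(rowSums(tab[, fams, drop = FALSE]), tab[[labcol]])
}
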