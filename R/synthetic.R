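## Seeded synthetic-study generator: an artificial tetraploid genome split
## into At/Bt sub-genomes, family sequences with planted duplicate pairs,
## tandem clusters and hotspots, negative-binomial RNA-seq counts with
## planted DEGs, phenotypes with a controlled height-lignin correlation, and
## 2000-bp promoters with planted motif hits. Every entity is recorded in a
## ground-truth object so downstream stages can be validated end to end.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

## Synthetic stand-ins for the essential-domain patterns of each family
## (exact 8-mer peptides planted into every family member).
.DOMAIN_MOTIFS <- c(
    PAL     = "GTITASGD", C4H  = "WKLVFAPR", `4CL` = "GEICIRGH",
    HCT     = "NCVAVGEV", C3H  = "FLLAGRDP", CSE   = "YREAPNWL",
    COMT    = "MGSTNEDQ", F5H  = "PHVALSRM", CCoAOMT = "EKDTWAMN",
    CCR     = "VVDVCSSG", CAD  = "GLGGVGHM")

.revTranslate <- function(protein) {
    codonsOf <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
    aas <- strsplit(protein, "")[[1]]
    paste(vapply(aas, function(a) {
        cods <- codonsOf[[a]]
        cods[sample.int(length(cods), 1L)]
    }, ""), collapse = "")
}

.mutateProtein <- function(protein, rate, protect = integer()) {
    aas <- strsplit(protein, "")[[1]]
    idx <- setdiff(seq_along(aas), protect)
    hit <- idx[stats::runif(length(idx)) < rate]
    for (i in hit) aas[i] <- sample(setdiff(.AA20, aas[i]), 1L)
    paste(aas, collapse = "")
}

.STOPS <- c("TAA", "TAG", "TGA")

## Substitutions only, spread evenly over the allowed positions, so the
## full-length local alignment has identity exactly (L - m) / L.
.mutateCdsToIdentity <- function(cds, identity, protectBp = integer()) {
    bases <- strsplit(cds, "")[[1]]
    L <- length(bases)
    m <- round((1 - identity) * L)
    if (m == 0L) return(cds)
    flank <- 9L
    allowed <- setdiff(seq(flank + 1L, L - flank), protectBp)
    if (m > length(allowed))
        stop("cannot place ", m, " substitutions in ", length(allowed),
             " allowed positions")
    pos <- allowed[unique(round(seq(1, length(allowed), length.out = m)))]
    for (p in pos) {
        codon0 <- (p - 1L) %/% 3L
        for (b in sample(setdiff(c("A", "C", "G", "T"), bases[p]))) {
            old <- bases[p]; bases[p] <- b
            codon <- paste(bases[(codon0 * 3L + 1L):(codon0 * 3L + 3L)],
                           collapse = "")
            if (!codon %in% .STOPS) break
            bases[p] <- old
        }
    }
    paste(bases, collapse = "")
}

#' Default specifications for the synthetic genome
#'
#' \code{defaultHotspotSpec()} plants two hotspots: six COMT genes within
#' 3 Mb on chromosome B16 and five HCT genes within 4 Mb on chromosome A08
#' (mirroring the kind of clustering seen in real willow chromosomes).
#' \code{defaultDuplicateSpec()} plants four duplicate pairs spanning the
#' interesting identity range, two of them tandem.
#'
#' @return data.frame specs consumed by \code{\link{generateGenome}}.
#' @export
defaultHotspotSpec <- function() {
    data.frame(chromosome = c("B16", "A08"),
               family = c("COMT", "HCT"),
               n = c(6L, 5L),
               span_bp = c(3e6, 4e6),
               stringsAsFactors = FALSE)
}

#' @rdname defaultHotspotSpec
#' @export
defaultDuplicateSpec <- function() {
    data.frame(family = c("HCT", "CAD", "COMT", "CCR"),
               identity = c(0.90, 0.85, 0.95, 0.85),
               coverage = c(1.0, 1.0, 1.0, 0.9),
               tandem = c(TRUE, TRUE, FALSE, FALSE),
               stringsAsFactors = FALSE)
}

#' Generate a synthetic tetraploid monolignol gene catalogue
#'
#' Builds 38 chromosomes (A01-A19, B01-B19, 10-20 Mb), founder protein
#' sequences for the 11 families (each carrying a fixed 8-mer domain motif),
#' \code{genesPerFamily} members per family derived from the founder by
#' protein-level substitutions and independent reverse translation, planted
#' duplicate pairs created by copying a parent CDS and applying evenly spread
#' nucleotide substitutions to hit the target identity (coverage controlled
#' by truncating the copy), planted hotspots, and a few unplaced genes on
#' scaffolds. Background genes are spaced at least 1.7 Mb apart on a
#' chromosome (and hotspot chromosomes carry hotspot genes only) so the only
#' regions satisfying the 5-genes-in-under-5-Mb rule are the planted ones.
#' Deterministic given \code{seed}.
#'
#' @param seed Integer RNG seed.
#' @param nChromPerSubgenome Chromosomes per sub-genome (default 19).
#' @param genesPerFamily Members per family (default 18, ~198 genes).
#' @param hotspotSpec data.frame like \code{\link{defaultHotspotSpec}()}.
#' @param duplicateSpec data.frame like \code{\link{defaultDuplicateSpec}()}.
#' @param nUnplaced Number of unplaced scaffold genes (default 6).
#' @param memberMutationRate Protein substitution rate between a founder and
#'   a member (default 0.15).
#' @return List with \code{catalog} (\code{\link{GeneCatalog}}),
#'   \code{proteins} (\code{AAStringSet}), \code{cds} (\code{DNAStringSet}),
#'   \code{references} (list of \code{\link{familyReference}}),
#'   \code{chromLengths}, and \code{truth} (list with \code{family_of},
#'   \code{duplicate_pairs}, \code{hotspots}).
#' @export
generateGenome <- function(seed,
                           nChromPerSubgenome = 19L,
                           genesPerFamily = 18L,
                           hotspotSpec = defaultHotspotSpec(),
                           duplicateSpec = defaultDuplicateSpec(),
                           nUnplaced = 6L,
                           memberMutationRate = 0.15) {
    if (any(duplicateSpec$identity > 1 | duplicateSpec$identity <= 0))
        stop("duplicate identities must lie in (0, 1]")
    if (any(duplicateSpec$coverage > 1 | duplicateSpec$coverage <= 0))
        stop("duplicate coverages must lie in (0, 1]")
    if (any(hotspotSpec$n < 5L))
        stop("hotspots must contain at least 5 genes")
    if (any(hotspotSpec$n > genesPerFamily))
        stop("hotspot gene counts exceed genesPerFamily")
    if (any(hotspotSpec$span_bp >= 5e6))
        stop("hotspot spans must be under 5 Mb")
    set.seed(seed)

    chroms <- c(sprintf("A%02d", seq_len(nChromPerSubgenome)),
                sprintf("B%02d", seq_len(nChromPerSubgenome)))
    chromLen <- stats::setNames(round(stats::runif(length(chroms), 10e6, 20e6)),
                                chroms)

    fams <- monolignolFamilies()
    ## founders: random proteins with the family domain motif at position 10
    founders <- stats::setNames(vapply(fams, function(f) {
        len <- sample(200:320, 1L)
        aas <- sample(.AA20, len, replace = TRUE)
        motif <- strsplit(.DOMAIN_MOTIFS[[f]], "")[[1]]
        aas[10:(9 + length(motif))] <- motif
        paste(aas, collapse = "")
    }, ""), fams)
    protectAa <- 10:17

    geneIds <- character(); geneFam <- character()
    proteins <- character(); cds <- character()
    for (f in fams) {
        for (k in seq_len(genesPerFamily)) {
            id <- sprintf("Sm%s%02d", f, k)
            prot <- .mutateProtein(founders[[f]], memberMutationRate, protectAa)
            geneIds <- c(geneIds, id); geneFam <- c(geneFam, f)
            proteins <- c(proteins, prot)
            cds <- c(cds, .revTranslate(prot))
        }
    }
    names(proteins) <- names(cds) <- geneIds
    famOf <- stats::setNames(geneFam, geneIds)

    ## planted duplicates: copy a parent CDS, truncate to the coverage
    ## fraction, substitute to the target identity (domain codons protected)
    dupTruth <- NULL
    for (k in seq_len(nrow(duplicateSpec))) {
        f <- duplicateSpec$family[k]
        parent <- geneIds[famOf[geneIds] == f][k]  # distinct parents per family
        childId <- paste0(parent, "d")
        pc <- cds[[parent]]
        keepBp <- floor(nchar(pc) * duplicateSpec$coverage[k] / 3) * 3
        child <- substr(pc, 1L, keepBp)
        protectBp <- (protectAa[1] * 3L - 2L):(protectAa[length(protectAa)] * 3L)
        child <- .mutateCdsToIdentity(child, duplicateSpec$identity[k], protectBp)
        prot <- as.character(Biostrings::translate(
            Biostrings::DNAString(child), if.fuzzy.codon = "solve"))
        geneIds <- c(geneIds, childId)
        famOf[childId] <- f
        proteins[childId] <- prot
        cds[childId] <- child
        pair <- sort(c(parent, childId))
        dupTruth <- rbind(dupTruth, data.frame(
            gene_a = pair[1], gene_b = pair[2],
            identity = duplicateSpec$identity[k],
            coverage = duplicateSpec$coverage[k],
            tandem = duplicateSpec$tandem[k],
            parent = parent, child = childId,
            stringsAsFactors = FALSE))
    }

    ## a few unplaced scaffold genes
    unplacedIds <- character()
    if (nUnplaced > 0L) {
        for (k in seq_len(nUnplaced)) {
            f <- fams[(k - 1L) %% length(fams) + 1L]
            id <- sprintf("SmU%s%02d", f, k)
            prot <- .mutateProtein(founders[[f]], memberMutationRate, protectAa)
            geneIds <- c(geneIds, id); famOf[id] <- f
            proteins[id] <- prot; cds[id] <- .revTranslate(prot)
            unplacedIds <- c(unplacedIds, id)
        }
    }

    geneLen <- stats::setNames(nchar(cds), names(cds))

    ## --- placement ---
    hotChrom <- hotspotSpec$chromosome
    placed <- data.frame(gene_id = character(), chromosome = character(),
                         start = integer(), end = integer(),
                         stringsAsFactors = FALSE)
    addPlacement <- function(id, chrom, start) {
        rbind(placed, data.frame(gene_id = id, chromosome = chrom,
                                 start = as.integer(start),
                                 end = as.integer(start + geneLen[[id]] - 1L),
                                 stringsAsFactors = FALSE))
    }

    hotspotTruth <- NULL
    hotspotGenes <- character()
    for (k in seq_len(nrow(hotspotSpec))) {
        f <- hotspotSpec$family[k]; n <- hotspotSpec$n[k]
        members <- setdiff(geneIds[famOf[geneIds] == f & !geneIds %in% unplacedIds],
                           c(dupTruth$child, hotspotGenes))
        members <- members[seq(length(members) - n + 1L, length(members))]
        hotspotGenes <- c(hotspotGenes, members)
        s0 <- 1e6
        spacing <- floor((hotspotSpec$span_bp[k] - max(geneLen[members]) - 1e4) /
                         (n - 1L))
        starts <- s0 + (seq_len(n) - 1L) * spacing
        for (i in seq_len(n)) placed <- addPlacement(members[i], hotspotSpec$chromosome[k],
                                                     starts[i])
        hotspotTruth <- rbind(hotspotTruth, data.frame(
            chromosome = hotspotSpec$chromosome[k],
            start = as.integer(starts[1]),
            end = as.integer(starts[n] + geneLen[[members[n]]] - 1L),
            n_genes = n,
            members = paste(members, collapse = ","),
            stringsAsFactors = FALSE))
    }

    bgChroms <- setdiff(chroms, hotChrom)
    cursor <- stats::setNames(round(stats::runif(length(bgChroms), 5e5, 1.5e6)),
                              bgChroms)
    hasTandem <- stats::setNames(rep(FALSE, length(bgChroms)), bgChroms)
    tandemChildOf <- stats::setNames(dupTruth$child[dupTruth$tandem],
                                     dupTruth$parent[dupTruth$tandem])
    tandemChildren <- unname(tandemChildOf)
    bgGenes <- setdiff(geneIds, c(hotspotGenes, unplacedIds, tandemChildren))
    for (id in bgGenes) {
        needsTandemRoom <- id %in% names(tandemChildOf)
        childLen <- if (needsTandemRoom) geneLen[[tandemChildOf[[id]]]] + 20000L else 0L
        eligible <- bgChroms[cursor + geneLen[[id]] + childLen + 5e5 <=
                             chromLen[bgChroms]]
        if (needsTandemRoom) eligible <- eligible[!hasTandem[eligible]]
        if (!length(eligible)) stop("could not place gene ", id)
        chrom <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
        start <- cursor[[chrom]]
        placed <- addPlacement(id, chrom, start)
        pos <- start + geneLen[[id]]
        if (needsTandemRoom) {
            childId <- tandemChildOf[[id]]
            childStart <- pos + 20000L
            placed <- addPlacement(childId, chrom, childStart)
            pos <- childStart + geneLen[[childId]]
            hasTandem[chrom] <- TRUE
        }
        cursor[chrom] <- pos + 1.7e6 + stats::runif(1, 0, 5e5)
    }
    ## non-tandem duplicate children go in as ordinary background genes
    for (id in setdiff(dupTruth$child[!dupTruth$tandem], placed$gene_id)) {
        eligible <- bgChroms[cursor + geneLen[[id]] + 5e5 <= chromLen[bgChroms]]
        chrom <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
        placed <- addPlacement(id, chrom, cursor[[chrom]])
        cursor[chrom] <- cursor[[chrom]] + geneLen[[id]] + 1.7e6 +
            stats::runif(1, 0, 5e5)
    }
    for (k in seq_along(unplacedIds)) {
        id <- unplacedIds[k]
        placed <- addPlacement(id, sprintf("scaffold_%d", k), 1L)
    }

    placed <- placed[match(geneIds, placed$gene_id), ]
    df <- data.frame(gene_id = placed$gene_id,
                     chromosome = placed$chromosome,
                     start = placed$start, end = placed$end,
                     strand = sample(c("+", "-"), nrow(placed), replace = TRUE),
                     family = unname(famOf[placed$gene_id]),
                     stringsAsFactors = FALSE)
    catalog <- GeneCatalog(df)

    ## references: founder plus two extra reference members per family
    references <- lapply(fams, function(f) {
        refs <- c(founders[[f]],
                  .mutateProtein(founders[[f]], memberMutationRate, protectAa),
                  .mutateProtein(founders[[f]], memberMutationRate, protectAa))
        members <- Biostrings::AAStringSet(refs)
        names(members) <- paste0("ref_", f, "_", seq_along(refs))
        familyReference(f, members, .DOMAIN_MOTIFS[[f]])
    })

    list(catalog = catalog,
         proteins = Biostrings::AAStringSet(proteins),
         cds = Biostrings::DNAStringSet(cds),
         references = references,
         chromLengths = chromLen,
         truth = list(
             family_of = famOf,
             duplicate_pairs = if (is.null(dupTruth)) data.frame()
                 else dupTruth[order(dupTruth$gene_a), ],
             hotspots = if (is.null(hotspotTruth)) data.frame()
                 else hotspotTruth[order(hotspotTruth$chromosome), ]))
}

#' Default sample sheet for the synthetic study
#'
#' Two parents and two F1 progeny of contrasting height, three biological
#' replicates each: short 'Yanjiang' and 'FS', tall '9901' and 'FH'.
#'
#' @return data.frame with \code{sample_id}, \code{genotype},
#'   \code{replicate}, \code{height_class}.
#' @export
defaultSampleSheet <- function() {
    genotypes <- c(Yanjiang = "short", FS = "short",
                   `9901` = "tall", FH = "tall")
    do.call(rbind, lapply(names(genotypes), function(g)
        data.frame(sample_id = sprintf("%s_%d", g, 1:3),
                   genotype = g, replicate = 1:3,
                   height_class = genotypes[[g]],
                   stringsAsFactors = FALSE)))
}

#' Generate negative-binomial RNA-seq counts with planted DEGs
#'
#' Non-DEG genes share a common mean across all samples; planted DEGs apply
#' their log2 effect to the tall group (a negative effect means the gene is
#' down-regulated in tall genotypes). Counts are drawn from a negative
#' binomial with the given dispersion (\code{size = 1/dispersion}), matching
#' the overdispersion model standard RNA-seq DE tools assume.
#'
#' @param seed Integer RNG seed.
#' @param geneIds Character vector of gene ids.
#' @param samples Sample sheet (default \code{\link{defaultSampleSheet}()}).
#' @param plantedDegs data.frame with \code{gene_id} and \code{log2fc}
#'   (tall over short), or \code{NULL} for none.
#' @param nbDispersion NB dispersion (> 0), default 0.05.
#' @param baseMean Baseline mean count, default 500.
#' @return List with \code{counts} (integer matrix) and \code{degs} (the
#'   planted-DEG data.frame with a \code{direction} column).
#' @export
generateCounts <- function(seed, geneIds, samples = defaultSampleSheet(),
                           plantedDegs = NULL, nbDispersion = 0.05,
                           baseMean = 500) {
    if (nbDispersion <= 0) stop("dispersion must be > 0")
    set.seed(seed)
    n <- length(geneIds); m <- nrow(samples)
    lfc <- stats::setNames(rep(0, n), geneIds)
    if (!is.null(plantedDegs)) {
        unknown <- setdiff(plantedDegs$gene_id, geneIds)
        if (length(unknown))
            stop("planted DEG ids not in geneIds: ",
                 paste(unknown, collapse = ", "))
        lfc[plantedDegs$gene_id] <- plantedDegs$log2fc
    }
    tall <- samples$height_class == "tall"
    counts <- matrix(0L, n, m, dimnames = list(geneIds, samples$sample_id))
    size <- 1 / nbDispersion
    for (g in seq_len(n)) {
        mu <- ifelse(tall, baseMean * 2^lfc[g], baseMean)
        counts[g, ] <- stats::rnbinom(m, size = size, mu = mu)
    }
    storage.mode(counts) <- "integer"
    degs <- if (is.null(plantedDegs)) {
        data.frame(gene_id = character(), log2fc = numeric(),
                   direction = character(), stringsAsFactors = FALSE)
    } else {
        data.frame(gene_id = plantedDegs$gene_id,
                   log2fc = plantedDegs$log2fc,
                   direction = ifelse(plantedDegs$log2fc >= 0,
                                      "up_in_tall", "up_in_short"),
                   stringsAsFactors = FALSE)
    }
    list(counts = counts, degs = degs)
}

#' Default planted-DEG specification
#'
#' Roughly a fifth of the genes become DEGs at |log2FC| = 2, most of them
#' down-regulated in the tall genotypes, echoing the predominance of
#' lignin-gene down-regulation in fast-growing trees.
#'
#' @param geneIds Character vector of gene ids.
#' @param fraction Fraction of genes planted as DEGs (default 0.2).
#' @param downFraction Fraction of DEGs down-regulated in tall (default
#'   19/23).
#' @param effect Absolute log2 fold change (default 2).
#' @return data.frame with \code{gene_id}, \code{log2fc}. Uses the current
#'   RNG stream; seed it (or call from \code{\link{makeStudy}}).
#' @export
defaultDegSpec <- function(geneIds, fraction = 0.2,
                           downFraction = 19 / 23, effect = 2) {
    nDeg <- max(1L, round(fraction * length(geneIds)))
    ids <- sort(sample(geneIds, nDeg))
    nDown <- round(downFraction * nDeg)
    sign <- c(rep(-1, nDown), rep(1, nDeg - nDown))
    data.frame(gene_id = ids, log2fc = sign * effect,
               stringsAsFactors = FALSE)
}

#' Generate promoters with planted motif occurrences
#'
#' Each gene gets a random ACGT background promoter; with probability
#' \code{plantRate} one to three motif instances (concrete sequences drawn
#' from the IUPAC pattern) are written into non-overlapping positions, on a
#' random strand (minus-strand plants insert the reverse complement).
#' Background coincidences with a motif may occur; the ground truth records
#' planted hits only.
#'
#' @param seed Integer RNG seed.
#' @param geneIds Character vector of gene ids.
#' @param motifVocabulary Motif table (default
#'   \code{\link{defaultMotifVocabulary}()}).
#' @param plantRate Probability a gene receives planted motifs, in [0, 1].
#' @param promoterLength Promoter length in bp (default 2000).
#' @return List with \code{promoters} (\code{DNAStringSet}) and \code{hits}
#'   (data.frame \code{gene_id}, \code{motif_id}, \code{offset},
#'   \code{strand}).
#' @export
generatePromoters <- function(seed, geneIds,
                              motifVocabulary = defaultMotifVocabulary(),
                              plantRate = 0.8, promoterLength = 2000) {
    if (plantRate < 0 || plantRate > 1) stop("plantRate must lie in [0, 1]")
    if (any(nchar(motifVocabulary$sequence) > promoterLength))
        stop("motif longer than the promoter")
    .checkIupac(motifVocabulary$sequence)
    set.seed(seed)
    proms <- character(length(geneIds))
    hits <- list()
    for (g in seq_along(geneIds)) {
        bases <- sample(c("A", "C", "G", "T"), promoterLength, replace = TRUE)
        if (stats::runif(1) < plantRate) {
            used <- IRanges::IRanges()
            for (j in seq_len(sample(1:3, 1L))) {
                k <- sample.int(nrow(motifVocabulary), 1L)
                pat <- motifVocabulary$sequence[k]
                w <- nchar(pat)
                for (try in 1:20) {
                    off <- sample.int(promoterLength - w + 1L, 1L) - 1L
                    cand <- IRanges::IRanges(off + 1L, off + w)
                    if (!length(IRanges::findOverlaps(cand, used))) break
                    off <- NA_integer_
                }
                if (is.na(off)) next
                used <- c(used, cand)
                inst <- vapply(strsplit(pat, "")[[1]], function(ch) {
                    opts <- strsplit(.IUPAC[[ch]], "")[[1]]
                    opts[sample.int(length(opts), 1L)]
                }, "")
                strand <- sample(c("+", "-"), 1L)
                write <- if (strand == "+") inst else
                    rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
                bases[(off + 1L):(off + w)] <- write
                hits[[length(hits) + 1L]] <- data.frame(
                    gene_id = geneIds[g],
                    motif_id = motifVocabulary$motif_id[k],
                    offset = off, strand = strand, stringsAsFactors = FALSE)
            }
        }
        proms[g] <- paste(bases, collapse = "")
    }
    promoters <- Biostrings::DNAStringSet(proms)
    names(promoters) <- geneIds
    hitDf <- if (length(hits)) do.call(rbind, hits)
             else data.frame(gene_id = character(), motif_id = character(),
                             offset = integer(), strand = character(),
                             stringsAsFactors = FALSE)
    list(promoters = promoters,
         hits = hitDf[order(hitDf$gene_id, hitDf$offset), , drop = FALSE])
}

#' Default 23-motif vocabulary
#'
#' A labelled vocabulary of 23 plant cis-regulatory elements over the IUPAC
#' DNA alphabet, tagged by transcription-factor family (MYB, AP2/ERF, bZIP,
#' MADS-box, NAC, ARF and others). A synthetic stand-in vocabulary: real
#' promoter scans should supply the user's own motif list.
#'
#' @return data.frame with \code{motif_id}, \code{sequence},
#'   \code{tf_family}.
#' @export
defaultMotifVocabulary <- function() {
    data.frame(
        motif_id = c("MYB1", "MYB2", "MYB3", "MYB4", "AC_I", "AC_II",
                     "AP2_1", "AP2_2", "ERE", "DRE",
                     "bZIP_Gbox", "bZIP_ABRE", "bZIP_TGA",
                     "MADS_CArG1", "MADS_CArG2",
                     "NAC_SNBE", "NAC_CGTA",
                     "ARF_AuxRE", "ARF_AuxRE2",
                     "WRKY_Wbox", "TCP_site", "GATA_box", "TELO_box"),
        sequence = c("CNGTTR", "GGATA", "MACCWAMC", "AGTTAGGTA", "ACCTACC",
                     "ACCAACC",
                     "GCCGCC", "ATCTA", "AWTTCAAA", "RCCGAC",
                     "CACGTG", "ACGTGKC", "TGACGTCA",
                     "CCWWWWWWGG", "CWWWWWWWWG",
                     "TTNCTTNNNNNNNAMGNAA", "CGTA",
                     "TGTCTC", "TGTCGG",
                     "TTGACC", "GGNCCC", "GATAAG", "AAACCCTA"),
        tf_family = c(rep("MYB", 6), rep("AP2/ERF", 4), rep("bZIP", 3),
                      rep("MADS", 2), rep("NAC", 2), rep("ARF", 2),
                      "WRKY", "TCP", "GATA", "TELO"),
        stringsAsFactors = FALSE)
}

#' Generate phenotypes with a controlled height-lignin correlation
#'
#' Heights are drawn uniformly over a sapling range; lignin contents are
#' constructed from the standardised heights plus noise and rescaled to a
#' physiological mg/g range, rejection-sampling until the Pearson
#' correlation lands within \code{tol} of \code{targetCorrelation}. The
#' assay inputs are then back-computed so that
#' \code{lignin = 2.184 * delta_A / dry_weight_g} holds exactly.
#'
#' @param seed Integer RNG seed.
#' @param genotypes Character vector of genotype names (>= 3).
#' @param targetCorrelation Target Pearson r in [-1, 1] (default -0.62).
#' @param tol Acceptance half-width on r (default 0.1).
#' @return data.frame with \code{genotype}, \code{height_cm},
#'   \code{delta_A}, \code{dry_weight_g}, \code{lignin_mg_per_g},
#'   \code{height_class}.
#' @export
generatePhenotypes <- function(seed,
                               genotypes = c("Yanjiang", "FS", "9901", "FH"),
                               targetCorrelation = -0.62, tol = 0.1) {
    if (length(genotypes) < 3L)
        stop("need at least 3 genotypes for a defined correlation")
    if (abs(targetCorrelation) > 1)
        stop("targetCorrelation must lie in [-1, 1]")
    set.seed(seed)
    n <- length(genotypes)
    rho <- targetCorrelation
    for (try in seq_len(10000)) {
        h <- stats::runif(n, 70, 190)
        z <- stats::rnorm(n)
        hs <- as.numeric(scale(h))
        zs <- as.numeric(scale(z))
        y <- rho * hs + sqrt(1 - rho^2) * zs
        lignin <- 600 + 220 * y
        if (any(lignin <= 50)) next
        r <- stats::cor(h, lignin)
        if (abs(r - rho) <= tol) break
        if (try == 10000) stop("could not hit the target correlation")
    }
    W <- round(stats::runif(n, 0.2, 0.5), 4)
    deltaA <- lignin * W / 2.184
    data.frame(genotype = genotypes,
               height_cm = round(h, 2),
               delta_A = deltaA,
               dry_weight_g = W,
               lignin_mg_per_g = ligninContent(deltaA, W),
               height_class = ifelse(rank(h) > n / 2, "tall", "short"),
               stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study
#'
#' Runs the genome, count, promoter and phenotype generators with sub-seeds
#' derived from \code{seed} and (optionally) writes every emitted file plus
#' the ground truth to \code{outDir}. Byte-identical outputs are guaranteed
#' for a fixed seed.
#'
#' @param seed Integer RNG seed.
#' @param outDir Optional output directory (created if needed).
#' @param ... Passed to \code{\link{generateGenome}}.
#' @return List with \code{catalog}, \code{proteins}, \code{cds},
#'   \code{references}, \code{counts}, \code{samples}, \code{phenotypes},
#'   \code{promoters}, \code{motifs} and \code{truth} (adding
#'   \code{degs} and \code{motif_hits} to the genome ground truth).
#' @export
makeStudy <- function(seed, outDir = NULL, ...) {
    genome <- generateGenome(seed, ...)
    ids <- geneIds(genome$catalog)
    set.seed(seed + 1L)
    degSpec <- defaultDegSpec(ids)
    cnt <- generateCounts(seed + 2L, ids, plantedDegs = degSpec)
    prom <- generatePromoters(seed + 3L, ids)
    pheno <- generatePhenotypes(seed + 4L)
    study <- list(catalog = genome$catalog,
                  proteins = genome$proteins,
                  cds = genome$cds,
                  references = genome$references,
                  chromLengths = genome$chromLengths,
                  counts = cnt$counts,
                  samples = defaultSampleSheet(),
                  phenotypes = pheno,
                  promoters = prom$promoters,
                  motifs = defaultMotifVocabulary(),
                  truth = c(genome$truth,
                            list(degs = cnt$degs, motif_hits = prom$hits)))
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        p <- function(f) file.path(outDir, f)
        writeGff3(study$catalog, p("genes.gff3"))
        writeFasta(study$proteins, p("proteins.faa"))
        writeFasta(study$cds, p("cds.fna"))
        writeCounts(study$counts, p("counts.tsv"))
        utils::write.table(study$samples, p("samples.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(study$phenotypes, p("phenotypes.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        writeFasta(study$promoters, p("promoters.fna"))
        utils::write.table(study$motifs, p("motifs.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(study$truth$duplicate_pairs,
                           p("truth_duplicates.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(study$truth$hotspots, p("truth_hotspots.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(study$truth$degs, p("truth_degs.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(study$truth$motif_hits, p("truth_motif_hits.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    study
}
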