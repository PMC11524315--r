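## Readers and writers for the plain-text formats the pipeline touches.
## Coordinates are 1-based inclusive everywhere inside the package; the only
## half-open conversion happens in writeHotspotsBed().

#' Read gene records from a GFF3 file
#'
#' Only \code{gene} features are consumed. The custom attributes
#' \code{family=} and \code{subgenome=} carry the catalogue annotation; when
#' absent, family defaults to \code{"unassigned"} and the sub-genome is
#' inferred from the chromosome name (see \code{\link{inferSubgenome}}).
#'
#' @param path Path to a GFF3 file.
#' @return A \code{\link{GeneCatalog}} (possibly empty).
#' @export
readGff3 <- function(path) {
    lines <- readLines(path)
    body <- !grepl("^#", lines) & nzchar(lines)
    for (k in which(body)) {
        f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
        if (length(f) != 9L)
            stop("malformed GFF3 line ", k, ": expected 9 tab-separated fields, got ",
                 length(f))
        s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
        if (is.na(s) || is.na(e))
            stop("malformed GFF3 line ", k, ": non-numeric coordinates")
        if (e < s)
            stop("invalid GFF3 line ", k, ": end < start")
    }
    if (!any(body))
        return(GeneCatalog(data.frame(gene_id = character(), chromosome = character(),
                                      start = integer(), end = integer(),
                                      strand = character())))
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    mc <- S4Vectors::mcols(gr)
    df <- data.frame(
        gene_id = as.character(mc$ID),
        chromosome = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr),
        end = GenomicRanges::end(gr),
        strand = as.character(GenomicRanges::strand(gr)),
        stringsAsFactors = FALSE)
    df$family <- if ("family" %in% colnames(mc)) {
        fam <- as.character(mc$family); fam[is.na(fam)] <- "unassigned"; fam
    } else "unassigned"
    df$subgenome <- if ("subgenome" %in% colnames(mc)) {
        sg <- as.character(mc$subgenome)
        sg[is.na(sg)] <- inferSubgenome(df$chromosome[is.na(sg)])
        sg
    } else inferSubgenome(df$chromosome)
    GeneCatalog(df)
}

#' Write a GeneCatalog as GFF3
#'
#' Emits one \code{gene} feature per record with \code{ID}, \code{family} and
#' \code{subgenome} attributes, so that \code{readGff3(writeGff3(x))} is the
#' identity on records.
#'
#' @param catalog A \code{\link{GeneCatalog}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGff3 <- function(catalog, path) {
    gr <- geneRanges(catalog)
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::ranges(gr),
                                  strand = GenomicRanges::strand(gr))
    mc <- S4Vectors::mcols(gr)
    S4Vectors::mcols(out)$source <- "lignoscan"
    S4Vectors::mcols(out)$type <- "gene"
    S4Vectors::mcols(out)$ID <- mc$gene_id
    S4Vectors::mcols(out)$family <- mc$family
    S4Vectors::mcols(out)$subgenome <- mc$subgenome
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}

.checkDuplicateIds <- function(ids, what) {
    if (anyDuplicated(ids))
        stop("duplicate ", what, " id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
}

#' Read a protein or DNA FASTA file
#'
#' Thin wrappers over \pkg{Biostrings} that reject duplicate sequence ids
#' (listing the offenders) and strip FASTA descriptions down to the id.
#'
#' @param path Path to a FASTA file.
#' @return An \code{AAStringSet} / \code{DNAStringSet} named by id.
#' @export
readProteinFasta <- function(path) {
    x <- Biostrings::readAAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    .checkDuplicateIds(names(x), "sequence")
    x
}

#' @rdname readProteinFasta
#' @export
readDnaFasta <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    .checkDuplicateIds(names(x), "sequence")
    x
}

#' Write sequences to FASTA
#'
#' @param seqs A named \code{XStringSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path) {
    .checkDuplicateIds(names(seqs), "sequence")
    Biostrings::writeXStringSet(seqs, path, width = 70L)
    invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns \code{sample_id}, \code{genotype}, \code{replicate},
#' \code{height_class}.
#'
#' @param path Path to the TSV.
#' @return data.frame, one row per sample.
#' @export
readSampleSheet <- function(path) {
    ss <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "genotype", "replicate", "height_class")
    miss <- setdiff(need, colnames(ss))
    if (length(miss))
        stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(paste(ss$genotype, ss$replicate)))
        stop("(genotype, replicate) pairs must be unique in the sample sheet")
    if (!all(ss$height_class %in% c("tall", "short")))
        stop("height_class must be 'tall' or 'short'")
    ss
}

#' Read a read-count table
#'
#' TSV whose first column is \code{gene_id} and whose remaining header names
#' are sample ids that must match the sample sheet exactly (same set).
#' Counts must be non-negative integers with no missing cells.
#'
#' @param path Path to the counts TSV.
#' @param samples Sample sheet data.frame (see \code{\link{readSampleSheet}}).
#' @return Integer matrix, genes x samples, columns ordered as in
#'   \code{samples}.
#' @export
readCounts <- function(path, samples) {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (colnames(tab)[1] != "gene_id")
        stop("first column of the counts table must be 'gene_id'")
    ids <- tab$gene_id
    .checkDuplicateIds(ids, "gene")
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!setequal(colnames(m), samples$sample_id))
        stop("counts header does not match the sample sheet: missing [",
             paste(setdiff(samples$sample_id, colnames(m)), collapse = ", "),
             "], extra [", paste(setdiff(colnames(m), samples$sample_id),
                                 collapse = ", "), "]")
    if (anyNA(m))
        stop("missing cells in the counts table")
    if (any(m < 0) || any(m != round(m)))
        stop("counts must be non-negative integers")
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    m[, samples$sample_id, drop = FALSE]
}

#' Write a count matrix as TSV
#'
#' @param counts Integer gene x sample matrix with rownames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(counts, path) {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a phenotype table
#'
#' TSV with columns \code{genotype}, \code{height_cm} and either
#' \code{lignin_mg_per_g} directly or the assay inputs \code{delta_A}
#' (OD280 difference) and \code{dry_weight_g}. When assay inputs are present
#' the lignin content is checked (or filled in) against the kit formula
#' \code{2.184 * delta_A / dry_weight_g}.
#'
#' @param path Path to the TSV.
#' @param tol Tolerance for the consistency check.
#' @return data.frame with a \code{lignin_mg_per_g} column guaranteed.
#' @export
readPhenotypes <- function(path, tol = 1e-6) {
    ph <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("genotype", "height_cm") %in% colnames(ph)))
        stop("phenotype table must have 'genotype' and 'height_cm' columns")
    if (any(ph$height_cm <= 0)) stop("height_cm must be > 0")
    hasAssay <- all(c("delta_A", "dry_weight_g") %in% colnames(ph))
    if (hasAssay) {
        computed <- ligninContent(ph$delta_A, ph$dry_weight_g)
        if ("lignin_mg_per_g" %in% colnames(ph)) {
            if (any(abs(ph$lignin_mg_per_g - computed) > tol))
                stop("lignin_mg_per_g inconsistent with 2.184 * delta_A / dry_weight_g")
        } else ph$lignin_mg_per_g <- computed
    } else if (!"lignin_mg_per_g" %in% colnames(ph)) {
        stop("phenotype table needs lignin_mg_per_g or (delta_A, dry_weight_g)")
    }
    ph
}

#' Read a motif list
#'
#' TSV with columns \code{motif_id}, \code{sequence} (IUPAC DNA) and
#' optionally \code{tf_family}.
#'
#' @param path Path to the TSV.
#' @return data.frame of motifs.
#' @export
readMotifTable <- function(path) {
    mt <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("motif_id", "sequence") %in% colnames(mt)))
        stop("motif table must have 'motif_id' and 'sequence' columns")
    .checkDuplicateIds(mt$motif_id, "motif")
    ok <- grepl("^[ACGTRYSWKMBDHVN]+$", toupper(mt$sequence))
    if (!all(ok))
        stop("invalid IUPAC letters in motif(s): ",
             paste(mt$motif_id[!ok], collapse = ", "))
    mt$sequence <- toupper(mt$sequence)
    mt
}

#' Write hotspots as BED
#'
#' BED uses 0-based half-open coordinates; the conversion from the package's
#' 1-based inclusive convention happens here and only here.
#'
#' @param hotspots data.frame from \code{\link{findHotspots}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeHotspotsBed <- function(hotspots, path) {
    bed <- data.frame(chrom = hotspots$chromosome,
                      chromStart = hotspots$start - 1L,
                      chromEnd = hotspots$end,
                      name = sprintf("hotspot_%d", seq_len(nrow(hotspots))),
                      score = hotspots$n_genes)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Bundled reference tables
#'
#' \code{referenceFamilyCounts()} returns the per-species family count table
#' from a published genome-wide survey of monolignol genes in nine angiosperm
#' species, including the At/Bt sub-genome split of the tetraploid willow
#' Salix matsudana. \code{referencePhenotypes()} returns the matching tree
#' height and lignin content genotype means for the two parents and two F1
#' progeny of contrasting height.
#'
#' @return data.frame.
#' @export
referenceFamilyCounts <- function() {
    utils::read.delim(system.file("extdata", "family_counts_9species.tsv",
                                  package = "lignoscan"),
                      check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname referenceFamilyCounts
#' @export
referencePhenotypes <- function() {
    utils::read.delim(system.file("extdata", "phenotypes_4genotypes.tsv",
                                  package = "lignoscan"),
                      stringsAsFactors = FALSE)
}
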