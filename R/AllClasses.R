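#' The eleven monolignol biosynthesis gene families
#'
#' Family labels for the enzymes of the phenylpropanoid pathway leading from
#' phenylalanine to the monolignols, in pathway order: phenylalanine ammonia
#' lyase (PAL), cinnamate-4-hydroxylase (C4H), 4-coumarate:CoA ligase (4CL),
#' hydroxycinnamoyl transferase (HCT), cinnamate-3-hydroxylase (C3H),
#' caffeoyl shikimate esterase (CSE), caffeic acid O-methyltransferase (COMT),
#' ferulate-5-hydroxylase (F5H), caffeoyl-CoA O-methyltransferase (CCoAOMT),
#' cinnamoyl-CoA reductase (CCR) and cinnamyl alcohol dehydrogenase (CAD).
#'
#' @return Character vector of the 11 family labels.
#' @export
#' @examples
#' monolignolFamilies()
monolignolFamilies <- function() {
    c("PAL", "C4H", "4CL", "HCT", "C3H", "CSE",
      "COMT", "F5H", "CCoAOMT", "CCR", "CAD")
}

.validFamilyLabels <- function() c(monolignolFamilies(), "unassigned")

#' GeneCatalog: an annotated monolignol gene set
#'
#' Wraps a \link[GenomicRanges]{GRanges} whose metadata columns carry, for
#' every gene, a unique \code{gene_id}, a \code{family} label (one of the 11
#' monolignol families or \code{"unassigned"}) and a \code{subgenome} tag
#' (\code{"At"}, \code{"Bt"} or \code{"none"} for unplaced genes).
#' Coordinates are 1-based inclusive throughout.
#'
#' @slot genes A \code{GRanges} with metadata columns \code{gene_id},
#'   \code{family} and \code{subgenome}.
#'
#' @aliases GeneCatalog-class
#' @export
setClass("GeneCatalog", representation(genes = "GRanges"))

setValidity("GeneCatalog", function(object) {
    gr <- object@genes
    mc <- S4Vectors::mcols(gr)
    need <- c("gene_id", "family", "subgenome")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(paste("missing metadata column(s):",
                     paste(miss, collapse = ", ")))
    if (anyDuplicated(mc$gene_id))
        return(paste("duplicated gene_id(s):",
                     paste(unique(mc$gene_id[duplicated(mc$gene_id)]),
                           collapse = ", ")))
    bad <- setdiff(unique(mc$family), .validFamilyLabels())
    if (length(bad))
        return(paste("unknown family label(s):", paste(bad, collapse = ", ")))
    if (!all(mc$subgenome %in% c("At", "Bt", "none")))
        return("subgenome must be one of At, Bt, none")
    if (length(gr) && any(GenomicRanges::start(gr) < 1L))
        return("gene start coordinates must be >= 1")
    if (length(gr) && !all(as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
        return("gene strand must be + or -")
    TRUE
})

#' Construct a GeneCatalog
#'
#' @param genes A \code{GRanges} carrying metadata columns \code{gene_id},
#'   \code{family}, \code{subgenome}, or a data.frame with columns
#'   \code{gene_id}, \code{chromosome}, \code{start}, \code{end},
#'   \code{strand} and optionally \code{family}, \code{subgenome}.
#'   Missing \code{family} defaults to \code{"unassigned"}; missing
#'   \code{subgenome} is inferred from the chromosome name (leading
#'   \code{A}/\code{B} after an optional \code{chr} prefix maps to
#'   \code{At}/\code{Bt}; anything else is \code{"none"}).
#' @return A \code{GeneCatalog}.
#' @export
#' @examples
#' df <- data.frame(gene_id = "g1", chromosome = "A01",
#'                  start = 100, end = 400, strand = "+")
#' GeneCatalog(df)
GeneCatalog <- function(genes) {
    if (is.data.frame(genes)) {
        stopifnot(all(c("gene_id", "chromosome", "start", "end", "strand")
                      %in% colnames(genes)))
        if (any(genes$end < genes$start))
            stop("end < start for gene(s): ",
                 paste(genes$gene_id[genes$end < genes$start], collapse = ", "))
        gr <- GenomicRanges::GRanges(
            seqnames = genes$chromosome,
            ranges = IRanges::IRanges(start = genes$start, end = genes$end),
            strand = genes$strand)
        S4Vectors::mcols(gr)$gene_id <- as.character(genes$gene_id)
        S4Vectors::mcols(gr)$family <-
            if ("family" %in% colnames(genes)) as.character(genes$family)
            else rep("unassigned", nrow(genes))
        S4Vectors::mcols(gr)$subgenome <-
            if ("subgenome" %in% colnames(genes)) as.character(genes$subgenome)
            else inferSubgenome(as.character(genes$chromosome))
        genes <- gr
    }
    methods::new("GeneCatalog", genes = genes)
}

#' Infer sub-genome tags from chromosome names
#'
#' A leading \code{A} or \code{B} (after an optional \code{chr} prefix) maps
#' to the At or Bt sub-genome; any other name means the gene is unplaced.
#'
#' @param chromosome Character vector of chromosome names.
#' @return Character vector over \code{c("At","Bt","none")}.
#' @export
inferSubgenome <- function(chromosome) {
    stripped <- sub("^chr", "", chromosome)
    ifelse(startsWith(stripped, "A"), "At",
           ifelse(startsWith(stripped, "B"), "Bt", "none"))
}

#' @describeIn GeneCatalog-class Underlying \code{GRanges} of gene spans.
#' @param object,x A \code{GeneCatalog}.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneCatalog-class
#' @export
setMethod("geneRanges", "GeneCatalog", function(x) x@genes)

#' @rdname GeneCatalog-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneCatalog-class
#' @export
setMethod("geneIds", "GeneCatalog",
          function(x) S4Vectors::mcols(x@genes)$gene_id)

#' @rdname GeneCatalog-class
#' @export
setGeneric("familyOf", function(x) standardGeneric("familyOf"))

#' @rdname GeneCatalog-class
#' @export
setMethod("familyOf", "GeneCatalog", function(x) {
    stats::setNames(S4Vectors::mcols(x@genes)$family, geneIds(x))
})

#' @rdname GeneCatalog-class
#' @export
setGeneric("subgenomeOf", function(x) standardGeneric("subgenomeOf"))

#' @rdname GeneCatalog-class
#' @export
setMethod("subgenomeOf", "GeneCatalog", function(x) {
    stats::setNames(S4Vectors::mcols(x@genes)$subgenome, geneIds(x))
})

#' @rdname GeneCatalog-class
#' @export
setMethod("length", "GeneCatalog", function(x) length(x@genes))

#' @rdname GeneCatalog-class
#' @param i Index or logical vector selecting genes.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "GeneCatalog", function(x, i, j, ..., drop = FALSE) {
    methods::initialize(x, genes = x@genes[i])
})

setMethod("show", "GeneCatalog", function(object) {
    fam <- familyOf(object)
    cat("GeneCatalog with", length(object), "genes on",
        length(unique(as.character(GenomicRanges::seqnames(object@genes)))),
        "sequences\n")
    cat("  families:",
        paste(names(sort(table(fam[fam != "unassigned"]), decreasing = TRUE)),
              collapse = " "), "\n")
    sg <- table(factor(subgenomeOf(object), levels = c("At", "Bt", "none")))
    cat("  sub-genomes: At =", sg[["At"]], " Bt =", sg[["Bt"]],
        " unplaced =", sg[["none"]], "\n")
    invisible(NULL)
})

#' Convert a GeneCatalog to a data.frame
#'
#' @param x A \code{GeneCatalog}.
#' @param row.names,optional,... Passed for S3 compatibility; ignored.
#' @return data.frame with gene_id, chromosome, start, end, strand, family,
#'   subgenome.
#' @export
as.data.frame.GeneCatalog <- function(x, row.names = NULL, optional = FALSE, ...) {
    gr <- x@genes
    data.frame(
        gene_id = geneIds(x),
        chromosome = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr),
        end = GenomicRanges::end(gr),
        strand = as.character(GenomicRanges::strand(gr)),
        family = S4Vectors::mcols(gr)$family,
        subgenome = S4Vectors::mcols(gr)$subgenome,
        stringsAsFactors = FALSE)
}

#' FPKMExperiment: length-normalised expression with sample annotation
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} whose assays include
#' \code{fpkm} (and usually raw \code{counts}), whose \code{rowData} carries
#' \code{gene_length} in bp, and whose \code{colData} carries the sample
#' sheet: \code{genotype}, \code{replicate} and \code{height_class}
#' (\code{"tall"} or \code{"short"}).
#'
#' @aliases FPKMExperiment-class
#' @export
setClass("FPKMExperiment", contains = "SummarizedExperiment")

setValidity("FPKMExperiment", function(object) {
    if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
        return("assay 'fpkm' is required")
    rd <- SummarizedExperiment::rowData(object)
    if (!"gene_length" %in% colnames(rd))
        return("rowData column 'gene_length' is required")
    if (any(rd$gene_length <= 0))
        return("gene lengths must be > 0")
    cd <- SummarizedExperiment::colData(object)
    miss <- setdiff(c("genotype", "replicate", "height_class"), colnames(cd))
    if (length(miss))
        return(paste("missing colData column(s):", paste(miss, collapse = ", ")))
    if (!all(cd$height_class %in% c("tall", "short")))
        return("height_class must be 'tall' or 'short'")
    if (anyDuplicated(paste(cd$genotype, cd$replicate)))
        return("(genotype, replicate) pairs must be unique")
    if (any(SummarizedExperiment::assay(object, "fpkm") < 0))
        return("FPKM values must be >= 0")
    TRUE
})

#' Construct an FPKMExperiment
#'
#' @param fpkm Numeric gene x sample matrix of FPKM values.
#' @param geneLengths Numeric vector of transcript lengths (bp), one per row.
#' @param samples data.frame with columns \code{sample_id}, \code{genotype},
#'   \code{replicate}, \code{height_class}, one row per column of \code{fpkm}.
#' @param counts Optional integer count matrix of the same shape.
#' @return An \code{FPKMExperiment}.
#' @export
FPKMExperiment <- function(fpkm, geneLengths, samples, counts = NULL) {
    stopifnot(nrow(fpkm) == length(geneLengths),
              ncol(fpkm) == nrow(samples))
    assays <- list(fpkm = fpkm)
    if (!is.null(counts)) assays <- c(list(counts = counts), assays)
    cd <- S4Vectors::DataFrame(samples)
    rownames(cd) <- samples$sample_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays,
        rowData = S4Vectors::DataFrame(gene_length = geneLengths,
                                       row.names = rownames(fpkm)),
        colData = cd)
    methods::new("FPKMExperiment", se)
}

#' @describeIn FPKMExperiment-class The FPKM assay matrix.
#' @param x An \code{FPKMExperiment}.
#' @export
setGeneric("fpkm", function(x) standardGeneric("fpkm"))

#' @rdname FPKMExperiment-class
#' @export
setMethod("fpkm", "FPKMExperiment",
          function(x) SummarizedExperiment::assay(x, "fpkm"))

#' @rdname FPKMExperiment-class
#' @export
setGeneric("heightClass", function(x) standardGeneric("heightClass"))

#' @rdname FPKMExperiment-class
#' @export
setMethod("heightClass", "FPKMExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    stats::setNames(cd$height_class, rownames(cd))
})
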