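## Stage orchestration: one config object, per-stage runners writing TSV
## outputs plus a run manifest (config hash, seed, input checksums), and a
## one-shot synthetic-study reproduction.

#' Pipeline configuration
#'
#' All thresholds default to the reference cut-offs of the analysis:
#' duplication identity/coverage 0.80 (strict), hotspots of >= 5 genes in
#' < 5 Mb, expression filter FPKM > 1.0, DEGs at 2-fold with BH FDR < 0.05,
#' 2000-bp promoters and 1000 bootstrap replicates.
#'
#' @param seed Integer seed for every stochastic stage (mandatory).
#' @param inputDir Directory holding the stage inputs (as emitted by
#'   \code{\link{makeStudy}}).
#' @param outDir Directory for stage outputs.
#' @param ... Overrides for individual thresholds.
#' @return A named list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(seed, inputDir, outDir, ...) {
    cfg <- list(seed = seed, inputDir = inputDir, outDir = outDir,
                identity_threshold = 0.80, coverage_threshold = 0.80,
                tandem_max_separation_bp = 100000,
                hotspot_min_genes = 5, hotspot_window_bp = 5e6,
                min_fpkm = 1.0, fc_threshold = 2, fdr = 0.05,
                min_align_score = 100,
                promoter_length = 2000, bootstrap_reps = 1000)
    dots <- list(...)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
    stopifnot(cfg$identity_threshold > 0, cfg$identity_threshold <= 1,
              cfg$coverage_threshold > 0, cfg$coverage_threshold <= 1,
              cfg$hotspot_min_genes >= 2, cfg$hotspot_window_bp > 0,
              cfg$fc_threshold >= 1, cfg$fdr > 0, cfg$fdr < 1,
              cfg$promoter_length > 0, cfg$bootstrap_reps >= 1)
    class(cfg) <- "PipelineConfig"
    cfg
}

## Hash of the analysis parameters only; file locations are deliberately
## excluded so identical analyses hash identically wherever they run.
.configHash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    flat <- config[setdiff(names(config), c("inputDir", "outDir"))]
    flat <- flat[order(names(flat))]
    writeLines(paste(names(flat), vapply(flat, paste, "", collapse = ","),
                     sep = "="), tmp)
    unname(tools::md5sum(tmp))
}

.writeManifest <- function(config, stage, inputs, outDir) {
    inputs <- inputs[file.exists(inputs)]
    inputKeys <- if (length(inputs)) paste0("input_md5:", basename(inputs))
                 else character()
    inputSums <- if (length(inputs)) unname(tools::md5sum(inputs))
                 else character()
    manifest <- data.frame(
        key = c("stage", "seed", "config_md5", inputKeys),
        value = c(stage, as.character(config$seed), .configHash(config),
                  inputSums),
        stringsAsFactors = FALSE)
    utils::write.table(manifest,
                       file.path(outDir, paste0("manifest_", stage, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
}

.stageInputs <- function(config, files) {
    paths <- file.path(config$inputDir, files)
    missing <- files[!file.exists(paths)]
    if (length(missing))
        stop("missing input file(s): ", paste(missing, collapse = ", "))
    paths
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Run one pipeline stage
#'
#' Stages: \code{make-study} (emit the synthetic study into
#' \code{inputDir}), \code{families} (count table), \code{duplicates},
#' \code{hotspots}, \code{trees}, \code{degs}, \code{phenotype},
#' \code{motifs}, \code{all}. Each stage reads its inputs from
#' \code{config$inputDir}, writes TSV (and BED/Newick) outputs into
#' \code{config$outDir} and records a manifest with the config hash, seed
#' and input checksums.
#'
#' @param stage Stage name.
#' @param config A \code{\link{pipelineConfig}}.
#' @return Invisibly, the stage's main result object.
#' @export
runStage <- function(stage, config) {
    stages <- c("make-study", "families", "duplicates", "hotspots", "trees",
                "degs", "phenotype", "motifs", "all")
    if (!stage %in% stages)
        stop("unknown stage '", stage, "'; usage: one of ",
             paste(stages, collapse = ", "))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    if (stage == "all") return(runAll(config))
    res <- switch(stage,
        "make-study" = {
            study <- makeStudy(config$seed, outDir = config$inputDir)
            .writeManifest(config, stage, character(), config$outDir)
            study
        },
        "families" = {
            ins <- .stageInputs(config, "genes.gff3")
            catalog <- readGff3(ins)
            tab <- countTable(catalog, groupBy = "subgenome")
            .writeTsv(tab, file.path(config$outDir, "family_counts.tsv"))
            .writeManifest(config, stage, ins, config$outDir)
            tab
        },
        "duplicates" = {
            ins <- .stageInputs(config, c("genes.gff3", "cds.fna"))
            catalog <- readGff3(ins[1])
            cds <- readDnaFasta(ins[2])
            pairs <- detectDuplicates(catalog, cds,
                                      identityThreshold = config$identity_threshold,
                                      coverageThreshold = config$coverage_threshold)
            pairs <- classifyTandem(pairs, catalog,
                                    maxSeparationBp = config$tandem_max_separation_bp)
            .writeTsv(pairs, file.path(config$outDir, "duplicate_pairs.tsv"))
            .writeManifest(config, stage, ins, config$outDir)
            pairs
        },
        "hotspots" = {
            ins <- .stageInputs(config, "genes.gff3")
            catalog <- readGff3(ins)
            hs <- findHotspots(catalog, minGenes = config$hotspot_min_genes,
                               windowBp = config$hotspot_window_bp)
            .writeTsv(hs, file.path(config$outDir, "hotspots.tsv"))
            writeHotspotsBed(hs, file.path(config$outDir, "hotspots.bed"))
            .writeManifest(config, stage, ins, config$outDir)
            hs
        },
        "trees" = {
            ins <- .stageInputs(config, c("genes.gff3", "proteins.faa"))
            catalog <- readGff3(ins[1])
            prots <- readProteinFasta(ins[2])
            fam <- familyOf(catalog)
            trees <- list()
            for (f in intersect(monolignolFamilies(), unique(fam))) {
                ids <- names(fam)[fam == f]
                if (length(ids) < 4L) next
                ## substitution-only members are already aligned; members of
                ## deviating length (e.g. truncated duplicates) are left out
                seqs <- prots[ids]
                w <- Biostrings::width(seqs)
                modal <- as.integer(names(which.max(table(w))))
                seqs <- seqs[w == modal]
                if (length(seqs) < 4L) next
                D <- pairwiseDistance(seqs, model = "poisson")
                trees[[f]] <- njTree(D)
                ape::write.tree(trees[[f]],
                                file.path(config$outDir,
                                          paste0("tree_", f, ".nwk")))
            }
            .writeManifest(config, stage, ins, config$outDir)
            trees
        },
        "degs" = {
            ins <- .stageInputs(config, c("genes.gff3", "counts.tsv",
                                          "samples.tsv"))
            catalog <- readGff3(ins[1])
            samples <- readSampleSheet(ins[3])
            counts <- readCounts(ins[2], samples)
            gr <- geneRanges(catalog)
            lens <- stats::setNames(GenomicRanges::width(gr), geneIds(catalog))
            fe <- computeFpkm(counts, lens[rownames(counts)], samples)
            fe <- filterExpressed(fe, minFpkm = config$min_fpkm)
            degs <- callDegs(fe, fcThreshold = config$fc_threshold,
                             fdr = config$fdr)
            .writeTsv(degs, file.path(config$outDir, "deg_report.tsv"))
            heat <- expressionHeatTable(fe)
            .writeTsv(data.frame(gene_id = rownames(heat), heat,
                                 check.names = FALSE),
                      file.path(config$outDir, "heat_table.tsv"))
            .writeManifest(config, stage, ins, config$outDir)
            degs
        },
        "phenotype" = {
            ins <- .stageInputs(config, "phenotypes.tsv")
            pheno <- readPhenotypes(ins)
            res <- heightLigninCorrelation(pheno, mode = "means")
            .writeTsv(data.frame(r = res$r, p_value = res$p_value,
                                 n = res$n, mode = res$mode),
                      file.path(config$outDir, "phenotype_stats.tsv"))
            .writeManifest(config, stage, ins, config$outDir)
            res
        },
        "motifs" = {
            ins <- .stageInputs(config, c("promoters.fna", "motifs.tsv",
                                          "genes.gff3"))
            promoters <- readDnaFasta(ins[1])
            motifs <- readMotifTable(ins[2])
            catalog <- readGff3(ins[3])
            hits <- scanMotifs(promoters, motifs)
            .writeTsv(hits, file.path(config$outDir, "motif_hits.tsv"))
            fm <- frequencyMatrix(hits, grouping = "gene",
                                  familyOf = familyOf(catalog),
                                  motifIds = motifs$motif_id)
            .writeTsv(data.frame(gene_id = rownames(fm), fm,
                                 check.names = FALSE),
                      file.path(config$outDir, "motif_matrix_by_gene.tsv"))
            .writeManifest(config, stage, ins, config$outDir)
            hits
        })
    invisible(res)
}

#' Run the whole pipeline
#'
#' Executes every stage in order. With \code{synthetic = TRUE} the synthetic
#' study is generated first (into \code{config$inputDir}); otherwise the
#' input files must already exist. A one-file summary is written at the end;
#' every number in it is recomputed from the stage outputs.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @param synthetic Generate the study first (default \code{TRUE} when
#'   \code{genes.gff3} is absent from \code{inputDir}).
#' @return Invisibly, a list with every stage result plus \code{summary}.
#' @export
runAll <- function(config,
                   synthetic = !file.exists(file.path(config$inputDir,
                                                      "genes.gff3"))) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    if (synthetic) runStage("make-study", config)
    fams <- runStage("families", config)
    pairs <- runStage("duplicates", config)
    hs <- runStage("hotspots", config)
    trees <- runStage("trees", config)
    degs <- runStage("degs", config)
    pheno <- runStage("phenotype", config)
    hits <- runStage("motifs", config)
    frac <- degFraction(sum(degs$is_deg), nrow(degs))
    summary <- c(
        sprintf("genes_per_subgenome\t%s",
                paste(sprintf("%s=%d", fams$group, fams$Total), collapse = ",")),
        sprintf("duplicate_pairs\t%d", nrow(pairs)),
        sprintf("tandem_pairs\t%d", sum(pairs$tandem)),
        sprintf("hotspots\t%d", nrow(hs)),
        sprintf("family_trees\t%d", length(trees)),
        sprintf("genes_tested\t%d", nrow(degs)),
        sprintf("degs\t%d", sum(degs$is_deg)),
        sprintf("deg_fraction\t%s", frac$text),
        sprintf("height_lignin_r\t%.4f", pheno$r),
        sprintf("motif_hits\t%d", nrow(hits)),
        sprintf("identity_threshold\t%g", config$identity_threshold),
        sprintf("coverage_threshold\t%g", config$coverage_threshold),
        sprintf("hotspot_min_genes\t%g", config$hotspot_min_genes),
        sprintf("hotspot_window_bp\t%g", config$hotspot_window_bp),
        sprintf("min_fpkm\t%g", config$min_fpkm),
        sprintf("fc_threshold\t%g", config$fc_threshold),
        sprintf("fdr\t%g", config$fdr),
        sprintf("promoter_length\t%g", config$promoter_length),
        sprintf("seed\t%d", config$seed))
    writeLines(summary, file.path(config$outDir, "summary.tsv"))
    invisible(list(families = fams, duplicates = pairs, hotspots = hs,
                   trees = trees, degs = degs, phenotype = pheno,
                   motif_hits = hits, summary = summary))
}
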