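smallStudy <- function(seed, outDir = NULL) {
    makeStudy(seed, outDir = outDir, genesPerFamily = 6L, nUnplaced = 2L,
              hotspotSpec = data.frame(chromosome = "B16", family = "COMT",
                                       n = 5L, span_bp = 3e6,
                                       stringsAsFactors = FALSE),
              duplicateSpec = data.frame(family = c("HCT", "CAD"),
                                         identity = c(0.9, 0.85),
                                         coverage = c(1, 1),
                                         tandem = c(TRUE, FALSE),
                                         stringsAsFactors = FALSE))
}

test_that("the generated study is byte-identical under a fixed seed", {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    smallStudy(123, d1)
    smallStudy(123, d2)
    files <- sort(list.files(d1))
    expect_identical(files, sort(list.files(d2)))
    for (f in files)
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         info = f)
    d3 <- withr::local_tempdir()
    smallStudy(124, d3)
    expect_false(identical(unname(tools::md5sum(file.path(d1, "cds.fna"))),
                           unname(tools::md5sum(file.path(d3, "cds.fna")))))
})

test_that("emitted files are read back into the generated objects", {
    d <- withr::local_tempdir()
    study <- smallStudy(321, d)
    cat <- readGff3(file.path(d, "genes.gff3"))
    expect_equal(as.data.frame(cat)[order(geneIds(cat)), ],
                 as.data.frame(study$catalog)[order(geneIds(study$catalog)), ],
                 ignore_attr = TRUE)
    cds <- readDnaFasta(file.path(d, "cds.fna"))
    expect_equal(as.character(cds), as.character(study$cds))
    counts <- readCounts(file.path(d, "counts.tsv"),
                         readSampleSheet(file.path(d, "samples.tsv")))
    expect_identical(counts, study$counts)
})

test_that("every ground-truth entity exists in the emitted study", {
    study <- smallStudy(55)
    ids <- geneIds(study$catalog)
    truth <- study$truth
    expect_true(all(c(truth$duplicate_pairs$gene_a,
                      truth$duplicate_pairs$gene_b) %in% ids))
    expect_true(all(unlist(strsplit(truth$hotspots$members, ",")) %in% ids))
    expect_true(all(truth$degs$gene_id %in% ids))
    expect_true(all(truth$motif_hits$gene_id %in% ids))
    expect_true(all(names(truth$family_of) %in% ids))
    expect_setequal(unique(truth$family_of), monolignolFamilies())
    ## catalogue annotation agrees with the truth map
    expect_equal(unname(familyOf(study$catalog)[ids]),
                 unname(truth$family_of[ids]))
    ## unplaced genes carry subgenome "none", placed genes At/Bt
    sg <- subgenomeOf(study$catalog)
    df <- as.data.frame(study$catalog)
    expect_true(all(sg[startsWith(df$chromosome, "scaffold")] == "none"))
    expect_true(all(sg[startsWith(df$chromosome, "A")] == "At"))
})

test_that("generator preconditions are enforced", {
    expect_error(generateGenome(1, duplicateSpec = data.frame(
        family = "PAL", identity = 1.2, coverage = 1, tandem = FALSE)),
        "identities")
    expect_error(generateGenome(1, hotspotSpec = data.frame(
        chromosome = "B16", family = "COMT", n = 3L, span_bp = 3e6)),
        "at least 5")
    expect_error(generateGenome(1, hotspotSpec = data.frame(
        chromosome = "B16", family = "COMT", n = 6L, span_bp = 6e6)),
        "under 5 Mb")
    expect_error(generateCounts(1, "g1", nbDispersion = 0), "dispersion")
    expect_error(generatePromoters(1, "g1", promoterLength = 5),
                 "longer than the promoter")
    expect_error(generatePhenotypes(1, genotypes = c("a", "b")),
                 "3 genotypes")
    expect_error(generatePhenotypes(1, targetCorrelation = -2), "\\[-1, 1\\]")
})

test_that("count generation is deterministic and respects planted effects", {
    ids <- sprintf("g%d", 1:50)
    a <- generateCounts(9, ids)
    b <- generateCounts(9, ids)
    expect_identical(a$counts, b$counts)

    planted <- data.frame(gene_id = c("g1", "g2"), log2fc = c(-2, 2))
    sim <- generateCounts(10, ids, plantedDegs = planted)
    tall <- defaultSampleSheet()$height_class == "tall"
    expect_lt(mean(sim$counts["g1", tall]), mean(sim$counts["g1", !tall]))
    expect_gt(mean(sim$counts["g2", tall]), mean(sim$counts["g2", !tall]))
    expect_equal(sim$degs$direction, c("up_in_short", "up_in_tall"))
})

test_that("phenotype generation hits the target correlation and the formula", {
    ph <- generatePhenotypes(31)
    expect_lte(abs(cor(ph$height_cm, ph$lignin_mg_per_g) + 0.62), 0.1)
    expect_true(all(abs(ph$lignin_mg_per_g -
                        2.184 * ph$delta_A / ph$dry_weight_g) < 1e-9))
    expect_identical(generatePhenotypes(31), generatePhenotypes(31))

    perfect <- generatePhenotypes(32, targetCorrelation = -1)
    expect_lte(cor(perfect$height_cm, perfect$lignin_mg_per_g), -0.9)
})

test_that("promoter generation is deterministic and plants what it records", {
    ids <- sprintf("g%d", 1:10)
    a <- generatePromoters(77, ids)
    b <- generatePromoters(77, ids)
    expect_identical(as.character(a$promoters), as.character(b$promoters))
    expect_true(all(Biostrings::width(a$promoters) == 2000))
    ## each recorded hit is present in the sequence
    for (k in seq_len(nrow(a$hits))) {
        h <- a$hits[k, ]
        motif <- defaultMotifVocabulary()
        pat <- motif$sequence[motif$motif_id == h$motif_id]
        found <- scanMotifs(a$promoters[h$gene_id],
                            stats::setNames(pat, h$motif_id))
        expect_true(any(found$offset == h$offset & found$strand == h$strand),
                    info = paste(h$gene_id, h$motif_id, h$offset, h$strand))
    }
})

test_that("planted duplicate identities are hit within one percent", {
    g <- generateGenome(88, genesPerFamily = 5, nUnplaced = 0,
                        hotspotSpec = defaultHotspotSpec()[0, ],
                        duplicateSpec = data.frame(
                            family = c("PAL", "CCR"),
                            identity = c(0.85, 0.95),
                            coverage = c(1, 1),
                            tandem = c(FALSE, FALSE)))
    for (k in seq_len(nrow(g$truth$duplicate_pairs))) {
        tr <- g$truth$duplicate_pairs[k, ]
        al <- alignLocal(g$cds[[tr$gene_a]], g$cds[[tr$gene_b]])
        expect_lte(abs(al$identity - tr$identity), 0.01, )
        expect_gt(al$coverage_longer, 0.99)
    }
})
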