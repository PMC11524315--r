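mkSamples <- function() defaultSampleSheet()

mkFpkm <- function(counts, lengths = NULL) {
    if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
    computeFpkm(counts, lengths, mkSamples())
}

test_that("FPKM follows the length/depth normalisation formula", {
    ## count 10, length 1000 bp, library 1e6 -> FPKM 10
    counts <- matrix(0L, 2, 12,
                     dimnames = list(c("g1", "g2"), mkSamples()$sample_id))
    counts[1, 1] <- 10L
    counts[2, 1] <- 1e6L - 10L
    counts[, 2:12] <- 1L
    fe <- computeFpkm(counts, c(1000, 5000), mkSamples())
    expect_equal(fpkm(fe)["g1", 1], 10.0)

    ## all-zero gene -> FPKM 0 everywhere
    expect_true(all(fpkm(fe)["g1", 2:12] >= 0))
    counts2 <- counts; counts2[1, ] <- 0L
    fe2 <- computeFpkm(counts2, c(1000, 5000), mkSamples())
    expect_equal(unname(fpkm(fe2)["g1", ]), rep(0, 12),
                 ignore_attr = TRUE)

    ## doubling a sample's counts leaves its FPKM column unchanged
    set.seed(70)
    counts3 <- matrix(rpois(60, 100) + 1L, 5, 12,
                      dimnames = list(sprintf("g%d", 1:5),
                                      mkSamples()$sample_id))
    fe3 <- mkFpkm(counts3)
    counts4 <- counts3; counts4[, 3] <- counts3[, 3] * 2L
    fe4 <- mkFpkm(counts4)
    expect_equal(fpkm(fe4)[, 3], fpkm(fe3)[, 3])

    ## zero library size is an error
    counts5 <- counts3; counts5[, 1] <- 0L
    expect_error(mkFpkm(counts5), "library")
})

test_that("expression filter is strict and idempotent", {
    f <- matrix(c(1.0, 1.0, 1.0,   # exactly 1 everywhere -> dropped
                  1.5, 0,   0,     # one replicate above -> kept
                  0.2, 0.9, 0.3),  # below -> dropped
                3, 3, byrow = TRUE,
                dimnames = list(c("gA", "gB", "gC"), c("s1", "s2", "s3")))
    samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                          genotype = c("X", "X", "Y"), replicate = c(1, 2, 1),
                          height_class = c("tall", "tall", "short"))
    fe <- FPKMExperiment(f, rep(1000, 3), samples)
    kept <- filterExpressed(fe)
    expect_equal(rownames(kept), "gB")
    expect_equal(rownames(filterExpressed(kept)), "gB")
})

test_that("BH adjustment equals the step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.42), 0.42)
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")

    ## exhaustive on the 0.05-step grid for short vectors
    grid <- seq(0, 1, by = 0.05)
    for (m in 1:3) {
        combos <- as.matrix(expand.grid(rep(list(grid), m)))
        got <- apply(combos, 1, function(p) bhAdjust(unname(p)))
        want <- apply(combos, 1, function(p) bhOracle(unname(p)))
        expect_equal(got, want, info = paste("length", m))
    }
    ## large fixed-seed samples of the grid for lengths 4..8
    set.seed(71)
    for (m in 4:8) {
        combos <- matrix(sample(grid, 400 * m, replace = TRUE), ncol = m)
        got <- apply(combos, 1, bhAdjust)
        want <- apply(combos, 1, bhOracle)
        expect_equal(got, want, info = paste("length", m))
    }
})

test_that("DEG calling applies the fold-change + FDR rule with directions", {
    set.seed(72)
    counts <- matrix(rpois(120, 400) + 1L, 10, 12,
                     dimnames = list(sprintf("g%d", 1:10),
                                     mkSamples()$sample_id))
    fe <- mkFpkm(counts)
    ## identical groups -> no DEGs
    degs <- callDegs(fe)
    expect_true(all(!degs$is_deg[degs$q_value > 0.05 | abs(degs$log2fc) < 1]))
    expect_equal(sum(degs$is_deg), 0)

    ## is_deg is exactly the conjunction of the two criteria
    expect_equal(degs$is_deg,
                 abs(degs$log2fc) >= 1 & degs$q_value < 0.05)

    ## a strong planted effect is called with the right direction
    tall <- mkSamples()$height_class == "tall"
    counts2 <- counts
    counts2[1, tall] <- counts2[1, tall] * 8L
    fe2 <- mkFpkm(counts2)
    degs2 <- callDegs(fe2)
    expect_true(degs2$is_deg[degs2$gene_id == "g1"])
    expect_equal(degs2$direction[degs2$gene_id == "g1"], "up_in_tall")

    ## fewer than 2 samples per group is an error
    sub <- fe[, c(1, 4, 7)]
    expect_error(callDegs(sub), "2 samples")
})

test_that("null simulations keep the empirical false-call rate at the FDR", {
    nGenes <- 200; nReps <- 50
    falls <- numeric(nReps)
    ids <- sprintf("g%03d", seq_len(nGenes))
    for (r in seq_len(nReps)) {
        sim <- generateCounts(1000 + r, ids, plantedDegs = NULL)
        fe <- computeFpkm(sim$counts, rep(1200, nGenes), mkSamples())
        degs <- callDegs(filterExpressed(fe))
        falls[r] <- mean(degs$q_value < 0.05)
    }
    ## binomial slack on 200 x 50 = 10000 null tests
    expect_lte(mean(falls), 0.05 + 2 * sqrt(0.05 * 0.95 / (nGenes * nReps)))
})

test_that("planted DEGs at |log2FC| = 2 are recovered with high sensitivity", {
    nGenes <- 200
    ids <- sprintf("g%03d", seq_len(nGenes))
    planted <- data.frame(gene_id = ids[seq(1, 200, by = 5)],
                          log2fc = rep(c(-2, -2, -2, 2), 10))
    sim <- generateCounts(77, ids, plantedDegs = planted,
                          nbDispersion = 0.05, baseMean = 500)
    fe <- computeFpkm(sim$counts, rep(1200, nGenes), mkSamples())
    degs <- callDegs(filterExpressed(fe))
    called <- degs$gene_id[degs$is_deg]
    sensitivity <- mean(planted$gene_id %in% called)
    expect_gte(sensitivity, 0.9)
    falseCalls <- setdiff(called, planted$gene_id)
    expect_lte(length(falseCalls) / max(1, length(called)), 0.05)
})

test_that("heat table is the elementwise log2(FPKM + 1)", {
    f <- matrix(c(0, 1, 7), 1, 3,
                dimnames = list("g", c("s1", "s2", "s3")))
    samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                          genotype = c("X", "X", "Y"), replicate = c(1, 2, 1),
                          height_class = c("tall", "tall", "short"))
    fe <- FPKMExperiment(f, 1000, samples)
    expect_equal(unname(expressionHeatTable(fe)[1, ]), c(0, 1, 3))
})

test_that("DEG fractions format as percentages with two decimals", {
    expect_equal(degFraction(23, 117)$percent, 19.66)
    expect_equal(degFraction(23, 117)$text, "23 of 117 (19.66%)")
})
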