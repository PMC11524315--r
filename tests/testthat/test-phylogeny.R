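test_that("pairwise-deletion distances match hand counts and closed forms", {
    D <- pairwiseDistance(c(a = "AC-T", b = "AG-T"), model = "p")
    expect_equal(D["a", "b"], 1 / 3)
    expect_equal(diag(D), c(a = 0, b = 0))

    ident <- pairwiseDistance(c(x = "ACGT", y = "ACGT"))
    expect_equal(ident["x", "y"], 0)

    ## p = 0.5 -> Poisson d = ln 2
    half <- c(u = strrep("AC", 50), v = strrep("AA", 50))
    expect_equal(pairwiseDistance(half)["u", "v"], log(2))

    ## hand-count oracle on random short gapped alignments
    set.seed(61)
    for (rep in 1:25) {
        L <- sample(4:6, 1)
        a <- sample(c("A", "C", "G", "-"), L, TRUE)
        b <- sample(c("A", "C", "G", "-"), L, TRUE)
        ok <- a != "-" & b != "-"
        if (!any(ok)) {
            expect_error(pairwiseDistance(
                c(a = paste(a, collapse = ""), b = paste(b, collapse = ""))),
                "comparable")
            next
        }
        p <- sum(a[ok] != b[ok]) / sum(ok)
        msa <- c(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
        expect_equal(pairwiseDistance(msa, model = "p")["a", "b"], p)
        if (p < 1)
            expect_equal(pairwiseDistance(msa)["a", "b"], -log(1 - p))
        else
            expect_error(pairwiseDistance(msa), "Poisson")
    }
})

test_that("Poisson distance is monotone in p and first-order equal for small p", {
    p <- seq(0.001, 0.9, by = 0.01)
    d <- -log(1 - p)
    expect_true(all(diff(d) > 0))
    small <- p[p <= 0.01]
    expect_true(all(abs(-log(1 - small) - small) / small < 0.01))
})

test_that("neighbor joining recovers additive topologies", {
    ## 4-taxon additive matrix from ((A:1,B:2):1,(C:3,D:1)) -> split AB|CD
    tr <- ape::read.tree(text = "((A:1,B:2):2,C:3,D:1);")
    D <- ape::cophenetic.phylo(tr)
    est <- njTree(D)
    expect_equal(as.numeric(ape::dist.topo(tr, est)), 0)

    ## random additive matrices, n <= 10
    set.seed(62)
    for (rep in 1:100) {
        tr <- ape::rtree(sample(4:10, 1))
        tr$edge.length <- tr$edge.length + 0.05  # keep edges positive
        D <- ape::cophenetic.phylo(tr)
        est <- njTree(D)
        expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), est)), 0,
                     info = paste("tree", rep))
    }
})

test_that("three-taxon tree solves the three-point formulas", {
    D <- matrix(c(0, 3, 4,
                  3, 0, 5,
                  4, 5, 0), 3, dimnames = list(letters[1:3], letters[1:3]))
    t3 <- njTree(D)
    ## a = (dab + dac - dbc)/2 = 1, b = 2, c = 3
    bl <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
    expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("degenerate distance matrices are rejected", {
    D <- matrix(c(0, 1, 1, 0), 2)
    expect_error(njTree(D), "3 taxa")
    D3 <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3)
    expect_error(njTree(D3), "symmetric")
    D4 <- diag(0, 3); D4[1, 2] <- D4[2, 1] <- NaN
    expect_error(njTree(D4), "NA")
})

test_that("bootstrap support is deterministic and saturates on a clean split", {
    set.seed(63)
    ## two clearly split halves over a long alignment
    left <- strsplit(strrep("A", 500), "")[[1]]
    right <- strsplit(strrep("C", 500), "")[[1]]
    noisy <- function(tpl) {
        idx <- sample(500, 40)
        tpl[idx] <- sample(c("A", "C", "G", "T"), 40, TRUE)
        paste(tpl, collapse = "")
    }
    msa <- c(l1 = noisy(left), l2 = noisy(left), l3 = noisy(left),
             r1 = noisy(right), r2 = noisy(right), r3 = noisy(right))
    bs <- bootstrapSupport(msa, nReps = 200, seed = 9)
    mainSplit <- grepl("^(l1\\|l2\\|l3|r1\\|r2\\|r3)$", bs$support$bipartition)
    expect_true(any(mainSplit))
    expect_equal(bs$support$support[mainSplit], rep(100, sum(mainSplit)))

    bs2 <- bootstrapSupport(msa, nReps = 200, seed = 9)
    expect_identical(bs$support, bs2$support)

    one <- bootstrapSupport(msa, nReps = 1, seed = 4)
    expect_true(all(one$support$support %in% c(0, 100)))

    expect_error(bootstrapSupport(msa, nReps = 0, seed = 1), "nReps")
    expect_error(bootstrapSupport(msa, nReps = 10), "seed")
})

test_that("family classes follow the monophyly rules", {
    gp <- c(m1 = "monocot", m2 = "monocot",
            h1 = "herb_dicot", h2 = "herb_dicot",
            w1 = "woody", w2 = "woody")
    ib <- ape::read.tree(text = "((m1,m2),(h1,h2),(w1,w2));")
    expect_equal(classifyFamily(ib, gp), "Ib")
    ia <- ape::read.tree(text = "((m1,m2),((h1,w1),(h2,w2)));")
    expect_equal(classifyFamily(ia, gp), "Ia")
    ii <- ape::read.tree(text = "((m1,h1),((m2,w1),(h2,w2)));")
    expect_equal(classifyFamily(ii, gp), "II")

    expect_error(classifyFamily(ia, gp[-1]), "without group label")
})

test_that("classification is leaf-order and rooting invariant", {
    gp <- c(m1 = "monocot", m2 = "monocot",
            h1 = "herb_dicot", h2 = "herb_dicot",
            w1 = "woody", w2 = "woody")
    trees <- list(ape::read.tree(text = "((m1,m2),(h1,h2),(w1,w2));"),
                  ape::read.tree(text = "((m1,m2),((h1,w1),(h2,w2)));"),
                  ape::read.tree(text = "((m1,h1),((m2,w1),(h2,w2)));"))
    for (tr in trees) {
        ref <- classifyFamily(tr, gp)
        for (tip in tr$tip.label) {
            rerooted <- ape::unroot(ape::root(tr, outgroup = tip,
                                              resolve.root = TRUE))
            expect_equal(classifyFamily(rerooted, gp), ref)
        }
        rot <- ape::rotateConstr(tr, rev(tr$tip.label))
        expect_equal(classifyFamily(rot, gp), ref)
    }
})

test_that("classification agrees with a rooting-based monophyly oracle", {
    set.seed(64)
    groups <- c("monocot", "herb_dicot", "woody")
    for (rep in 1:100) {
        n <- sample(6:12, 1)
        tr <- ape::unroot(ape::rtree(n))
        labs <- sample(groups, n, TRUE)
        ## ensure all three groups occur
        labs[1:3] <- sample(groups)
        gp <- setNames(labs, tr$tip.label)
        ## sometimes plant a clean group structure so Ia/Ib arise
        if (rep %% 3 == 0) {
            ord <- tr$tip.label[order(match(gp[tr$tip.label], groups))]
            k1 <- sum(gp == "monocot"); k2 <- sum(gp == "herb_dicot")
            nwk <- sprintf("((%s),(%s),(%s));",
                           paste(ord[seq_len(k1)], collapse = ","),
                           paste(ord[k1 + seq_len(k2)], collapse = ","),
                           paste(ord[(k1 + k2 + 1):n], collapse = ","))
            tr <- ape::read.tree(text = nwk)
        }
        expect_equal(classifyFamily(tr, gp), classifyOracle(tr, gp),
                     info = paste("tree", rep))
    }
})

test_that("monophyly detection matches the rooting oracle on random trees", {
    set.seed(65)
    for (rep in 1:60) {
        n <- sample(5:12, 1)
        tr <- ape::unroot(ape::rtree(n))
        leaves <- sample(tr$tip.label, sample(2:(n - 2), 1))
        expect_equal(isMonophyletic(tr, leaves), monophylyOracle(tr, leaves),
                     info = paste("case", rep))
    }
})
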