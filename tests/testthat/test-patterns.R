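test_that("gene standardization gives mean-0 sd-1 rows and drops constants", {
    m <- rbind(A = c(1, 2, 3), B = c(2, 4, 6), C = c(5, 5, 5),
               D = c(9, 7, 8))
    colnames(m) <- paste0("s", 1:3)
    ex <- IKCExpression(m)
    expect_warning(z <- standardizeGenes(ex, rownames(m)), "constant")
    expect_false("C" %in% rownames(z))
    expect_equal(unname(z["A", ]), c(-1, 0, 1))
    expect_equal(z["A", ], z["B", ])   # proportional genes: identical z-rows
    expect_equal(unname(rowMeans(z)), rep(0, 3))
    expect_equal(unname(apply(z, 1, sd)), rep(1, 3))
    mc <- rbind(A = c(1, 1, 1), B = c(2, 2, 2))
    colnames(mc) <- paste0("s", 1:3)
    expect_error(suppressWarnings(
        standardizeGenes(IKCExpression(mc), c("A", "B"))), "constant")
    expect_error(standardizeGenes(ex, "NOPE"), "NOPE")
})

test_that("k-means handles the degenerate k choices", {
    withr::local_seed(8)
    z <- matrix(rnorm(6 * 10), 6, 10,
                dimnames = list(paste0("G", 1:6), paste0("s", 1:10)))
    one <- kmeansPatterns(z, k = 1, seed = 1)
    expect_true(all(one@clusters == 1L))
    each <- kmeansPatterns(z, k = 6, seed = 1)
    expect_equal(sort(unname(each@clusters)), 1:6)  # every gene its own cluster
    expect_error(kmeansPatterns(z, k = 7, seed = 1), "at least k")
})

test_that("k-means recovers well-separated planted blocks and is seed-stable", {
    withr::local_seed(9)
    blocks <- rep(1:3, each = 20)
    centers <- matrix(rnorm(3 * 15, sd = 1), 3, 15) * 6
    z <- centers[blocks, ] + matrix(rnorm(60 * 15, sd = 0.5), 60, 15)
    rownames(z) <- sprintf("G%02d", 1:60)
    colnames(z) <- paste0("s", 1:15)
    fit <- kmeansPatterns(z, k = 3, seed = 5)
    # exact block recovery: the contingency table is a permutation matrix
    tab <- table(blocks, fit@clusters)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    # bitwise-stable membership for a fixed seed
    expect_identical(fit@clusters, kmeansPatterns(z, k = 3, seed = 5)@clusters)
})

test_that("pattern labeling picks argmax/argmin response association", {
    n <- 20
    resp <- rep(c("R", "NR"), each = 10)
    clin <- data.frame(sample_id = paste0("s", 1:n), responder = resp)
    rUp <- ifelse(resp == "R", 1, -1)
    z <- rbind(A1 = rUp, A2 = rUp, B1 = -rUp, B2 = -rUp,
               C1 = rep(c(1, -1), n / 2), C2 = rep(c(-1, 1), n / 2))
    colnames(z) <- clin$sample_id
    assign <- structure(c(1L, 1L, 2L, 2L, 3L, 3L), names = rownames(z))
    pa <- new("PatternAssignment", clusters = assign,
              association = rep(NA_real_, 3), labels = integer(0))
    lab <- labelPatterns(pa, z, clin)
    expect_equal(lab@labels[["immune"]], 1L)
    expect_equal(lab@labels[["keratin"]], 2L)
    gs <- patternGeneSets(lab)
    expect_setequal(geneIds(gs[["IMMUNE"]]), c("A1", "A2"))
    expect_setequal(geneIds(gs[["KERATIN"]]), c("B1", "B2"))

    # relabeling invariance: permuting cluster indices keeps the gene sets
    perm <- c(2L, 3L, 1L)
    pa2 <- new("PatternAssignment", clusters = structure(perm[assign],
               names = names(assign)), association = rep(NA_real_, 3),
               labels = integer(0))
    gs2 <- patternGeneSets(labelPatterns(pa2, z, clin))
    expect_setequal(geneIds(gs2[["IMMUNE"]]), geneIds(gs[["IMMUNE"]]))
    expect_setequal(geneIds(gs2[["KERATIN"]]), geneIds(gs[["KERATIN"]]))

    # exact association tie is an error, not a silent choice
    zTie <- rbind(A = rUp, B = rUp, C = -rUp, D = -rUp)
    colnames(zTie) <- clin$sample_id
    paTie <- new("PatternAssignment",
                 clusters = structure(c(1L, 2L, 3L, 4L),
                                      names = rownames(zTie)),
                 association = rep(NA_real_, 4), labels = integer(0))
    expect_error(labelPatterns(paTie, zTie, clin), "tie")

    # near-null data: labels assigned but flagged as weak
    withr::local_seed(10)
    zNull <- matrix(rnorm(4 * n, sd = 1), 4, n,
                    dimnames = list(c("A", "B", "C", "D"), clin$sample_id))
    zNull <- zNull / 50
    paN <- new("PatternAssignment",
               clusters = structure(c(1L, 1L, 2L, 2L),
                                    names = rownames(zNull)),
               association = rep(NA_real_, 2), labels = integer(0))
    expect_warning(labN <- labelPatterns(paN, zNull, clin), "weak")
    expect_length(labN@labels, 2)
})

test_that("planted programs are recovered cleanly when k matches the truth", {
    sim <- simulateCohort(smallSimConfig(seed = 12))
    genes <- c(sim$truth$immune_genes, sim$truth$keratin_genes)
    norm <- normalizeCounts(sim$expr)
    z <- standardizeGenes(norm, genes)
    fit <- kmeansPatterns(z, k = 2, seed = 3)
    lab <- labelPatterns(fit, z, sim$clinical)
    gs <- patternGeneSets(lab)
    expect_setequal(geneIds(gs[["IMMUNE"]]), sim$truth$immune_genes)
    expect_setequal(geneIds(gs[["KERATIN"]]), sim$truth$keratin_genes)
})

test_that("with forced extra clusters every program gene keeps the right sign", {
    sim <- simulateCohort(smallSimConfig(seed = 12))
    genes <- c(sim$truth$immune_genes, sim$truth$keratin_genes)
    norm <- normalizeCounts(sim$expr)
    z <- standardizeGenes(norm, genes)
    lab <- labelPatterns(kmeansPatterns(z, k = 5, seed = 3), z,
                         sim$clinical)
    cl <- lab@clusters
    assoc <- lab@association
    expect_true(all(assoc[cl[sim$truth$immune_genes]] > 0))
    expect_true(all(assoc[cl[sim$truth$keratin_genes]] < 0))
    # the labeled clusters are pure
    gs <- patternGeneSets(lab)
    expect_true(all(geneIds(gs[["IMMUNE"]]) %in% sim$truth$immune_genes))
    expect_true(all(geneIds(gs[["KERATIN"]]) %in% sim$truth$keratin_genes))
})
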