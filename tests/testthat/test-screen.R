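test_that("rank-sum test matches exact enumeration and degenerate cases", {
    r <- rankSumTest(c(1, 2), c(3, 4))
    expect_equal(r$U, 0)
    expect_equal(r$p, 1 / 3)   # 2 of C(4,2)=6 assignments as extreme
    expect_equal(rankSumTest(c(1, 2, 3), c(1, 2, 3))$p, 1)
    expect_lt(rankSumTest(1:50, 51:100)$p, 1e-10)
    expect_error(rankSumTest(numeric(0), 1), "empty")
})

test_that("BH adjustment reproduces hand step-up computations", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
                 c(0.04, 0.04, 0.04, 0.04))
    expect_equal(bhAdjust(0.37), 0.37)
    expect_equal(bhAdjust(c(0.5, 1.0)), c(1.0, 1.0))
    p <- runif(50)
    expect_true(all(bhAdjust(p) >= p))
    expect_equal(order(bhAdjust(p)[order(p)]), 1:50)  # ranking preserved
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("signature screen keeps top-k per direction with deterministic ties", {
    withr::local_seed(3)
    nR <- 10; nN <- 10
    resp <- c(rep("R", nR), rep("NR", nN))
    clin <- data.frame(sample_id = paste0("s", 1:20), responder = resp)
    base <- matrix(rnorm(45 * 20), 45, 20)
    base[1:20, resp == "R"] <- base[1:20, resp == "R"] + 3   # 20 up in R
    base[21:25, resp == "NR"] <- base[21:25, resp == "NR"] + 3  # 5 up in NR
    rownames(base) <- sprintf("SIG%02d", 1:45)
    colnames(base) <- clin$sample_id
    sel <- screenSignatures(base, clin, topK = 15, pMax = 0.05)
    expect_equal(sum(sel$direction == "up_in_R"), 15)
    expect_equal(sum(sel$direction == "up_in_NR"), 5)
    full <- attr(sel, "full")
    expect_equal(nrow(full), 45)

    # identical rows get identical p and are ordered by name
    dup <- base
    dup["SIG02", ] <- dup["SIG01", ]
    sel2 <- screenSignatures(dup, clin, topK = NULL)
    i1 <- which(sel2$feature == "SIG01")
    i2 <- which(sel2$feature == "SIG02")
    expect_equal(sel2$p[i1], sel2$p[i2])
    expect_lt(i1, i2)

    # null scores: nothing passes, warning raised
    nullm <- matrix(5, 4, 20,
                    dimnames = list(paste0("N", 1:4), clin$sample_id))
    expect_warning(selN <- screenSignatures(nullm, clin), "no signature")
    expect_equal(nrow(selN), 0)

    # a missing response group is an error
    clinOne <- data.frame(sample_id = clin$sample_id, responder = "R")
    expect_error(screenSignatures(base, clinOne, 15), "each response group")
})

test_that("signature gene pooling is a sorted deduplicated union", {
    coll <- GeneSetCollection(list(GeneSet("A", c("g1", "g2")),
                                   GeneSet("B", c("g2", "g3"))))
    expect_identical(poolSignatureGenes(c("A", "B"), coll),
                     c("G1", "G2", "G3"))
    expect_identical(poolSignatureGenes("A", coll), c("G1", "G2"))
    expect_error(poolSignatureGenes(c("A", "ZZ"), coll), "ZZ")
})

test_that("gene candidate screen recovers planted genes and applies caps", {
    withr::local_seed(4)
    n <- 40
    resp <- rep(c("R", "NR"), each = n / 2)
    clin <- data.frame(sample_id = paste0("s", 1:n), responder = resp)
    m <- matrix(rnorm(50 * n), 50, n,
                dimnames = list(sprintf("G%02d", 1:50), clin$sample_id))
    planted <- sprintf("G%02d", 1:7)
    m[planted, resp == "R"] <- m[planted, resp == "R"] + 4
    m["G50", ] <- 1  # constant gene: p = 1, never selected
    ex <- IKCExpression(m)
    sel <- screenGeneCandidates(ex, clin, rownames(m))
    expect_setequal(sel$feature[sel$p < 1e-4], planted)
    expect_false("G50" %in% sel$feature)
    selCap <- screenGeneCandidates(ex, clin, rownames(m), topK = 3)
    expect_lte(sum(selCap$direction == "up_in_R"), 3)
    expect_warning(screenGeneCandidates(ex, clin, c(planted, "NOPE")),
                   "absent")
    expect_error(screenGeneCandidates(ex, clin, c("NO1", "NO2")), "none")
})

test_that("median-of-ratios normalization matches hand computation and DESeq2", {
    m <- cbind(s1 = c(2, 4, 8), s2 = c(4, 8, 16))
    rownames(m) <- c("A", "B", "C")
    ex <- IKCExpression(m, "counts")
    norm <- normalizeCounts(ex)
    sf <- S4Vectors::metadata(norm)$size_factors
    expect_equal(unname(sf[["s2"]] / sf[["s1"]]), 2)
    expect_equal(exprValues(norm)[, "s1"], exprValues(norm)[, "s2"],
                 ignore_attr = TRUE)

    # identical samples: equal size factors
    m2 <- cbind(s1 = c(3, 5), s2 = c(3, 5))
    rownames(m2) <- c("A", "B")
    sf2 <- S4Vectors::metadata(normalizeCounts(
        IKCExpression(m2, "counts")))$size_factors
    expect_equal(unname(sf2[1]), unname(sf2[2]))

    # independent oracle on random all-positive counts
    withr::local_seed(5)
    mr <- matrix(rpois(50 * 8, 40) + 1, 50, 8,
                 dimnames = list(paste0("G", 1:50), paste0("s", 1:8)))
    sfPkg <- S4Vectors::metadata(normalizeCounts(
        IKCExpression(mr, "counts")))$size_factors
    sfRef <- DESeq2::estimateSizeFactorsForMatrix(mr)
    expect_equal(unname(sfPkg), unname(sfRef), tolerance = 1e-10)

    mz <- cbind(s1 = c(0, 0), s2 = c(1, 2))
    rownames(mz) <- c("A", "B")
    expect_error(normalizeCounts(IKCExpression(mz, "counts")), "all-zero")
    expect_error(normalizeCounts(IKCExpression(m, "normalized")), "counts")
})

test_that("differential expression uses pseudocount log2FC and both thresholds", {
    n <- 12
    resp <- rep(c("R", "NR"), each = 6)
    clin <- data.frame(sample_id = paste0("s", 1:n), responder = resp)
    m <- rbind(DIFF = ifelse(resp == "R", 8, 0),
               C1 = rep(10, n), C2 = rep(20, n), C3 = rep(40, n))
    colnames(m) <- clin$sample_id
    de <- differentialExpression(IKCExpression(m, "counts"), clin,
                                 topK = 35, pMax = 0.005)
    expect_identical(de$feature, "DIFF")
    expect_equal(de$log2_fold_change, log2(9))
    expect_identical(de$direction, "up_in_R")
    full <- attr(de, "full")
    expect_equal(full$log2_fold_change[full$feature == "C1"], 0)
    expect_equal(full$p[full$feature == "C1"], 1)

    clinSmall <- clin[c(1, 2, 7, 8), ]
    expect_error(
        differentialExpression(IKCExpression(m[, c(1, 2, 7, 8)], "counts"),
                               clinSmall), ">= 3 samples")
})

test_that("planted strong DE genes are selected on a simulated cohort", {
    sim <- simulateCohort(smallSimConfig(seed = 11))
    de <- differentialExpression(sim$expr, sim$clinical, topK = 35)
    upR <- de$feature[de$direction == "up_in_R"]
    upN <- de$feature[de$direction == "up_in_NR"]
    expect_gt(mean(upR %in% c(sim$truth$immune_genes,
                              sim$truth$checkpoint_genes)), 0.9)
    expect_gt(mean(upN %in% sim$truth$keratin_genes), 0.9)
})

test_that("pseudogene filter removes by biotype and preserves order", {
    bt <- data.frame(symbol = c("B", "C"),
                     biotype = c("processed_pseudogene", "protein_coding"))
    expect_identical(filterPseudogenes(c("A", "B", "C"), bt), c("A", "C"))
    expect_warning(out <- filterPseudogenes(c("A", "B"), NULL), "skipped")
    expect_identical(out, c("A", "B"))
    allPg <- data.frame(symbol = c("A", "B"),
                        biotype = c("pseudogene", "unitary_pseudogene"))
    expect_warning(out2 <- filterPseudogenes(c("A", "B"), allPg), "all input")
    expect_length(out2, 0)
    expect_error(filterPseudogenes("A", data.frame(x = 1)), "symbol")
})

test_that("rank-based screens are invariant to per-gene monotone transforms", {
    withr::local_seed(6)
    n <- 20
    resp <- rep(c("R", "NR"), each = 10)
    clin <- data.frame(sample_id = paste0("s", 1:n), responder = resp)
    m <- matrix(rexp(10 * n) + 0.1, 10, n,
                dimnames = list(paste0("G", 1:10), clin$sample_id))
    base <- attr(screenGeneCandidates(IKCExpression(m), clin, rownames(m),
                                      pMax = 1.1), "full")
    m2 <- m
    m2[3, ] <- log(m[3, ] + 1)      # monotone transform of one gene
    m2[7, ] <- m[7, ]^2
    after <- attr(screenGeneCandidates(IKCExpression(m2), clin, rownames(m2),
                                       pMax = 1.1), "full")
    expect_equal(after$p, base$p)
    expect_equal(after$statistic, base$statistic)
})
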