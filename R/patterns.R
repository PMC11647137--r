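#' Per-gene z-scores across samples
#'
#' Centers and scales each selected gene's expression to mean 0, sd 1
#' (sample sd convention) so that K-means distances are scale-free.
#' Constant genes are dropped with a warning.
#'
#' @param expr an [IKCExpression-class].
#' @param genes gene symbols to standardize (must be in the matrix).
#' @return genes x samples matrix of z-scores.
#' @export
standardizeGenes <- function(expr, genes) {
    genes <- unique(toupper(genes))
    present <- genes %in% geneIds(expr)
    if (!all(present))
        stop2("gene(s) absent from the matrix: ",
              paste(genes[!present], collapse = ", "))
    m <- exprValues(expr)[genes, , drop = FALSE]
    sds <- apply(m, 1L, stats::sd)
    if (all(sds == 0)) stop2("all selected genes are constant")
    if (any(sds == 0)) {
        warn2("dropping ", sum(sds == 0), " constant gene(s)")
        m <- m[sds > 0, , drop = FALSE]
        sds <- sds[sds > 0]
    }
    (m - rowMeans(m)) / sds
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
.kmeansppCenters <- function(x, k) {
    n <- nrow(x)
    centers <- integer(k)
    centers[1L] <- sample.int(n, 1L)
    d2 <- rowSums((x - x[rep(centers[1L], n), , drop = FALSE])^2)
    for (i in seq_len(k - 1L)) {
        probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[i + 1L] <- sample.int(n, 1L, prob = probs)
        nd <- rowSums((x - x[rep(centers[i + 1L], n), , drop = FALSE])^2)
        d2 <- pmin(d2, nd)
    }
    x[centers, , drop = FALSE]
}

# One Lloyd run from given centers; empty clusters are reseeded from the
# point farthest from its assigned center.
.lloyd <- function(x, centers, iterMax = 100L) {
    k <- nrow(centers)
    assign <- integer(nrow(x))
    for (it in seq_len(iterMax)) {
        d <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
            outer(rep(1, nrow(x)), rowSums(centers^2))
        newAssign <- max.col(-d, ties.method = "first")
        for (cl in seq_len(k)) {
            if (!any(newAssign == cl)) {
                far <- which.max(d[cbind(seq_len(nrow(x)), newAssign)])
                newAssign[far] <- cl
            }
        }
        if (identical(newAssign, assign)) break
        assign <- newAssign
        for (cl in seq_len(k))
            centers[cl, ] <- colMeans(x[assign == cl, , drop = FALSE])
    }
    wss <- sum((x - centers[assign, , drop = FALSE])^2)
    list(assign = assign, centers = centers, wss = wss)
}

#' K-means clustering of genes into expression patterns
#'
#' Lloyd's algorithm with Euclidean distance and k-means++ initialization,
#' run \code{nInit} times; the restart with the lowest within-cluster sum
#' of squares wins. Empty clusters are reseeded from the farthest point.
#' Deterministic for a fixed \code{seed}.
#'
#' @param zMatrix genes x samples matrix of z-scores
#'   (from [standardizeGenes()]).
#' @param k number of patterns (default 5).
#' @param nInit number of random restarts (default 25).
#' @param seed RNG seed for initialization.
#' @return A [PatternAssignment-class] (unlabeled).
#' @export
kmeansPatterns <- function(zMatrix, k = 5, nInit = 25, seed = 1L) {
    x <- as.matrix(zMatrix)
    if (nrow(x) < k)
        stop2("need at least k = ", k, " genes, have ", nrow(x))
    best <- withLocalSeed(seed, {
        best <- NULL
        for (i in seq_len(nInit)) {
            fit <- .lloyd(x, .kmeansppCenters(x, k))
            if (is.null(best) || fit$wss < best$wss) best <- fit
        }
        best
    })
    clusters <- best$assign
    names(clusters) <- rownames(x)
    new("PatternAssignment", clusters = clusters,
        association = rep(NA_real_, k), labels = integer(0))
}

#' Label the immune and keratin patterns
#'
#' Scores each cluster by its response association: the mean over member
#' genes of (mean z-score in responders minus mean z-score in
#' non-responders). The cluster with the largest association is the immune
#' pattern (up in responders); the smallest is the keratin pattern (up in
#' non-responders). A tie between clusters is an error (choose a different
#' seed or k) rather than a silent arbitrary choice; if every cluster's
#' association is weak (|assoc| below \code{warnBelow}) a warning flags
#' probably-null data.
#'
#' @param assignment a [PatternAssignment-class] from [kmeansPatterns()].
#' @param zMatrix the z-score matrix the clustering ran on.
#' @param clinical clinical data.frame (sample_id, responder).
#' @param warnBelow association magnitude below which a warning is raised
#'   (default 0.1).
#' @return the assignment with association scores and immune/keratin labels.
#' @export
labelPatterns <- function(assignment, zMatrix, clinical, warnBelow = 0.1) {
    stopifnot(is(assignment, "PatternAssignment"))
    k <- max(assignment@clusters)
    if (k < 2L) stop2("need at least 2 clusters to label patterns")
    resp <- clinical$responder[match(colnames(zMatrix), clinical$sample_id)]
    isR <- !is.na(resp) & resp == "R"
    isN <- !is.na(resp) & resp == "NR"
    if (!any(isR) || !any(isN))
        stop2("both response groups must be present")
    geneDiff <- rowMeans(zMatrix[, isR, drop = FALSE]) -
        rowMeans(zMatrix[, isN, drop = FALSE])
    cl <- assignment@clusters[rownames(zMatrix)]
    assoc <- vapply(seq_len(k), function(i) mean(geneDiff[cl == i]),
                    numeric(1))
    immune <- which.max(assoc)
    keratin <- which.min(assoc)
    if (immune == keratin ||
        sum(assoc == max(assoc)) > 1L || sum(assoc == min(assoc)) > 1L)
        stop2("tied cluster association; rerun with a different seed or k")
    if (max(abs(assoc)) < warnBelow)
        warn2("all cluster associations are weak (|assoc| < ", warnBelow,
              "); patterns may reflect noise")
    new("PatternAssignment", clusters = assignment@clusters,
        association = assoc,
        labels = c(immune = as.integer(immune),
                   keratin = as.integer(keratin)))
}

#' Extract the immune and keratin patterns as gene sets
#'
#' @param assignment a labeled [PatternAssignment-class].
#' @return A [GeneSetCollection-class] with sets \code{IMMUNE} and
#'   \code{KERATIN}.
#' @export
patternGeneSets <- function(assignment) {
    stopifnot(is(assignment, "PatternAssignment"))
    if (!length(assignment@labels))
        stop2("assignment has not been labeled; run labelPatterns() first")
    cl <- assignment@clusters
    GeneSetCollection(list(
        GeneSet("IMMUNE",
                names(cl)[cl == assignment@labels[["immune"]]],
                "genes of the immune (responder-up) pattern"),
        GeneSet("KERATIN",
                names(cl)[cl == assignment@labels[["keratin"]]],
                "genes of the keratin (non-responder-up) pattern")))
}

#' Write a pattern assignment as TSV
#' @param assignment a [PatternAssignment-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePatterns <- function(assignment, path) {
    cl <- assignment@clusters
    df <- data.frame(gene = names(cl), cluster = unname(cl),
                     association = if (all(is.na(assignment@association)))
                         NA_real_ else assignment@association[cl])
    if (length(assignment@labels)) {
        lab <- rep(NA_character_, length(cl))
        lab[cl == assignment@labels[["immune"]]] <- "immune"
        lab[cl == assignment@labels[["keratin"]]] <- "keratin"
        df$pattern <- lab
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
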