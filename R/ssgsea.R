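#' Per-sample rank transform
#'
#' Ranks each sample's expression values from 1 (lowest) to N (highest),
#' averaging ranks at ties. The downstream enrichment statistic depends on
#' expression only through these ranks, which makes it invariant to any
#' strictly increasing per-sample transform of the data.
#'
#' @param expr an [IKCExpression-class] (or a genes x samples matrix).
#' @return numeric genes x samples matrix of ranks; every column sums to
#'   N(N+1)/2.
#' @export
rankTransform <- function(expr) {
    m <- if (is(expr, "IKCExpression")) exprValues(expr) else as.matrix(expr)
    if (nrow(m) < 2L) stop2("need at least 2 genes to rank")
    ranks <- apply(m, 2L, rank, ties.method = "average")
    dimnames(ranks) <- dimnames(m)
    ranks
}

# Walk order of one sample: genes sorted by decreasing rank, ties broken by
# ascending symbol. Returns the position (1 = top) of every gene.
.walkPositions <- function(r) {
    ord <- order(-r, names(r), method = "radix")
    pos <- integer(length(r))
    pos[ord] <- seq_along(r)
    pos
}

#' Single-sample enrichment score (ssGSEA running sum)
#'
#' Walks the genes of one sample in decreasing rank order (ties broken by
#' ascending gene symbol). At each position the weighted fraction of
#' in-set ranks seen so far (weights \eqn{R_g^\alpha}) is compared with the
#' fraction of out-of-set genes seen so far; the enrichment score is the sum
#' of these differences over all positions:
#' \deqn{ES = \sum_i \left( \frac{\sum_{g \in S, pos(g) \le i} R_g^\alpha}
#'   {\sum_{g \in S} R_g^\alpha} -
#'   \frac{|\{g \notin S, pos(g) \le i\}|}{N - |S|} \right).}
#'
#' Genes of the set absent from the ranked vector are dropped with a
#' warning; a set with no overlap, or covering every gene, is an error.
#'
#' @param sampleRanks named numeric vector of one sample's ranks (as one
#'   column of [rankTransform()]).
#' @param geneSet a [GeneSet-class] or character vector of symbols.
#' @param alpha rank-weighting exponent (default 0.25).
#' @return finite numeric scalar.
#' @export
enrichmentScore <- function(sampleRanks, geneSet, alpha = 0.25) {
    genes <- if (is(geneSet, "GeneSet")) geneIds(geneSet)
             else unique(toupper(geneSet))
    nm <- if (is(geneSet, "GeneSet")) geneSet@name else "gene set"
    if (is.null(names(sampleRanks))) stop2("sampleRanks must be named")
    inMat <- genes %in% names(sampleRanks)
    if (!any(inMat))
        stop2("gene set '", nm, "' has no overlap with the matrix genes")
    if (!all(inMat))
        warn2("dropping ", sum(!inMat), " gene(s) of '", nm,
              "' absent from the matrix")
    genes <- genes[inMat]
    N <- length(sampleRanks)
    if (length(genes) >= N)
        stop2("gene set '", nm, "' covers every gene in the matrix")
    r <- sampleRanks
    pos <- .walkPositions(r)
    u <- N - pos + 1          # number of walk positions at/after each gene
    w <- r^alpha
    inS <- names(r) %in% genes
    sum(w[inS] * u[inS]) / sum(w[inS]) -
        (N * (N + 1) / 2 - sum(u[inS])) / (N - sum(inS))
}

#' ssGSEA score matrix for a collection of gene sets
#'
#' Computes the enrichment score of every set in every sample. When
#' \code{normalize = TRUE} (the default, matching the usual ssGSEA
#' convention) every score is divided by the range (max - min) of the raw
#' enrichment scores over the entire matrix, which ties each sample's score
#' to the cohort it was computed in; normalization is a no-op when all
#' scores are equal.
#'
#' @param expr an [IKCExpression-class].
#' @param collection a [GeneSetCollection-class]; every set must overlap the
#'   matrix genes (sets with no overlap are a single error listing them).
#' @param alpha rank-weighting exponent (default 0.25).
#' @param normalize divide by the global score range (default TRUE).
#' @return A [ScoreMatrix-class], signatures x samples.
#' @export
ssgseaScores <- function(expr, collection, alpha = 0.25, normalize = TRUE) {
    stopifnot(is(expr, "IKCExpression"), is(collection, "GeneSetCollection"))
    if (!length(collection)) stop2("empty gene-set collection")
    ranks <- rankTransform(expr)
    genes <- rownames(ranks)
    N <- nrow(ranks)
    setNames <- names(collection)
    memb <- matrix(FALSE, length(collection), N,
                   dimnames = list(setNames, genes))
    dropped <- character(0)
    for (i in seq_along(collection@sets)) {
        g <- collection@sets[[i]]@genes
        hit <- g %in% genes
        if (!all(hit)) dropped <- c(dropped, setNames[i])
        memb[i, g[hit]] <- TRUE
    }
    sizes <- rowSums(memb)
    if (any(sizes == 0L))
        stop2("gene set(s) with no overlap with the matrix: ",
              paste(setNames[sizes == 0L], collapse = ", "))
    if (any(sizes >= N))
        stop2("gene set(s) covering every matrix gene: ",
              paste(setNames[sizes >= N], collapse = ", "))
    if (length(dropped))
        warn2("dropped genes absent from the matrix for set(s): ",
              paste(unique(dropped), collapse = ", "))
    M <- memb * 1
    es <- matrix(NA_real_, length(collection), ncol(ranks),
                 dimnames = list(setNames, colnames(ranks)))
    sumU <- N * (N + 1) / 2
    for (j in seq_len(ncol(ranks))) {
        r <- ranks[, j]
        u <- N - .walkPositions(r) + 1
        w <- r^alpha
        Mu <- as.vector(M %*% u)
        es[, j] <- as.vector(M %*% (w * u)) / as.vector(M %*% w) -
            (sumU - Mu) / (N - sizes)
    }
    if (normalize) {
        rng <- max(es) - min(es)
        if (rng > 0) es <- es / rng
    }
    new("ScoreMatrix", scores = es, alpha = alpha, normalized = normalize)
}

#' Write a score matrix as TSV with a JSON sidecar
#'
#' The sidecar (\code{<path>.json}) records the exponent and normalization
#' flag so a score file is self-describing.
#'
#' @param sm a [ScoreMatrix-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeScores <- function(sm, path) {
    stopifnot(is(sm, "ScoreMatrix"))
    df <- data.frame(signature = rownames(sm@scores), sm@scores,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(alpha = sm@alpha, normalized = sm@normalized),
                         paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}
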