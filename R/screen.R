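#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Thin, validated wrapper around [stats::wilcox.test()]: the p-value is by
#' exact enumeration when both groups have at most 8 observations and there
#' are no ties, and by the normal approximation with tie and continuity
#' correction otherwise. The returned statistic is the Mann-Whitney U for
#' \code{x} (number of (x, y) pairs with x > y, ties counting 1/2).
#'
#' @param x,y non-empty numeric vectors.
#' @return list with elements \code{U} and \code{p} (two-sided).
#' @export
rankSumTest <- function(x, y) {
    if (!length(x) || !length(y)) stop2("empty group in rank-sum test")
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- length(x) <= 8L && length(y) <= 8L && !ties
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    p <- ht$p.value
    if (!is.finite(p)) p <- 1   # fully tied data carries no evidence
    list(U = unname(ht$statistic), p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (same order), capped at 1.
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p) | p < 0 | p > 1))
        stop2("p-values must be in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Rank-sum association screen of a feature matrix
#'
#' Tests every row of \code{features} for a responder vs non-responder
#' difference. The effect is the difference of group medians (R minus NR);
#' the direction is \code{up_in_R} when the effect is positive (falling back
#' to the mean difference at a zero median difference).
#'
#' @param features numeric features x samples matrix with rownames.
#' @param responder character vector of "R"/"NR" aligned with the columns
#'   (NA samples are excluded).
#' @return data.frame with columns feature, statistic, p, adj_p, direction,
#'   effect (one row per feature, input order).
#' @export
rankSumScreen <- function(features, responder) {
    keep <- !is.na(responder)
    features <- features[, keep, drop = FALSE]
    responder <- responder[keep]
    isR <- responder == "R"
    if (sum(isR) < 2L || sum(!isR) < 2L)
        stop2("need at least 2 samples in each response group (have ",
              sum(isR), " R, ", sum(!isR), " NR)")
    n <- nrow(features)
    stat <- p <- eff <- numeric(n)
    for (i in seq_len(n)) {
        xr <- features[i, isR]
        xn <- features[i, !isR]
        ht <- rankSumTest(xr, xn)
        stat[i] <- ht$U
        p[i] <- ht$p
        d <- stats::median(xr) - stats::median(xn)
        if (d == 0) d <- mean(xr) - mean(xn)
        eff[i] <- d
    }
    data.frame(feature = rownames(features), statistic = stat, p = p,
               adj_p = bhAdjust(p),
               direction = ifelse(eff >= 0, "up_in_R", "up_in_NR"),
               effect = eff, stringsAsFactors = FALSE)
}

# Top-k per direction by ascending p; ties by decreasing |effect| then name.
.selectTopPerDirection <- function(tab, topK, pMax) {
    pass <- tab[tab$p < pMax, , drop = FALSE]
    pick <- lapply(c("up_in_R", "up_in_NR"), function(d) {
        sub <- pass[pass$direction == d, , drop = FALSE]
        sub <- sub[order(sub$p, -abs(sub$effect), sub$feature), , drop = FALSE]
        if (!is.null(topK)) sub <- utils::head(sub, topK)
        sub
    })
    out <- do.call(rbind, pick)
    rownames(out) <- NULL
    out
}

#' Screen signature scores for response association
#'
#' Stage 1 of the derivation pipeline: every signature's ssGSEA scores are
#' tested responders vs non-responders with the rank-sum test, and the top
#' \code{topK} signatures per direction (up in R; up in NR) with
#' \code{p < pMax} are kept, ordered by ascending p (ties by absolute
#' effect, then name).
#'
#' @param scores a [ScoreMatrix-class] (or signatures x samples matrix).
#' @param clinical clinical data.frame (needs sample_id, responder).
#' @param topK maximum signatures kept per direction (default 15).
#' @param pMax p-value threshold (default 0.05).
#' @return data.frame of selected signatures (columns as in
#'   [rankSumScreen()]); the complete screen is in \code{attr(, "full")}.
#' @export
screenSignatures <- function(scores, clinical, topK = 15, pMax = 0.05) {
    m <- if (is(scores, "ScoreMatrix")) scores(scores) else as.matrix(scores)
    resp <- clinical$responder[match(colnames(m), clinical$sample_id)]
    full <- rankSumScreen(m, resp)
    sel <- .selectTopPerDirection(full, topK, pMax)
    if (!nrow(sel)) warn2("no signature passed p < ", pMax)
    attr(sel, "full") <- full
    sel
}

#' Pool the member genes of selected signatures
#'
#' @param selected character vector of signature names (or a data.frame with
#'   a \code{feature} column, as returned by [screenSignatures()]).
#' @param collection the [GeneSetCollection-class] the signatures came from.
#' @return sorted character vector: the deduplicated union of member genes.
#' @export
poolSignatureGenes <- function(selected, collection) {
    nm <- if (is.data.frame(selected)) selected$feature else selected
    missing <- setdiff(nm, names(collection))
    if (length(missing))
        stop2("signature(s) not in collection: ",
              paste(missing, collapse = ", "))
    sort(unique(unlist(lapply(nm, function(s) collection[[s]]@genes))))
}

#' Screen candidate genes for response association
#'
#' Rank-sum test of each candidate gene's expression between responders and
#' non-responders. With \code{topK = NULL} all genes with \code{p < pMax}
#' are kept; otherwise at most \code{topK} per direction, ordered by p.
#' Candidates absent from the matrix are dropped with a warning.
#'
#' @param expr an [IKCExpression-class].
#' @param clinical clinical data.frame (sample_id, responder).
#' @param genes candidate gene symbols.
#' @param topK per-direction cap, or NULL for no cap (default).
#' @param pMax p-value threshold (default 0.05).
#' @return data.frame of selected genes; full table in \code{attr(, "full")}.
#' @export
screenGeneCandidates <- function(expr, clinical, genes, topK = NULL,
                                 pMax = 0.05) {
    genes <- unique(toupper(genes))
    present <- genes %in% geneIds(expr)
    if (!any(present))
        stop2("none of the candidate genes are in the expression matrix")
    if (!all(present))
        warn2("dropping ", sum(!present),
              " candidate gene(s) absent from the matrix")
    m <- exprValues(expr)[genes[present], , drop = FALSE]
    resp <- clinical$responder[match(colnames(m), clinical$sample_id)]
    full <- rankSumScreen(m, resp)
    sel <- .selectTopPerDirection(full, topK, pMax)
    attr(sel, "full") <- full
    sel
}

#' Median-of-ratios count normalization
#'
#' Size factor of each sample = median over reference genes (those with a
#' nonzero geometric mean across samples) of that sample's count divided by
#' the gene's geometric mean; each column is divided by its size factor.
#'
#' @param counts an [IKCExpression-class] with \code{valueKind == "counts"}.
#' @return normalized [IKCExpression-class]; size factors are attached as
#'   \code{metadata(x)$size_factors}.
#' @export
normalizeCounts <- function(counts) {
    stopifnot(is(counts, "IKCExpression"))
    if (valueKind(counts) != "counts")
        stop2("normalizeCounts expects raw counts")
    m <- exprValues(counts)
    if (any(colSums(m) == 0))
        stop2("sample(s) with all-zero counts: ",
              paste(colnames(m)[colSums(m) == 0], collapse = ", "))
    logGeo <- rowMeans(log(m))
    ref <- is.finite(logGeo)
    if (!any(ref))
        stop2("no gene has all-positive counts; cannot form reference")
    sf <- apply(m, 2L, function(col)
        exp(stats::median(log(col[ref]) - logGeo[ref])))
    norm <- sweep(m, 2L, sf, "/")
    out <- IKCExpression(norm, "normalized")
    S4Vectors::metadata(out)$size_factors <- sf
    out
}

#' Differential expression between responders and non-responders
#'
#' Counts are normalized by median-of-ratios; each gene gets a pseudocount
#' fold change \code{log2((mean_R + 1) / (mean_NR + 1))} and a rank-sum
#' p-value (BH-adjusted p reported alongside). The candidate pool is genes
#' with \code{p < pMax} and \code{|log2FC| > lfcMin}; the top \code{topK}
#' per direction by ascending p are selected.
#'
#' @param counts an [IKCExpression-class] of raw counts.
#' @param clinical clinical data.frame (sample_id, responder).
#' @param topK per-direction cap (default 35).
#' @param pMax p-value threshold (default 0.005).
#' @param lfcMin absolute log2 fold-change threshold (default 1).
#' @return data.frame of selected genes with columns feature, statistic, p,
#'   adj_p, direction, effect, log2_fold_change; full per-gene table in
#'   \code{attr(, "full")}.
#' @export
differentialExpression <- function(counts, clinical, topK = 35,
                                   pMax = 0.005, lfcMin = 1) {
    norm <- normalizeCounts(counts)
    m <- exprValues(norm)
    resp <- clinical$responder[match(colnames(m), clinical$sample_id)]
    keep <- !is.na(resp)
    if (sum(resp[keep] == "R") < 3L || sum(resp[keep] == "NR") < 3L)
        stop2("differential expression needs >= 3 samples per response group")
    full <- rankSumScreen(m, resp)
    isR <- keep & resp == "R"
    isN <- keep & resp == "NR"
    lfc <- log2((rowMeans(m[, isR, drop = FALSE]) + 1) /
                (rowMeans(m[, isN, drop = FALSE]) + 1))
    full$log2_fold_change <- unname(lfc[full$feature])
    full$direction <- ifelse(full$log2_fold_change >= 0, "up_in_R", "up_in_NR")
    pool <- full[abs(full$log2_fold_change) > lfcMin, , drop = FALSE]
    pool$effect <- pool$log2_fold_change
    sel <- .selectTopPerDirection(pool, topK, pMax)
    attr(sel, "full") <- full
    sel
}

#' Remove pseudogenes from a gene list
#'
#' Genes whose biotype (from a user-supplied symbol-to-biotype table, e.g.
#' GENCODE-derived) contains "pseudogene" are removed; genes absent from
#' the table are kept. Order is preserved.
#'
#' @param genes character vector of symbols.
#' @param biotypeTable data.frame with columns \code{symbol}, \code{biotype},
#'   or NULL/empty to skip filtering (with a warning).
#' @return filtered character vector.
#' @export
filterPseudogenes <- function(genes, biotypeTable = NULL) {
    if (is.null(biotypeTable) || !nrow(biotypeTable)) {
        warn2("no biotype table supplied; pseudogene filter skipped")
        return(genes)
    }
    if (!all(c("symbol", "biotype") %in% names(biotypeTable)))
        stop2("biotype table needs columns 'symbol' and 'biotype'")
    bt <- biotypeTable$biotype[match(toupper(genes),
                                     toupper(biotypeTable$symbol))]
    drop <- !is.na(bt) & grepl("pseudogene", bt, ignore.case = TRUE)
    out <- genes[!drop]
    if (!length(out)) warn2("all input genes were pseudogenes")
    out
}

#' Write a screen or differential-expression table as TSV
#' @param table data.frame as returned by the screen functions.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScreenTable <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
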