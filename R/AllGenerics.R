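#' Gene identifiers of an object
#' @param x an object carrying gene identifiers.
#' @return character vector of upper-case gene symbols.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Sample identifiers of an object
#' @param x an object carrying sample identifiers.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Expression values
#' @param x an [IKCExpression-class].
#' @return numeric genes x samples matrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Declared value kind of an expression matrix
#' @param x an [IKCExpression-class].
#' @return `"counts"` or `"normalized"`.
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' Enrichment scores
#' @param x a [ScoreMatrix-class].
#' @return numeric signatures x samples matrix.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @export
#' @rdname geneIds
setMethod("geneIds", "IKCExpression", function(x) rownames(x))
#' @export
#' @rdname geneIds
setMethod("geneIds", "GeneSet", function(x) x@genes)
#' @export
#' @rdname sampleIds
setMethod("sampleIds", "IKCExpression", function(x) colnames(x))
#' @export
#' @rdname sampleIds
setMethod("sampleIds", "ScoreMatrix", function(x) colnames(x@scores))
#' @export
#' @rdname exprValues
setMethod("exprValues", "IKCExpression",
    function(x) assay(x, withDimnames = TRUE))
#' @export
#' @rdname valueKind
setMethod("valueKind", "IKCExpression", function(x) x@valueKind)
#' @export
#' @rdname scores
setMethod("scores", "ScoreMatrix", function(x) x@scores)

#' Names of the sets in a collection
#' @param x a [GeneSetCollection-class].
#' @export
setMethod("names", "GeneSetCollection",
    function(x) vapply(x@sets, slot, character(1), "name"))

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' Extract one gene set by position or name
#' @param x a [GeneSetCollection-class].
#' @param i index or set name.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) {
    if (is.character(i)) {
        j <- match(i, names(x))
        if (is.na(j)) stop("no gene set named '", i, "'")
        i <- j
    }
    x@sets[[i]]
})

#' Subset a collection, preserving order
#' @param x a [GeneSetCollection-class].
#' @param i indices or set names.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) {
        j2 <- match(i, names(x))
        if (anyNA(j2))
            stop("no gene set named '", paste(i[is.na(j2)], collapse = "', '"), "'")
        i <- j2
    }
    GeneSetCollection(x@sets[i])
})

#' @export
setMethod("show", "GeneSet", function(object) {
    cat("GeneSet '", object@name, "' (", length(object@genes), " genes): ",
        paste(utils::head(object@genes, 5), collapse = ", "),
        if (length(object@genes) > 5) ", ..." else "", "\n", sep = "")
})

#' @export
setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection of", length(object), "sets\n")
    if (length(object))
        cat("  ", paste(utils::head(names(object), 8), collapse = ", "),
            if (length(object) > 8) ", ..." else "", "\n", sep = "")
})

#' @export
setMethod("show", "IKCExpression", function(object) {
    cat("IKCExpression: ", nrow(object), " genes x ", ncol(object),
        " samples (", object@valueKind, ")\n", sep = "")
})

#' @export
setMethod("show", "ScoreMatrix", function(object) {
    cat("ScoreMatrix: ", nrow(object@scores), " signatures x ",
        ncol(object@scores), " samples (alpha = ", object@alpha,
        ", ", if (object@normalized) "range-normalized" else "raw",
        ")\n", sep = "")
})

#' @export
setMethod("show", "IKCProfile", function(object) {
    p <- object@profile
    cat("IKCProfile for", nrow(p), "samples;")
    if (length(object@cutoff))
        cat(" cutoff =", signif(object@cutoff, 4),
            sprintf("(%d high / %d low)\n",
                    sum(p$group == "high"), sum(p$group == "low")))
    else cat(" ungrouped\n")
    cat("  ikc_score range: [", signif(min(p$ikc_score), 4), ", ",
        signif(max(p$ikc_score), 4), "]\n", sep = "")
})

#' @export
setMethod("show", "PatternAssignment", function(object) {
    k <- max(object@clusters)
    cat("PatternAssignment:", length(object@clusters), "genes in", k,
        "patterns\n")
    if (length(object@labels))
        cat("  immune = cluster ", object@labels[["immune"]],
            ", keratin = cluster ", object@labels[["keratin"]], "\n", sep = "")
})
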