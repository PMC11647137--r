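#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom S4Vectors metadata
NULL

#' Bulk expression container
#'
#' An \code{IKCExpression} is a \linkS4class{SummarizedExperiment} holding one
#' genes-by-samples assay (\code{"exprs"}) together with a declared value kind:
#' \code{"counts"} (non-negative raw counts, the input of the differential
#' expression stage) or \code{"normalized"} (library-size corrected or
#' otherwise continuous values). Gene identifiers are upper-case HGNC-style
#' symbols and are unique; sample identifiers are unique.
#'
#' @slot valueKind either \code{"counts"} or \code{"normalized"}.
#' @seealso [IKCExpression()] for the validating constructor,
#'   [readExpression()] to load a TSV file.
#' @exportClass IKCExpression
setClass("IKCExpression",
    contains = "SummarizedExperiment",
    slots = c(valueKind = "character"),
    prototype = prototype(valueKind = "normalized"))

setValidity("IKCExpression", function(object) {
    msg <- character()
    m <- assay(object, withDimnames = TRUE)
    if (!object@valueKind %in% c("counts", "normalized"))
        msg <- c(msg, "valueKind must be 'counts' or 'normalized'")
    if (nrow(m) < 2L || ncol(m) < 2L)
        msg <- c(msg, "need at least 2 genes and 2 samples")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "gene and sample identifiers are required")
    if (anyDuplicated(rownames(m)))
        msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(m)))
        msg <- c(msg, "duplicate sample identifiers")
    if (!is.numeric(m) || any(!is.finite(m)))
        msg <- c(msg, "all expression values must be finite numbers")
    else if (object@valueKind == "counts" && any(m < 0))
        msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Construct an IKCExpression object
#'
#' @param values numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns (colnames = sample ids). Symbols are upper-cased.
#' @param valueKind `"counts"` or `"normalized"`.
#' @return A validated [IKCExpression-class] object.
#' @examples
#' m <- matrix(rpois(20, 10), 4, 5,
#'     dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' ex <- IKCExpression(m, "counts")
#' geneIds(ex)
#' @export
IKCExpression <- function(values, valueKind = c("normalized", "counts")) {
    valueKind <- match.arg(valueKind)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    rownames(values) <- toupper(rownames(values))
    se <- SummarizedExperiment(assays = list(exprs = values))
    new("IKCExpression", se, valueKind = valueKind)
}

#' A named gene set
#'
#' @slot name unique set name.
#' @slot description free-text description (may be empty).
#' @slot genes character vector of unique upper-case gene symbols.
#' @exportClass GeneSet
setClass("GeneSet",
    slots = c(name = "character", description = "character",
              genes = "character"))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    if (length(object@genes) == 0L)
        msg <- c(msg, "gene set is empty")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "duplicate genes in set")
    if (length(msg)) msg else TRUE
})

#' @rdname GeneSet-class
#' @param name,description,genes see slots.
#' @export
GeneSet <- function(name, genes, description = "") {
    new("GeneSet", name = as.character(name),
        description = as.character(description),
        genes = unique(toupper(as.character(genes))))
}

#' An ordered collection of gene sets
#'
#' Set order is preserved from the source (GMT) file and set names are
#' unique within a collection.
#'
#' @slot sets list of [GeneSet-class] objects.
#' @exportClass GeneSetCollection
setClass("GeneSetCollection", slots = c(sets = "list"))

setValidity("GeneSetCollection", function(object) {
    if (!all(vapply(object@sets, is, logical(1), "GeneSet")))
        return("all elements must be GeneSet objects")
    if (anyDuplicated(vapply(object@sets, slot, character(1), "name")))
        return("duplicate gene-set names in collection")
    TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets a list of [GeneSet-class] objects.
#' @export
GeneSetCollection <- function(sets = list()) {
    new("GeneSetCollection", sets = unname(sets))
}

#' Signature-by-sample enrichment scores
#'
#' Holds the ssGSEA score matrix (signatures in rows, samples in columns)
#' with the exponent used and whether cohort-level range normalization was
#' applied.
#'
#' @slot scores numeric matrix, signatures x samples.
#' @slot alpha rank-weighting exponent used.
#' @slot normalized whether scores were divided by the global ES range.
#' @exportClass ScoreMatrix
setClass("ScoreMatrix",
    slots = c(scores = "matrix", alpha = "numeric", normalized = "logical"))

setValidity("ScoreMatrix", function(object) {
    msg <- character()
    if (any(!is.finite(object@scores)))
        msg <- c(msg, "scores must be finite")
    if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
        msg <- c(msg, "score matrix must carry signature and sample names")
    if (object@normalized &&
        diff(range(object@scores)) > 1 + 1e-8)
        msg <- c(msg, "normalized scores must span at most 1")
    if (length(msg)) msg else TRUE
})

#' Per-sample component and composite scores
#'
#' One row per sample with the Immune, Keratin (KRT) and Immune Checkpoint
#' ssGSEA scores, the composite score
#' \code{ikc_score = immune_score + checkpoint_score - krt_score}
#' (an exact identity enforced by the class validity), and an optional
#' high/low group label once a cutoff has been applied.
#'
#' @slot profile data.frame with columns sample_id, immune_score, krt_score,
#'   checkpoint_score, ikc_score, group (NA until [dichotomize()] is called).
#' @slot cutoff numeric(0) until a cutoff is applied.
#' @exportClass IKCProfile
setClass("IKCProfile",
    slots = c(profile = "data.frame", cutoff = "numeric"))

setValidity("IKCProfile", function(object) {
    p <- object@profile
    need <- c("sample_id", "immune_score", "krt_score", "checkpoint_score",
              "ikc_score", "group")
    if (!all(need %in% names(p)))
        return(paste("profile must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(p$sample_id))
        return("duplicate sample ids")
    if (max(abs(p$ikc_score -
            (p$immune_score + p$checkpoint_score - p$krt_score))) > 1e-8)
        return("ikc_score must equal immune + checkpoint - krt")
    if (!all(p$group %in% c("high", "low", NA_character_)))
        return("group must be 'high', 'low' or NA")
    grouped <- !any(is.na(p$group))
    if (grouped && length(object@cutoff) != 1L)
        return("grouped profile must record its cutoff")
    if (!grouped && any(!is.na(p$group)))
        return("group labels must be all present or all absent")
    TRUE
})

#' Gene expression pattern assignment
#'
#' The result of K-means pattern discovery on response-associated genes:
#' every gene is assigned to one of k clusters; after labeling, the cluster
#' whose genes are most up-regulated in responders is the immune pattern
#' and the most non-responder-skewed cluster is the keratin pattern.
#'
#' @slot clusters named integer vector, gene -> cluster in 1..k.
#' @slot association per-cluster mean standardized responder-minus-
#'   non-responder difference (length k; NA before labeling).
#' @slot labels named integer vector with elements "immune" and "keratin"
#'   (empty before labeling).
#' @exportClass PatternAssignment
setClass("PatternAssignment",
    slots = c(clusters = "integer", association = "numeric",
              labels = "integer"))

setValidity("PatternAssignment", function(object) {
    k <- max(object@clusters)
    if (is.null(names(object@clusters)))
        return("clusters must be named by gene")
    if (!all(object@clusters >= 1L))
        return("cluster indices must be in 1..k")
    if (length(object@labels)) {
        if (!setequal(names(object@labels), c("immune", "keratin")))
            return("labels must name 'immune' and 'keratin'")
        if (object@labels[["immune"]] == object@labels[["keratin"]])
            return("immune and keratin labels must differ")
        if (any(object@labels < 1L | object@labels > k))
            return("labels must reference existing clusters")
    }
    TRUE
})
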