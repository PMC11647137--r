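#' Read a genes-by-samples expression matrix from TSV
#'
#' The file must have a header row of sample identifiers and gene symbols in
#' the first column (conventionally named \code{gene}). Symbols are
#' upper-cased at ingestion; duplicate symbol rows are collapsed to their
#' per-sample mean (a message reports how many). With \code{transpose = TRUE}
#' the file is read as samples-in-rows and flipped.
#'
#' @param path TSV file path.
#' @param valueKind `"counts"` (validated non-negative) or `"normalized"`.
#' @param transpose set to \code{TRUE} for samples-in-rows files.
#' @return An [IKCExpression-class].
#' @export
readExpression <- function(path, valueKind = c("normalized", "counts"),
                           transpose = FALSE) {
    valueKind <- match.arg(valueKind)
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character",
                             check.names = FALSE, quote = "")
    if (ncol(raw) < 3L)
        stop2("expression file needs a gene column plus at least 2 samples: ",
              path)
    ids <- raw[[1L]]
    vals <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                   dimnames = list(NULL, colnames(raw)[-1L]))
    for (j in seq_len(ncol(raw) - 1L)) {
        col <- raw[[j + 1L]]
        num <- suppressWarnings(as.numeric(col))
        bad <- which(is.na(num))
        if (length(bad))
            stop2("non-numeric value '", col[bad[1L]], "' at row ", bad[1L],
                  " (gene ", ids[bad[1L]], "), column '",
                  colnames(raw)[j + 1L], "' of ", path)
        vals[, j] <- num
    }
    rownames(vals) <- toupper(ids)
    if (transpose) {
        vals <- t(vals)
        # after transposing, rows are genes taken from the header
        rownames(vals) <- toupper(rownames(vals))
    }
    if (anyDuplicated(rownames(vals))) {
        ndup <- sum(duplicated(rownames(vals)))
        message("collapsing ", ndup, " duplicate gene row(s) by mean")
        vals <- rowsum(vals, group = rownames(vals), reorder = FALSE) /
            as.vector(table(rownames(vals))[unique(rownames(vals))])
    }
    IKCExpression(vals, valueKind)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpression()]: first column \code{gene}, one column per
#' sample.
#'
#' @param expr an [IKCExpression-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(expr, path) {
    stopifnot(is(expr, "IKCExpression"))
    m <- exprValues(expr)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is tab-separated: set name, description, then one or more gene
#' symbols. Genes are upper-cased and deduplicated per set; the order of sets
#' in the file is preserved.
#'
#' @param path GMT file path.
#' @return A [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop2("empty GMT file: ", path)
    sets <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop2("GMT line ", i, " has fewer than 3 fields (name, ",
                  "description, >=1 gene): ", path)
        sets[[i]] <- GeneSet(f[1L], f[-(1:2)], description = f[2L])
    }
    nm <- vapply(sets, slot, character(1), "name")
    if (anyDuplicated(nm))
        stop2("duplicate gene-set name(s) in ", path, ": ",
              paste(unique(nm[duplicated(nm)]), collapse = ", "))
    GeneSetCollection(sets)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a non-empty [GeneSetCollection-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(collection, path) {
    stopifnot(is(collection, "GeneSetCollection"))
    if (!length(collection)) stop2("refusing to write an empty collection")
    lines <- vapply(collection@sets, function(s) {
        paste(c(s@name, if (nzchar(s@description)) s@description else "na",
                s@genes), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

.RESPONSE_CLASSES <- c("CR", "PR", "SD", "PD")

#' Derive responder status from RECIST response class
#'
#' Complete and partial responses (CR/PR) are responders (\code{"R"});
#' stable and progressive disease (SD/PD) are non-responders (\code{"NR"}).
#' \code{NA} propagates.
#'
#' @param responseClass character vector of CR/PR/SD/PD (or NA).
#' @return character vector of "R"/"NR"/NA.
#' @export
responderFromResponse <- function(responseClass) {
    bad <- setdiff(unique(responseClass[!is.na(responseClass)]),
                   .RESPONSE_CLASSES)
    if (length(bad))
        stop2("unknown response class token(s): ", paste(bad, collapse = ", "))
    out <- rep(NA_character_, length(responseClass))
    out[responseClass %in% c("CR", "PR")] <- "R"
    out[responseClass %in% c("SD", "PD")] <- "NR"
    out
}

#' Read a clinical table from TSV
#'
#' Required column: \code{sample_id}. Recognized optional columns:
#' \code{response} (RECIST class CR/PR/SD/PD), \code{pfs_time} (months, > 0),
#' \code{pfs_event} (0/1), \code{pdl1_tps} (percent, 0-100), \code{tmb}
#' (mutations/Mb, >= 0), \code{tumor_purity} (fraction, 0-1). Extra columns
#' are ignored. A binary \code{responder} column (R = CR/PR, NR = SD/PD) is
#' derived.
#'
#' @param path TSV file path.
#' @return data.frame with validated, typed columns.
#' @export
readClinical <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, quote = "",
                            stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    if (!"sample_id" %in% names(df))
        stop2("clinical table must have a 'sample_id' column: ", path)
    out <- data.frame(sample_id = as.character(df$sample_id),
                      stringsAsFactors = FALSE)
    if (anyDuplicated(out$sample_id))
        stop2("duplicate sample_id in clinical table")
    out$response <- if ("response" %in% names(df))
        as.character(df$response) else NA_character_
    out$responder <- responderFromResponse(out$response)
    hasTime <- "pfs_time" %in% names(df)
    hasEvent <- "pfs_event" %in% names(df)
    if (hasTime && !hasEvent)
        stop2("pfs_time present without pfs_event")
    if (hasTime) {
        out$pfs_time <- as.numeric(df$pfs_time)
        out$pfs_event <- as.numeric(df$pfs_event)
        if (any(out$pfs_time <= 0, na.rm = TRUE))
            stop2("pfs_time must be positive")
        if (!all(out$pfs_event %in% c(0, 1, NA)))
            stop2("pfs_event must be 0 or 1")
        if (any(!is.na(out$pfs_time) & is.na(out$pfs_event)))
            stop2("pfs_event missing for sample(s) with pfs_time")
    }
    if ("pdl1_tps" %in% names(df)) {
        out$pdl1_tps <- as.numeric(df$pdl1_tps)
        if (any(out$pdl1_tps < 0 | out$pdl1_tps > 100, na.rm = TRUE))
            stop2("pdl1_tps must be in [0, 100]")
    }
    if ("tmb" %in% names(df)) {
        out$tmb <- as.numeric(df$tmb)
        if (any(out$tmb < 0, na.rm = TRUE)) stop2("tmb must be >= 0")
    }
    if ("tumor_purity" %in% names(df)) {
        out$tumor_purity <- as.numeric(df$tumor_purity)
        if (any(out$tumor_purity < 0 | out$tumor_purity > 1, na.rm = TRUE))
            stop2("tumor_purity must be in [0, 1]")
    }
    out
}

#' Write a clinical table as TSV
#' @param clinical data.frame as returned by [readClinical()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClinical <- function(clinical, path) {
    utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' The packaged gene-symbol alias table
#'
#' Maps common aliases (e.g. the checkpoint literature's \code{PDL1}) to
#' canonical HGNC symbols (\code{CD274}) and lists the canonical checkpoint
#' symbols themselves so they are recognized. Users can supply their own
#' two-column (alias, symbol) TSV to [mapGeneSymbols()].
#'
#' @return data.frame with columns \code{alias}, \code{symbol}.
#' @export
defaultAliasTable <- function() {
    path <- system.file("extdata", "gene_aliases.tsv", package = "IKCscore",
                        mustWork = TRUE)
    readAliasTable(path)
}

#' Read an alias table from a two-column TSV
#' @param path TSV with header columns \code{alias} and \code{symbol}.
#' @return data.frame with upper-cased \code{alias}, \code{symbol} columns.
#' @export
readAliasTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("alias", "symbol") %in% names(df)))
        stop2("alias table needs columns 'alias' and 'symbol'")
    df$alias <- toupper(df$alias)
    df$symbol <- toupper(df$symbol)
    conflict <- unique(df$alias[duplicated(df$alias)])
    conflict <- conflict[vapply(conflict, function(a)
        length(unique(df$symbol[df$alias == a])) > 1L, logical(1))]
    if (length(conflict))
        stop2("conflicting duplicate alias(es): ",
              paste(conflict, collapse = ", "))
    unique(df[, c("alias", "symbol")])
}

#' Map gene symbols through an alias table
#'
#' Aliases are replaced by their canonical symbol; symbols not present in
#' the table (as alias or canonical) pass through unchanged with one warning
#' listing them. Order is preserved.
#'
#' @param genes character vector of symbols (case-insensitive).
#' @param aliasTable data.frame (alias, symbol); defaults to the packaged
#'   table from [defaultAliasTable()].
#' @return character vector of mapped upper-case symbols.
#' @export
mapGeneSymbols <- function(genes, aliasTable = defaultAliasTable()) {
    if (!length(genes)) return(character(0))
    if (!all(c("alias", "symbol") %in% names(aliasTable)))
        stop2("alias table needs columns 'alias' and 'symbol'")
    conflict <- unique(aliasTable$alias[duplicated(aliasTable$alias)])
    conflict <- conflict[vapply(conflict, function(a)
        length(unique(aliasTable$symbol[aliasTable$alias == a])) > 1L,
        logical(1))]
    if (length(conflict))
        stop2("conflicting duplicate alias(es): ",
              paste(conflict, collapse = ", "))
    g <- toupper(genes)
    hit <- match(g, toupper(aliasTable$alias))
    out <- ifelse(is.na(hit), g, aliasTable$symbol[hit])
    known <- is.na(hit) & g %in% toupper(aliasTable$symbol)
    unknown <- unique(g[is.na(hit) & !known])
    if (length(unknown))
        warn2("symbol(s) not in alias table, passed through: ",
              paste(unknown, collapse = ", "))
    out
}
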