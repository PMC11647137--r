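#' The immune checkpoint gene set
#'
#' The seven canonical checkpoint genes (PD-L1, PD-L2, CTLA-4, PD-1, LAG-3,
#' TIM-3, TIGIT), alias-mapped to HGNC symbols (so \code{PDL1} becomes
#' \code{CD274}).
#'
#' @param aliasTable alias table (default: the packaged one).
#' @return A [GeneSet-class] named \code{CHECKPOINT} with 7 genes.
#' @export
checkpointGeneSet <- function(aliasTable = defaultAliasTable()) {
    literature <- c("PDL1", "PDCD1LG2", "CTLA4", "PDCD1", "LAG3", "HAVCR2",
                    "TIGIT")
    GeneSet("CHECKPOINT", mapGeneSymbols(literature, aliasTable),
            "immune checkpoint genes")
}

#' Compute Immune, Keratin, Checkpoint and composite scores
#'
#' The three component scores are ssGSEA scores of the immune-pattern,
#' keratin-pattern and checkpoint gene sets, normalized jointly (one
#' [ssgseaScores()] call over the 3 x samples score matrix) so that they
#' share one scale; the composite is
#' \code{ikc_score = immune_score + checkpoint_score - krt_score}.
#'
#' @param expr an [IKCExpression-class].
#' @param immuneSet,krtSet [GeneSet-class] (or character vectors) for the
#'   immune and keratin patterns.
#' @param ckptSet checkpoint [GeneSet-class]; default [checkpointGeneSet()].
#' @param alpha ssGSEA exponent (default 0.25).
#' @return An ungrouped [IKCProfile-class].
#' @export
computeComponents <- function(expr, immuneSet, krtSet,
                              ckptSet = checkpointGeneSet(), alpha = 0.25) {
    asSet <- function(x, nm) if (is(x, "GeneSet")) x else GeneSet(nm, x)
    coll <- GeneSetCollection(list(
        GeneSet("IMMUNE", geneIds(asSet(immuneSet, "IMMUNE"))),
        GeneSet("KERATIN", geneIds(asSet(krtSet, "KERATIN"))),
        GeneSet("CHECKPOINT", geneIds(asSet(ckptSet, "CHECKPOINT")))))
    sm <- ssgseaScores(expr, coll, alpha = alpha, normalize = TRUE)
    s <- scores(sm)
    prof <- data.frame(sample_id = colnames(s),
                       immune_score = s["IMMUNE", ],
                       krt_score = s["KERATIN", ],
                       checkpoint_score = s["CHECKPOINT", ],
                       stringsAsFactors = FALSE)
    prof$ikc_score <- prof$immune_score + prof$checkpoint_score -
        prof$krt_score
    prof$group <- NA_character_
    rownames(prof) <- NULL
    new("IKCProfile", profile = prof, cutoff = numeric(0))
}

#' Split samples into high and low score groups
#'
#' A sample is \code{high} iff its composite score is strictly greater than
#' the cutoff (a boundary sample goes to \code{low}). A cutoff outside the
#' observed score range leaves one group empty and raises a warning.
#'
#' @param profile an [IKCProfile-class].
#' @param cutoff numeric cutoff, e.g. from [optimalCutoff()].
#' @return the profile with group labels and the cutoff recorded.
#' @export
dichotomize <- function(profile, cutoff) {
    stopifnot(is(profile, "IKCProfile"), is.numeric(cutoff),
              length(cutoff) == 1L)
    p <- profile@profile
    if (cutoff < min(p$ikc_score) || cutoff >= max(p$ikc_score))
        warn2("cutoff ", signif(cutoff, 4),
              " is outside the observed score range; one group is empty")
    p$group <- ifelse(p$ikc_score > cutoff, "high", "low")
    new("IKCProfile", profile = p, cutoff = cutoff)
}

#' Per-sample score table of a profile
#' @param profile an [IKCProfile-class].
#' @return data.frame with sample_id, the three component scores,
#'   ikc_score and group.
#' @export
profileTable <- function(profile) {
    stopifnot(is(profile, "IKCProfile"))
    profile@profile
}

#' Write an IKC profile as TSV
#' @param profile an [IKCProfile-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProfile <- function(profile, path) {
    utils::write.table(profileTable(profile), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
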