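#' Pipeline configuration
#'
#' The defaults are the reference preset of the derivation pipeline: top 15
#' signatures per direction at p < 0.05, top 35 differential genes per
#' direction at p < 0.005 and |log2FC| > 1, top 30 genes per direction in
#' the final re-screen at p < 0.05, 5 K-means patterns, ssGSEA exponent
#' 0.25 and a minimum group proportion of 0.1 for the survival cutoff.
#'
#' @param top_k_signatures stage-1 per-direction signature cap (default 15).
#' @param top_k_de DE per-direction gene cap (default 35).
#' @param top_k_final final re-screen per-direction cap (default 30).
#' @param p_signature stage-1 p threshold (default 0.05).
#' @param p_gene gene-screen p threshold (default 0.05).
#' @param p_de DE p threshold (default 0.005).
#' @param lfc_de DE absolute log2 fold-change threshold (default 1).
#' @param k_patterns number of K-means patterns (default 5).
#' @param alpha ssGSEA exponent (default 0.25).
#' @param minprop minimum group fraction for the survival cutoff
#'   (default 0.1).
#' @param seed RNG seed for K-means restarts (default 42).
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(top_k_signatures = 15, top_k_de = 35,
                           top_k_final = 30, p_signature = 0.05,
                           p_gene = 0.05, p_de = 0.005, lfc_de = 1.0,
                           k_patterns = 5, alpha = 0.25, minprop = 0.1,
                           seed = 42L) {
    cfg <- list(top_k_signatures = top_k_signatures, top_k_de = top_k_de,
                top_k_final = top_k_final, p_signature = p_signature,
                p_gene = p_gene, p_de = p_de, lfc_de = lfc_de,
                k_patterns = k_patterns, alpha = alpha, minprop = minprop,
                seed = as.integer(seed))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Derive immune and keratin patterns from a cohort
#'
#' Runs the full signature-derivation pipeline on raw counts:
#' \enumerate{
#'   \item ssGSEA scores of the signature library; rank-sum screen keeps
#'     the top signatures per direction (up in responders / up in
#'     non-responders);
#'   \item the member genes of the selected signatures are pooled and
#'     re-screened gene-by-gene (all genes with p < \code{p_gene});
#'   \item differential expression (median-of-ratios normalization,
#'     rank-sum p, pseudocount log2FC) keeps the top genes per direction;
#'   \item the union of (2) and (3) is filtered for pseudogenes (when a
#'     biotype table is given) and re-screened keeping the top
#'     \code{top_k_final} per direction;
#'   \item the final genes are standardized and clustered with K-means
#'     into \code{k_patterns} patterns, and the most responder-up cluster
#'     is labeled immune, the most non-responder-up cluster keratin.
#' }
#'
#' @param counts an [IKCExpression-class] of raw counts.
#' @param clinical clinical data.frame (sample_id, responder).
#' @param collection signature library [GeneSetCollection-class].
#' @param config a [pipelineConfig()].
#' @param biotypeTable optional symbol-to-biotype data.frame for the
#'   pseudogene filter (skipped with a note when NULL).
#' @return list with \code{patterns} (IMMUNE/KERATIN
#'   [GeneSetCollection-class]), \code{assignment}
#'   ([PatternAssignment-class]), \code{report} (stage counts),
#'   and the per-stage tables (\code{signature_screen}, \code{gene_screen},
#'   \code{de_table}, \code{final_screen}).
#' @export
deriveSignatures <- function(counts, clinical, collection,
                             config = pipelineConfig(),
                             biotypeTable = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    if (valueKind(counts) != "counts")
        stop2("the derivation pipeline starts from raw counts")

    sm <- ssgseaScores(counts, collection, alpha = config$alpha)
    selSig <- screenSignatures(sm, clinical,
                               topK = config$top_k_signatures,
                               pMax = config$p_signature)
    if (!nrow(selSig)) stop2("stage 1: no response-associated signatures")

    pooled <- poolSignatureGenes(selSig, collection)
    norm <- normalizeCounts(counts)
    sigGenes <- screenGeneCandidates(norm, clinical, pooled, topK = NULL,
                                     pMax = config$p_gene)

    de <- differentialExpression(counts, clinical, topK = config$top_k_de,
                                 pMax = config$p_de, lfcMin = config$lfc_de)

    unionGenes <- sort(union(sigGenes$feature, de$feature))
    if (is.null(biotypeTable)) {
        message("no biotype table supplied; pseudogene filter skipped")
        filtered <- unionGenes
    } else {
        filtered <- filterPseudogenes(unionGenes, biotypeTable)
    }

    finalSel <- screenGeneCandidates(norm, clinical, filtered,
                                     topK = config$top_k_final,
                                     pMax = config$p_gene)
    z <- standardizeGenes(norm, finalSel$feature)
    km <- kmeansPatterns(z, k = config$k_patterns, nInit = 25,
                         seed = config$seed)
    labeled <- labelPatterns(km, z, clinical)
    patterns <- patternGeneSets(labeled)

    clSizes <- as.integer(table(factor(labeled@clusters,
                                       levels = seq_len(config$k_patterns))))
    report <- list(
        n_signatures_screened = length(collection),
        n_signatures_selected = nrow(selSig),
        n_signatures_up_in_R = sum(selSig$direction == "up_in_R"),
        n_signatures_up_in_NR = sum(selSig$direction == "up_in_NR"),
        n_pooled_genes = length(pooled),
        n_signature_genes_selected = nrow(sigGenes),
        n_de_genes = nrow(de),
        n_de_up_in_R = sum(de$direction == "up_in_R"),
        n_de_up_in_NR = sum(de$direction == "up_in_NR"),
        n_union_genes = length(unionGenes),
        n_after_pseudogene_filter = length(filtered),
        n_final_genes = nrow(finalSel),
        k_patterns = config$k_patterns,
        cluster_sizes = clSizes,
        immune_cluster = labeled@labels[["immune"]],
        keratin_cluster = labeled@labels[["keratin"]],
        n_immune_pattern = length(geneIds(patterns[["IMMUNE"]])),
        n_keratin_pattern = length(geneIds(patterns[["KERATIN"]])))

    list(patterns = patterns, assignment = labeled, report = report,
         signature_screen = selSig, gene_screen = sigGenes, de_table = de,
         final_screen = finalSel)
}

#' Evaluate an IKC profile against clinical outcomes
#'
#' Joins the profile with the clinical table on sample_id and computes: AUC
#' of the composite score for responder status; the best survival cutoff
#' (maximally selected log-rank); Kaplan-Meier curves, log-rank test and
#' univariate Cox hazard ratio for the high vs low groups; the Cox hazard
#' ratio per unit of the continuous score; and, when the columns are
#' present, comparator AUCs for PD-L1 (continuous TPS, 3-level, binary)
#' and TMB (continuous and the 10 mut/Mb grouping), plus the
#' IKCscore-vs-TMB and purity-vs-KRTscore Spearman correlations.
#'
#' @param profile an [IKCProfile-class].
#' @param clinical clinical data.frame.
#' @param config a [pipelineConfig()] (for \code{minprop}).
#' @return nested list report.
#' @export
evaluateProfile <- function(profile, clinical, config = pipelineConfig()) {
    p <- profileTable(profile)
    j <- merge(p, clinical, by = "sample_id", sort = FALSE)
    if (!nrow(j)) stop2("no overlapping samples between profile and clinical")
    report <- list(n_samples = nrow(j))

    hasResp <- !is.na(j$responder)
    if (any(hasResp) && length(unique(j$responder[hasResp])) == 2L) {
        lab <- j$responder[hasResp] == "R"
        roc <- rocAuc(j$ikc_score[hasResp], lab)
        report$auc_ikc <- roc$auc
        for (comp in c("immune_score", "checkpoint_score", "krt_score"))
            report[[paste0("auc_", sub("_score", "", comp))]] <-
                rocAuc(j[[comp]][hasResp], lab)$auc
        if (!is.null(j$pdl1_tps) && !all(is.na(j$pdl1_tps))) {
            ok <- hasResp & !is.na(j$pdl1_tps)
            lab2 <- j$responder[ok] == "R"
            report$auc_pdl1_continuous <- rocAuc(j$pdl1_tps[ok], lab2)$auc
            report$auc_pdl1_level <-
                rocAuc(pdl1Level(j$pdl1_tps[ok]), lab2)$auc
            report$auc_pdl1_binary <-
                rocAuc(as.integer(pdl1Binary(j$pdl1_tps[ok]) == "pos"),
                       lab2)$auc
        }
        if (!is.null(j$tmb) && !all(is.na(j$tmb))) {
            ok <- hasResp & !is.na(j$tmb)
            lab2 <- j$responder[ok] == "R"
            report$auc_tmb_continuous <- rocAuc(j$tmb[ok], lab2)$auc
            report$auc_tmb_group <-
                rocAuc(as.integer(tmbGroup(j$tmb[ok]) == "high"), lab2)$auc
        }
    }

    if (!is.null(j$tmb) && !all(is.na(j$tmb))) {
        ct <- spearmanCor(j$ikc_score, j$tmb)
        report$cor_ikc_tmb <- list(rho = ct$rho, p = ct$p)
    }
    if (!is.null(j$tumor_purity) && !all(is.na(j$tumor_purity))) {
        ct <- spearmanCor(j$krt_score, j$tumor_purity)
        report$cor_purity_krt <- list(rho = ct$rho, p = ct$p)
    }

    if (!is.null(j$pfs_time) && any(!is.na(j$pfs_time))) {
        ok <- !is.na(j$pfs_time) & !is.na(j$pfs_event)
        sc <- j$ikc_score[ok]; tt <- j$pfs_time[ok]; ee <- j$pfs_event[ok]
        cut <- optimalCutoff(sc, tt, ee, minprop = config$minprop)
        report$cutoff <- cut$cutoff
        report$cutoff_note <-
            "log-rank p at the selected cutoff is exploratory (uncorrected)"
        grp <- ifelse(sc > cut$cutoff, "high", "low")
        lr <- logrankTest(tt, ee, grp)
        report$logrank_chi2 <- lr$chi2
        report$logrank_p <- lr$p
        cx <- coxUnivariate(tt, ee, as.integer(grp == "high"))
        report$hr_high_vs_low <- list(hr = cx$hr, ci_low = cx$ci_low,
                                      ci_high = cx$ci_high, p = cx$p)
        cxc <- coxUnivariate(tt, ee, sc)
        report$hr_per_unit_score <- list(hr = cxc$hr, ci_low = cxc$ci_low,
                                         ci_high = cxc$ci_high, p = cxc$p)
        report$km <- lapply(split(seq_along(tt), grp), function(i)
            kmEstimate(tt[i], ee[i]))
    }
    report
}

# ---- file-level runners (the engine behind the command-line interface) ----

#' Simulate a cohort and write it to disk
#'
#' Writes \code{expression.tsv}, \code{clinical.tsv}, \code{signatures.gmt}
#' and \code{truth.json} into \code{outDir}.
#'
#' @param outDir output directory (created if needed).
#' @param config a [simulationConfig()].
#' @return invisible named vector of the four file paths.
#' @export
runSimulate <- function(outDir, config = simulationConfig()) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateCohort(config)
    lib <- simulateSignatureLibrary(config, sim$truth)
    paths <- c(expression = file.path(outDir, "expression.tsv"),
               clinical = file.path(outDir, "clinical.tsv"),
               signatures = file.path(outDir, "signatures.gmt"),
               truth = file.path(outDir, "truth.json"))
    writeExpression(sim$expr, paths[["expression"]])
    writeClinical(sim$clinical, paths[["clinical"]])
    writeGmt(lib, paths[["signatures"]])
    jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA)
    invisible(paths)
}

#' Run the derivation pipeline on files
#'
#' Reads counts, clinical table and signature GMT; writes
#' \code{patterns.gmt} (IMMUNE/KERATIN), \code{patterns.tsv} (gene,
#' cluster, association, pattern) and \code{derive_report.json} with the
#' stage counts.
#'
#' @param exprPath counts TSV. @param clinicalPath clinical TSV.
#' @param gmtPath signature library GMT. @param outDir output directory.
#' @param config a [pipelineConfig()].
#' @param biotypePath optional symbol/biotype TSV for the pseudogene filter.
#' @param transpose read the expression file as samples-in-rows.
#' @return invisible derivation result (as [deriveSignatures()]).
#' @export
runDerive <- function(exprPath, clinicalPath, gmtPath, outDir,
                      config = pipelineConfig(), biotypePath = NULL,
                      transpose = FALSE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    counts <- readExpression(exprPath, "counts", transpose = transpose)
    clinical <- readClinical(clinicalPath)
    collection <- readGmt(gmtPath)
    biotype <- if (!is.null(biotypePath))
        utils::read.delim(biotypePath, stringsAsFactors = FALSE) else NULL
    res <- deriveSignatures(counts, clinical, collection, config, biotype)
    writeGmt(res$patterns, file.path(outDir, "patterns.gmt"))
    writePatterns(res$assignment, file.path(outDir, "patterns.tsv"))
    jsonlite::write_json(res$report,
                         file.path(outDir, "derive_report.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(res)
}

#' Score samples with derived patterns
#'
#' The GMT must contain sets named \code{IMMUNE} and \code{KERATIN}; the
#' checkpoint set is built internally. Writes \code{profile.tsv}.
#'
#' @param exprPath expression TSV (counts or normalized; scoring is
#'   rank-based). @param gmtPath GMT with IMMUNE and KERATIN sets.
#' @param outDir output directory. @param config a [pipelineConfig()].
#' @param valueKind declared kind of the expression values.
#' @param transpose read the expression file as samples-in-rows.
#' @return invisible [IKCProfile-class].
#' @export
runScore <- function(exprPath, gmtPath, outDir,
                     config = pipelineConfig(),
                     valueKind = "counts", transpose = FALSE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    expr <- readExpression(exprPath, valueKind, transpose = transpose)
    coll <- readGmt(gmtPath)
    missing <- setdiff(c("IMMUNE", "KERATIN"), names(coll))
    if (length(missing))
        stop2("GMT must contain set(s): ", paste(missing, collapse = ", "))
    prof <- computeComponents(expr, coll[["IMMUNE"]], coll[["KERATIN"]],
                              alpha = config$alpha)
    writeProfile(prof, file.path(outDir, "profile.tsv"))
    invisible(prof)
}

#' Evaluate a score profile against a clinical table
#'
#' Writes \code{evaluate_report.json} and, when survival data are present,
#' \code{km_curves.tsv}.
#'
#' @param profilePath profile TSV from [runScore()].
#' @param clinicalPath clinical TSV. @param outDir output directory.
#' @param config a [pipelineConfig()].
#' @return invisible report list.
#' @export
runEvaluate <- function(profilePath, clinicalPath, outDir,
                        config = pipelineConfig()) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    pt <- utils::read.delim(profilePath, stringsAsFactors = FALSE)
    pt$group <- if ("group" %in% names(pt))
        as.character(pt$group) else NA_character_
    pt$group[pt$group %in% c("NA", "")] <- NA_character_
    grouped <- !any(is.na(pt$group))
    prof <- new("IKCProfile", profile = pt[, c("sample_id", "immune_score",
                    "krt_score", "checkpoint_score", "ikc_score", "group")],
                cutoff = if (grouped) stats::median(pt$ikc_score)
                         else numeric(0))
    clinical <- readClinical(clinicalPath)
    report <- evaluateProfile(prof, clinical, config)
    km <- report$km
    report$km <- NULL
    jsonlite::write_json(report, file.path(outDir, "evaluate_report.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(km)) {
        rows <- do.call(rbind, lapply(names(km), function(g)
            data.frame(group = g, time = km[[g]]$time, surv = km[[g]]$surv,
                       n_risk = km[[g]]$n_risk)))
        utils::write.table(rows, file.path(outDir, "km_curves.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(report)
}
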