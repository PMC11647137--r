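#' Simulation configuration
#'
#' Defaults describe an NSCLC-like immunotherapy cohort: 120 pre-treatment
#' tumors with negative-binomial RNA-seq counts for 2000 genes, a planted
#' 60-gene immune program up-regulated in responders, a planted 60-gene
#' keratin program up-regulated in non-responders, the seven canonical
#' checkpoint genes co-regulated with the immune program, a signature
#' library of 100 sets of which 40 overlap the planted programs, a
#' responder fraction of 0.4, and censored exponential progression-free
#' survival whose log-hazard decreases with the true (immune + checkpoint -
#' keratin) activity, so high-scoring patients progress later.
#'
#' @param n_samples number of patients (default 120).
#' @param n_genes total genes (default 2000).
#' @param n_immune_genes planted immune-program genes (default 60).
#' @param n_keratin_genes planted keratin-program genes (default 60).
#' @param checkpoint_genes include the 7 canonical checkpoint symbols,
#'   co-regulated with the immune program (default TRUE).
#' @param n_signatures size of the simulated signature library (default 100).
#' @param signatures_overlapping_truth how many library sets overlap the
#'   planted programs (default 40, split evenly immune/keratin).
#' @param effect_size log2-fold shift of program genes between responders
#'   and non-responders (default 1.5).
#' @param nb_dispersion negative-binomial dispersion: variance =
#'   mean + dispersion * mean^2 (default 0.2).
#' @param base_mean_log_range range of baseline log2 mean expression
#'   (default c(2, 10)).
#' @param responder_fraction fraction of CR/PR patients (default 0.4).
#' @param survival_beta log-hazard per unit of true score (default -1;
#'   negative so that a high score means longer survival).
#' @param baseline_hazard events per month at true score 0 (default 0.05).
#' @param censoring_rate fraction of patients censored (default 0.3).
#' @param seed RNG seed (default 42).
#' @return validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(n_samples = 120, n_genes = 2000,
                             n_immune_genes = 60, n_keratin_genes = 60,
                             checkpoint_genes = TRUE, n_signatures = 100,
                             signatures_overlapping_truth = 40,
                             effect_size = 1.5, nb_dispersion = 0.2,
                             base_mean_log_range = c(2, 10),
                             responder_fraction = 0.4,
                             survival_beta = -1.0, baseline_hazard = 0.05,
                             censoring_rate = 0.3, seed = 42L) {
    cfg <- list(n_samples = n_samples, n_genes = n_genes,
                n_immune_genes = n_immune_genes,
                n_keratin_genes = n_keratin_genes,
                checkpoint_genes = isTRUE(checkpoint_genes),
                n_signatures = n_signatures,
                signatures_overlapping_truth = signatures_overlapping_truth,
                effect_size = effect_size, nb_dispersion = nb_dispersion,
                base_mean_log_range = base_mean_log_range,
                responder_fraction = responder_fraction,
                survival_beta = survival_beta,
                baseline_hazard = baseline_hazard,
                censoring_rate = censoring_rate, seed = as.integer(seed))
    nProgram <- n_immune_genes + n_keratin_genes +
        if (cfg$checkpoint_genes) 7L else 0L
    if (nProgram >= n_genes)
        stop2("program genes (", nProgram, ") must be fewer than n_genes")
    if (responder_fraction <= 0 || responder_fraction >= 1)
        stop2("responder_fraction must be in (0, 1)")
    if (censoring_rate < 0 || censoring_rate >= 1)
        stop2("censoring_rate must be in [0, 1)")
    if (nb_dispersion <= 0) stop2("nb_dispersion must be > 0")
    if (n_samples < 8) stop2("need at least 8 samples")
    class(cfg) <- "SimulationConfig"
    cfg
}

.CHECKPOINT_SYMBOLS <- c("CD274", "PDCD1LG2", "CTLA4", "PDCD1", "LAG3",
                         "HAVCR2", "TIGIT")

#' Simulate an immunotherapy cohort
#'
#' Counts are negative-binomial with per-gene baseline means; planted
#' immune-program genes are shifted up by \code{effect_size} (log2) in
#' responders, keratin-program genes up in non-responders, and checkpoint
#' genes follow the immune program. Progression-free survival is
#' exponential with hazard
#' \code{baseline_hazard * exp(survival_beta * true_score)}, censored
#' independently at rate \code{censoring_rate}. PD-L1 TPS is a noisy
#' monotone transform of checkpoint activity; TMB is simulated independent
#' of the score; tumor purity co-varies with keratin activity. Fully
#' reproducible from the config seed.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{expr} (counts [IKCExpression-class]),
#'   \code{clinical} (data.frame) and \code{truth} (planted gene lists,
#'   per-sample activities, true score, uncensored event times).
#' @export
simulateCohort <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    withLocalSeed(config$seed, {
        n <- config$n_samples
        nI <- config$n_immune_genes
        nK <- config$n_keratin_genes
        nC <- if (config$checkpoint_genes) 7L else 0L
        nNull <- config$n_genes - nI - nK - nC
        geneIds <- c(sprintf("IMMG%03d", seq_len(nI)),
                     sprintf("KERG%03d", seq_len(nK)),
                     if (nC) .CHECKPOINT_SYMBOLS,
                     sprintf("NULG%04d", seq_len(nNull)))
        sampleIds <- sprintf("S%03d", seq_len(n))

        nR <- max(2L, round(config$responder_fraction * n))
        responder <- rep("NR", n)
        responder[sample.int(n, nR)] <- "R"
        isR <- responder == "R"
        response <- ifelse(isR,
            ifelse(stats::runif(n) < 0.1, "CR", "PR"),
            ifelse(stats::runif(n) < 0.8, "SD", "PD"))

        # latent program activities in log2 units; the responder vs
        # non-responder separation IS effect_size, so effect_size = 0 is a
        # true null for expression, score and survival alike
        immuneAct <- stats::rnorm(n, mean = ifelse(isR, config$effect_size,
                                                   0), sd = 0.3)
        keratinAct <- stats::rnorm(n, mean = ifelse(isR, 0,
                                                    config$effect_size),
                                   sd = 0.3)
        ckptAct <- immuneAct + stats::rnorm(n, 0, 0.15)
        trueScore <- immuneAct + ckptAct - keratinAct

        base <- stats::runif(config$n_genes, config$base_mean_log_range[1],
                             config$base_mean_log_range[2])
        shift <- matrix(0, config$n_genes, n)
        shift[seq_len(nI), ] <- matrix(immuneAct, nI, n, byrow = TRUE)
        if (nK) shift[nI + seq_len(nK), ] <-
            matrix(keratinAct, nK, n, byrow = TRUE)
        if (nC) shift[nI + nK + seq_len(nC), ] <-
            matrix(ckptAct, nC, n, byrow = TRUE)
        mu <- 2^(base + shift)
        counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                        size = 1 / config$nb_dispersion),
                         config$n_genes, n,
                         dimnames = list(geneIds, sampleIds))

        hazard <- config$baseline_hazard *
            exp(config$survival_beta * trueScore)
        eventTime <- stats::rexp(n, rate = hazard)
        censored <- stats::rbinom(n, 1L, config$censoring_rate) == 1L
        pfsTime <- ifelse(censored, stats::runif(n) * eventTime, eventTime)
        pfsTime <- pmax(pfsTime, 1e-3)
        pfsEvent <- as.numeric(!censored)

        zc <- (ckptAct - mean(ckptAct)) / stats::sd(ckptAct)
        pdl1 <- round(100 * stats::plogis(-0.5 + 1.2 * zc +
                                          stats::rnorm(n, 0, 0.8)), 1)
        tmb <- round(stats::rlnorm(n, meanlog = log(5), sdlog = 0.6), 2)
        zk <- (keratinAct - mean(keratinAct)) / stats::sd(keratinAct)
        purity <- round(stats::plogis(0.4 + 0.7 * zk +
                                      stats::rnorm(n, 0, 0.5)), 3)

        clinical <- data.frame(sample_id = sampleIds, response = response,
                               responder = responder, pfs_time = pfsTime,
                               pfs_event = pfsEvent, pdl1_tps = pdl1,
                               tmb = tmb, tumor_purity = purity,
                               stringsAsFactors = FALSE)
        truth <- list(immune_genes = geneIds[seq_len(nI)],
                      keratin_genes = geneIds[nI + seq_len(nK)],
                      checkpoint_genes = if (nC) .CHECKPOINT_SYMBOLS
                                         else character(0),
                      immune_activity = immuneAct,
                      keratin_activity = keratinAct,
                      checkpoint_activity = ckptAct,
                      true_score = trueScore, responder = responder,
                      event_time_uncensored = eventTime,
                      sample_ids = sampleIds)
        list(expr = IKCExpression(counts, "counts"), clinical = clinical,
             truth = truth)
    })
}

#' Simulate a signature library
#'
#' Builds \code{n_signatures} gene sets of 10-50 genes. A configured number
#' overlap the planted programs (drawing at least half of their members
#' from the immune or keratin program, split evenly between the two); the
#' rest draw only from null genes. Deterministic from the config seed.
#'
#' @param config a [simulationConfig()].
#' @param truth the \code{truth} element of [simulateCohort()].
#' @return A [GeneSetCollection-class]; the per-set planted type
#'   ("immune", "keratin" or "none") is in \code{attr(, "truth_overlap")}.
#' @export
simulateSignatureLibrary <- function(config, truth) {
    stopifnot(inherits(config, "SimulationConfig"))
    nSig <- config$n_signatures
    nOv <- config$signatures_overlapping_truth
    if (nOv > nSig)
        stop2("signatures_overlapping_truth exceeds n_signatures")
    nullGenes <- setdiff(
        c(sprintf("NULG%04d", seq_len(config$n_genes -
            config$n_immune_genes - config$n_keratin_genes -
            if (config$checkpoint_genes) 7L else 0L))),
        character(0))
    nImmSig <- ceiling(nOv / 2)
    type <- c(rep("immune", nImmSig), rep("keratin", nOv - nImmSig),
              rep("none", nSig - nOv))
    rsample <- function(v, k = 1L) v[sample.int(length(v), k)]
    withLocalSeed(config$seed + 1L, {
        sets <- vector("list", nSig)
        for (i in seq_len(nSig)) {
            prog <- switch(type[i], immune = truth$immune_genes,
                           keratin = truth$keratin_genes, none = NULL)
            if (is.null(prog)) {
                genes <- rsample(nullGenes, rsample(10:50))
            } else {
                # a program-typed set draws at least half its members from
                # the program, so its size is capped by the program size
                maxSize <- min(50L, 2L * length(prog))
                if (maxSize < 10L)
                    stop2("program too small for requested overlap")
                size <- rsample(10:maxSize)
                nProg <- rsample(ceiling(size / 2):min(size, length(prog)))
                genes <- c(rsample(prog, nProg),
                           if (size > nProg) rsample(nullGenes,
                                                     size - nProg))
            }
            sets[[i]] <- GeneSet(sprintf("SIG%03d", i), genes,
                                 paste0("simulated (", type[i], ")"))
        }
        coll <- GeneSetCollection(sets)
        attr(coll, "truth_overlap") <- type
        coll
    })
}
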