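# Independent oracle implementations, deliberately naive and separate from
# the package's code paths.

# Literal running-sum ssGSEA enrichment score: walk genes in decreasing
# rank order (ties by ascending symbol), accumulating the weighted in-set
# rank ECDF minus the uniform out-of-set ECDF.
bruteEnrichmentScore <- function(r, setGenes, alpha = 0.25) {
    ord <- order(-r, names(r))
    inS <- names(r)[ord] %in% setGenes
    w <- (r[ord])^alpha
    N <- length(r)
    nS <- sum(inS)
    stopifnot(nS >= 1, nS < N)
    es <- 0
    pin <- 0
    pout <- 0
    sumW <- sum(w[inS])
    for (i in seq_len(N)) {
        if (inS[i]) pin <- pin + w[i] / sumW
        else pout <- pout + 1 / (N - nS)
        es <- es + (pin - pout)
    }
    as.numeric(es)
}

# Brute-force AUC: average over all (positive, negative) pairs.
bruteAuc <- function(scores, labels) {
    sp <- scores[labels == 1]
    sn <- scores[labels == 0]
    mean(outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Hypergeometric log-rank chi-squared, computed from first principles.
logrankChi2Oracle <- function(times, events, groups) {
    g <- as.character(groups)
    lv <- sort(unique(g))
    stopifnot(length(lv) == 2)
    O <- E <- V <- 0
    for (t in sort(unique(times[events == 1]))) {
        atRisk <- times >= t
        n <- sum(atRisk)
        n1 <- sum(atRisk & g == lv[1])
        d <- sum(times == t & events == 1)
        d1 <- sum(times == t & events == 1 & g == lv[1])
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
}

# Efron partial log-likelihood for a single covariate.
efronLogLik <- function(beta, times, events, x) {
    eta <- beta * x
    ll <- 0
    for (t in sort(unique(times[events == 1]))) {
        dIdx <- which(times == t & events == 1)
        rIdx <- which(times >= t)
        d <- length(dIdx)
        sumR <- sum(exp(eta[rIdx]))
        sumD <- sum(exp(eta[dIdx]))
        ll <- ll + sum(eta[dIdx])
        for (l in seq_len(d) - 1)
            ll <- ll - log(sumR - (l / d) * sumD)
    }
    ll
}

# Exhaustive-scan survival cutpoint oracle using the hand-rolled log-rank.
optimalCutoffOracle <- function(scores, times, events, minprop = 0.1) {
    u <- sort(unique(scores))
    cand <- (u[-1] + u[-length(u)]) / 2
    n <- length(scores)
    minN <- ceiling(minprop * n)
    best <- NULL
    bestChi <- -Inf
    for (ct in cand) {
        nl <- sum(scores <= ct)
        if (nl < minN || n - nl < minN) next
        chi <- logrankChi2Oracle(times, events,
                                 ifelse(scores > ct, "high", "low"))
        if (chi > bestChi + 1e-12) {
            bestChi <- chi
            best <- ct
        }
    }
    list(cutoff = best, chi2 = bestChi)
}
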