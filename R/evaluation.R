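#' @importFrom survival Surv survfit survdiff coxph
NULL

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores; the AUC is computed by the rank
#' (Mann-Whitney) formulation, \eqn{AUC = U / (n_1 n_0)}, which handles
#' score ties exactly and is invariant to monotone score transforms.
#'
#' @param scores numeric vector.
#' @param labels binary labels (1/TRUE = positive class) aligned with
#'   \code{scores}; both classes must be present.
#' @return list with \code{thresholds}, \code{tpr}, \code{fpr} (one point
#'   per unique score, plus the two trivial endpoints) and \code{auc}.
#' @export
rocAuc <- function(scores, labels) {
    lab <- as.integer(as.logical(labels))
    keep <- !is.na(scores) & !is.na(lab)
    scores <- scores[keep]; lab <- lab[keep]
    n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
    if (n1 == 0L || n0 == 0L)
        stop2("both classes must be present to compute a ROC curve")
    r <- rank(scores, ties.method = "average")
    U <- sum(r[lab == 1L]) - n1 * (n1 + 1) / 2
    auc <- U / (n1 * n0)
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
    tpr <- vapply(thr, function(t) mean(scores[lab == 1L] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(scores[lab == 0L] >= t), numeric(1))
    list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive survival times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return list with \code{time}, \code{surv} (survival probability after
#'   each event time) and \code{n_risk}.
#' @export
kmEstimate <- function(times, events) {
    if (any(times <= 0)) stop2("survival times must be positive")
    if (!all(events %in% c(0, 1))) stop2("events must be 0 or 1")
    fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                             conf.type = "none")
    list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
         n_event = fit$n.event)
}

#' Two-group log-rank test
#'
#' Hypergeometric expected counts and variance at each event time; the
#' statistic is chi-squared with 1 degree of freedom.
#'
#' @param times positive survival times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups two-level grouping vector.
#' @return list with \code{chi2} and \code{p}.
#' @export
logrankTest <- function(times, events, groups) {
    g <- as.factor(groups)
    if (nlevels(droplevels(g)) != 2L)
        stop2("log-rank test needs exactly 2 non-empty groups")
    sd <- survival::survdiff(survival::Surv(times, events) ~ g)
    list(chi2 = unname(sd$chisq),
         p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; the hazard ratio is per
#' unit of the covariate, with a Wald 95\% confidence interval.
#'
#' @param times positive survival times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param covariate numeric covariate (must not be constant).
#' @return list with \code{hr}, \code{ci_low}, \code{ci_high}, \code{p}
#'   and the log-hazard coefficient \code{beta}.
#' @export
coxUnivariate <- function(times, events, covariate) {
    if (stats::sd(covariate) == 0)
        stop2("covariate is constant; Cox model is not identifiable")
    fit <- survival::coxph(survival::Surv(times, events) ~ covariate,
                           ties = "efron")
    if (!is.null(fit$info) && any(grepl("infinite", fit$info)))
        stop2("monotone partial likelihood (perfect separation)")
    beta <- unname(stats::coef(fit))
    se <- sqrt(unname(stats::vcov(fit)[1, 1]))
    if (!is.finite(beta) || !is.finite(se) || abs(beta) > 50)
        stop2("Cox fit did not converge (possible perfect separation)")
    z <- stats::qnorm(0.975)
    list(hr = exp(beta), ci_low = exp(beta - z * se),
         ci_high = exp(beta + z * se),
         p = 2 * stats::pnorm(-abs(beta / se)), beta = beta, se = se)
}

#' Best survival cutoff by maximally selected log-rank statistic
#'
#' Scans every candidate cutoff (midpoints of consecutive sorted unique
#' scores) whose split leaves at least \code{minprop} of the samples in
#' each group, and returns the cutoff maximizing the standardized log-rank
#' statistic (equivalently the chi-squared); ties go to the lower cutoff.
#' The log-rank p-value at the selected cutoff is reported uncorrected for
#' the maximal selection and must be treated as exploratory.
#'
#' @param scores numeric score per sample.
#' @param times,events survival data aligned with \code{scores}.
#' @param minprop minimum fraction of samples per group (default 0.1).
#' @return list with \code{cutoff}, \code{chi2}, \code{p} (exploratory,
#'   uncorrected) and the number of candidates scanned.
#' @export
optimalCutoff <- function(scores, times, events, minprop = 0.1) {
    keep <- !is.na(scores) & !is.na(times) & !is.na(events)
    scores <- scores[keep]; times <- times[keep]; events <- events[keep]
    n <- length(scores)
    u <- sort(unique(scores))
    if (length(u) < 2L) stop2("scores are constant; no cutoff exists")
    cand <- (u[-1L] + u[-length(u)]) / 2
    minN <- ceiling(minprop * n)
    ok <- vapply(cand, function(ct) {
        nl <- sum(scores <= ct)
        nl >= minN && (n - nl) >= minN
    }, logical(1))
    cand <- cand[ok]
    if (!length(cand))
        stop2("no candidate cutoff leaves >= ", minprop,
              " of samples in each group")
    chi2 <- vapply(cand, function(ct) {
        logrankTest(times, events, scores > ct)$chi2
    }, numeric(1))
    best <- which.max(chi2)   # which.max takes the first (= lowest) at ties
    list(cutoff = cand[best], chi2 = chi2[best],
         p = stats::pchisq(chi2[best], 1, lower.tail = FALSE),
         n_candidates = length(cand))
}

#' Spearman rank correlation
#'
#' Average ranks at ties; the p-value uses the t-approximation.
#'
#' @param x,y numeric vectors (n >= 3, neither constant).
#' @return list with \code{rho} and \code{p}.
#' @export
spearmanCor <- function(x, y) {
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L) stop2("need at least 3 paired observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop2("constant vector in correlation")
    ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    list(rho = unname(ht$estimate), p = ht$p.value)
}

#' PD-L1 tumor proportion score bins
#'
#' Three-level binning: level 0 (< 1\%), level 1 (1-49\%), level 2
#' (>= 50\%); the binary version is negative (< 1\%) vs positive (>= 1\%).
#'
#' @param tps tumor proportion score, percent in \[0, 100\].
#' @return \code{pdl1Level}: integer 0/1/2; \code{pdl1Binary}: "neg"/"pos".
#' @export
pdl1Level <- function(tps) {
    if (any(tps < 0 | tps > 100, na.rm = TRUE))
        stop2("PD-L1 TPS must be in [0, 100]")
    ifelse(tps < 1, 0L, ifelse(tps < 50, 1L, 2L))
}

#' @rdname pdl1Level
#' @export
pdl1Binary <- function(tps) {
    if (any(tps < 0 | tps > 100, na.rm = TRUE))
        stop2("PD-L1 TPS must be in [0, 100]")
    ifelse(tps < 1, "neg", "pos")
}

#' TMB high/low grouping
#'
#' High iff TMB >= cutoff (mutations/Mb); the default cutoff of 10 follows
#' the FDA label, with the boundary value 10 classed high.
#'
#' @param tmb tumor mutation burden, mutations/Mb (>= 0).
#' @param cutoff threshold (default 10).
#' @return "high"/"low".
#' @export
tmbGroup <- function(tmb, cutoff = 10) {
    if (any(tmb < 0, na.rm = TRUE)) stop2("TMB must be >= 0")
    ifelse(tmb >= cutoff, "high", "low")
}
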