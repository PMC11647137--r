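test_that("AUC equals pair counting, hand example, and pROC", {
    expect_equal(rocAuc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc, 0.75)
    expect_equal(rocAuc(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0))$auc, 1.0)
    expect_error(rocAuc(1:4, c(1, 1, 1, 1)), "both classes")

    withr::local_seed(15)
    for (rep in 1:50) {
        n <- sample(10:60, 1)
        s <- sample(1:20, n, replace = TRUE)  # plenty of ties
        l <- rbinom(n, 1, 0.5)
        if (length(unique(l)) < 2) next
        r <- rocAuc(s, l)
        expect_equal(r$auc, bruteAuc(s, l), tolerance = 1e-13)
        expect_equal(r$auc, as.numeric(suppressMessages(
            pROC::auc(pROC::roc(l, s, quiet = TRUE, direction = "<")))),
            tolerance = 1e-12)
        expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
    }
    # complement symmetry without ties
    s <- runif(30); l <- rbinom(30, 1, 0.5); l[1:2] <- c(0, 1)
    expect_equal(rocAuc(s, l)$auc + rocAuc(-s, l)$auc, 1)
})

test_that("Kaplan-Meier matches the empirical and hand product-limit curves", {
    km <- kmEstimate(1:4, rep(1, 4))
    expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
    km2 <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
    expect_equal(km2$surv[km2$time == 1], 2 / 3)
    expect_equal(km2$surv[km2$time == 3], 0)
    expect_true(all(kmEstimate(1:5, rep(0, 5))$surv == 1))
    expect_error(kmEstimate(c(-1, 2), c(1, 1)), "positive")

    # without censoring the KM curve is the empirical survival function
    withr::local_seed(16)
    t <- rexp(40)
    km3 <- kmEstimate(t, rep(1, 40))
    emp <- vapply(km3$time, function(x) mean(t > x), numeric(1))
    expect_equal(km3$surv, emp)
})

test_that("log-rank agrees with the hypergeometric oracle", {
    t <- c(1, 2, 3, 4); e <- rep(1, 4); g <- c("A", "A", "B", "B")
    lr <- logrankTest(t, e, g)
    expect_equal(lr$chi2, 49 / 17)          # O=2, E=5/6, V=17/36
    expect_equal(lr$chi2, logrankChi2Oracle(t, e, g))
    same <- logrankTest(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
    expect_equal(same$chi2, 0)
    expect_equal(same$p, 1)
    expect_error(logrankTest(t, e, rep("A", 4)), "2 non-empty")

    withr::local_seed(17)
    for (rep in 1:20) {
        n <- 30
        t <- rexp(n); e <- rbinom(n, 1, 0.7)
        g <- rep(c("A", "B"), n / 2)
        expect_equal(logrankTest(t, e, g)$chi2, logrankChi2Oracle(t, e, g),
                     tolerance = 1e-10)
    }
})

test_that("Cox fit maximizes the Efron partial likelihood", {
    t <- c(1, 1, 2, 2, 3, 4)
    e <- c(1, 1, 1, 0, 1, 1)
    x <- c(2, 0, 1, 1, 0, 1)
    fit <- coxUnivariate(t, e, x)
    betaOracle <- stats::optimize(function(b) -efronLogLik(b, t, e, x),
                                  c(-5, 5), tol = 1e-9)$minimum
    expect_equal(fit$beta, betaOracle, tolerance = 1e-4)
    # sign symmetry
    fitNeg <- coxUnivariate(t, e, -x)
    expect_equal(fitNeg$hr, 1 / fit$hr, tolerance = 1e-8)
    expect_error(coxUnivariate(t, e, rep(1, 6)), "constant")
})

test_that("Cox null simulations keep the CI on 1 about 95% of the time", {
    withr::local_seed(18)
    cover <- replicate(100, {
        t <- rexp(120); e <- rbinom(120, 1, 0.8); x <- rnorm(120)
        f <- coxUnivariate(t, e, x)
        f$ci_low <= 1 && 1 <= f$ci_high
    })
    expect_gt(mean(cover), 0.85)
})

test_that("optimal cutoff matches the exhaustive-scan oracle", {
    withr::local_seed(19)
    # two separated score clusters with divergent survival
    sc <- c(rnorm(20, 0, 0.3), rnorm(20, 5, 0.3))
    t <- c(rexp(20, 1), rexp(20, 0.1))
    e <- rep(1, 40)
    cut <- optimalCutoff(sc, t, e)
    expect_gt(cut$cutoff, 1)
    expect_lt(cut$cutoff, 4)
    expect_gte(sum(sc <= cut$cutoff), 4)    # minprop constraint
    expect_gte(sum(sc > cut$cutoff), 4)
    for (rep in 1:10) {
        s2 <- rnorm(30); t2 <- rexp(30, exp(-s2)); e2 <- rbinom(30, 1, 0.8)
        got <- optimalCutoff(s2, t2, e2, minprop = 0.15)
        want <- optimalCutoffOracle(s2, t2, e2, minprop = 0.15)
        expect_equal(got$cutoff, want$cutoff)
        expect_equal(got$chi2, want$chi2, tolerance = 1e-9)
    }
    expect_error(optimalCutoff(rep(1, 10), rexp(10), rep(1, 10)), "constant")
})

test_that("Spearman correlation matches hand rank computation", {
    expect_equal(spearmanCor(1:10, 1:10)$rho, 1)
    expect_equal(spearmanCor(1:10, 10:1)$rho, -1)
    expect_equal(spearmanCor(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
    expect_error(spearmanCor(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("PD-L1 and TMB binning follow the clinical conventions", {
    expect_equal(pdl1Level(c(0, 0.9, 1, 30, 49.9, 50, 100)),
                 c(0L, 0L, 1L, 1L, 1L, 2L, 2L))
    expect_identical(pdl1Binary(c(0, 30, 50)), c("neg", "pos", "pos"))
    expect_identical(tmbGroup(c(0, 9.9, 10, 25)),
                     c("low", "low", "high", "high"))
    expect_error(pdl1Level(120), "\\[0, 100\\]")
    expect_error(tmbGroup(-1), ">= 0")
})
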