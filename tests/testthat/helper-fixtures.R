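# Shared fixtures, built in code.

# Small cohort for fast unit tests (same structure as the default, scaled).
smallSimConfig <- function(seed = 1L) {
    simulationConfig(n_samples = 60, n_genes = 300, n_immune_genes = 20,
                     n_keratin_genes = 20, n_signatures = 30,
                     signatures_overlapping_truth = 12, seed = seed)
}

# Memoized default fixture shared by the acceptance tests.
.fixtureCache <- new.env(parent = emptyenv())

defaultFixture <- function() {
    if (is.null(.fixtureCache$fix)) {
        cfg <- simulationConfig(seed = 42)
        sim <- simulateCohort(cfg)
        lib <- simulateSignatureLibrary(cfg, sim$truth)
        der <- suppressWarnings(suppressMessages(
            deriveSignatures(sim$expr, sim$clinical, lib)))
        .fixtureCache$fix <- list(cfg = cfg, sim = sim, lib = lib, der = der)
    }
    .fixtureCache$fix
}

# Tiny expression matrix with chosen values.
toyExpression <- function(values, valueKind = "normalized") {
    IKCExpression(values, valueKind)
}

writeTempTsv <- function(lines) {
    path <- withr::local_tempfile(fileext = ".tsv",
                                  .local_envir = parent.frame())
    writeLines(lines, path)
    path
}

# A strictly increasing random transform factory (positive inputs).
randomMonotone <- function() {
    kind <- sample(c("power", "exp", "log", "affine"), 1)
    a <- runif(1, 0.5, 2)
    b <- runif(1, 0.1, 1)
    switch(kind,
           power = function(x) x^a,
           exp = function(x) exp(b * x / 500),
           log = function(x) log(x + a),
           affine = function(x) a * x + b)
}
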