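# IKCscore

Derivation and application of a composite transcriptomic biomarker of
immune-checkpoint-blockade (ICB) response from bulk tumor RNA-seq,
aimed at researchers working on immunotherapy response prediction in
NSCLC and related solid tumors.

Only a minority of advanced NSCLC patients respond to anti-PD-(L)1
therapy, and the clinical biomarkers (PD-L1 immunohistochemistry, tumor
mutation burden) discriminate poorly. The score implemented here combines
three tumor-microenvironment components, each a single-sample gene-set
enrichment (ssGSEA) score of a fixed gene set:

```
IKCscore = Immune score + Immune Checkpoint score − KRTscore
```

- **Immune score** — genes up-regulated in responders (antigen
  presentation / complement biology);
- **Immune Checkpoint score** — CD274, PDCD1LG2, CTLA4, PDCD1, LAG3,
  HAVCR2, TIGIT;
- **KRTscore** — keratin/epidermal genes up-regulated in non-responders
  and correlated with tumor purity.

For one sample with per-gene ranks R_g (average ranks at ties, N genes),
the enrichment score of a set S walks genes in decreasing rank order and
integrates the difference between the weighted in-set rank ECDF
(weights R_g^α, α = 0.25) and the uniform out-of-set ECDF; scores are
normalized cohort-wide by the global score range.

The package provides the full derivation pipeline (signature screening
with Wilcoxon rank-sum tests, gene pooling, differential expression,
pseudogene filtering, K-means pattern discovery and immune/keratin
labeling), the scoring engine, the evaluation statistics (ROC/AUC,
Kaplan-Meier, log-rank, univariate Cox, maximally selected survival
cutoff, Spearman, PD-L1/TMB comparator bins) and a negative-binomial
cohort simulator with planted immune and keratin programs for
end-to-end validation. Objects are Bioconductor-style S4
(`IKCExpression` extends `SummarizedExperiment`; `GeneSetCollection`,
`ScoreMatrix`, `IKCProfile`, `PatternAssignment` carry validity checks
and accessors).

## Worked example

```r
library(IKCscore)

cfg <- simulationConfig(seed = 42)            # NSCLC-like synthetic cohort
sim <- simulateCohort(cfg)                    # counts + clinical + truth
lib <- simulateSignatureLibrary(cfg, sim$truth)

der <- deriveSignatures(sim$expr, sim$clinical, lib)
der$patterns
#> GeneSetCollection of 2 sets
#>   IMMUNE, KERATIN
unlist(der$report[c("n_signatures_selected", "n_pooled_genes",
                    "n_de_genes", "n_union_genes", "n_final_genes")])
#> n_signatures_selected        n_pooled_genes            n_de_genes
#>                    30                   368                    70
#>         n_union_genes         n_final_genes
#>                   138                    60

prof <- computeComponents(sim$expr, der$patterns[["IMMUNE"]],
                          der$patterns[["KERATIN"]])
head(profileTable(prof), 3)
#>   sample_id immune_score krt_score checkpoint_score  ikc_score group
#> 1      S001    0.2983028 0.7534381        0.3522242 -0.1029111  <NA>
#> 2      S002    0.6356750 0.5378501        0.6144088  0.7122337  <NA>
#> 3      S003    0.6742731 0.5264806        0.6751020  0.8228945  <NA>

rep <- evaluateProfile(prof, sim$clinical)
#> AUC = 1.000                       # score vs RECIST responder status
#> cutoff = 0.051                    # maximally selected log-rank cutpoint
#> HR (high vs low) = 0.014 [0.003, 0.060]
#> log-rank p = 7.49e-21
```

The pipeline selects 15 signatures per direction, 35 differential genes
per direction, 60 final genes and 5 expression patterns; the composite
score of the high-score group is strongly protective for progression-free
survival (hazard ratio far below 1) because the simulator links the
hazard to the true planted score. The synthetic separation is by design
cleaner than any real cohort — it verifies machinery, not clinical
performance.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/ikc.R simulate --out-dir cohort --seed 42
Rscript inst/scripts/ikc.R derive --expr cohort/expression.tsv \
    --clinical cohort/clinical.tsv --signatures cohort/signatures.gmt \
    --out-dir derived
Rscript inst/scripts/ikc.R score --expr cohort/expression.tsv \
    --patterns derived/patterns.gmt --out-dir scored
Rscript inst/scripts/ikc.R evaluate --profile scored/profile.tsv \
    --clinical cohort/clinical.tsv --out-dir evaluated
```

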