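---
title: "Deriving and evaluating the IKC score: methods and design notes"
author: "IKCscore package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and evaluating the IKC score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IKCscore)
```

## The problem and the model

Only a minority of advanced NSCLC patients respond durably to immune
checkpoint blockade, and the approved biomarkers (PD-L1 immunohistochemistry,
tumor mutation burden) are weak discriminators. This package implements a
composite transcriptomic biomarker computed from bulk tumor RNA-seq:

$$\mathrm{IKCscore} = \mathrm{Immune\ score} +
  \mathrm{Immune\ Checkpoint\ score} - \mathrm{KRTscore}$$

Each component is a single-sample gene-set enrichment (ssGSEA) score of a
fixed gene set: an *immune pattern* (genes up-regulated in responders,
dominated by antigen presentation and complement biology), a *keratin
pattern* (epidermal/keratin genes up-regulated in non-responders, and
positively correlated with tumor purity), and a seven-gene immune
checkpoint set (CD274, PDCD1LG2, CTLA4, PDCD1, LAG3, HAVCR2, TIGIT; the
literature alias PDL1 is mapped to CD274 by the packaged alias table).

### The ssGSEA statistic

For one sample, expression values are converted to ranks $R_g$ (1 = lowest,
$N$ = highest, average ranks at ties). Genes are walked in decreasing rank
order, ties broken by ascending symbol for determinism, and the enrichment
score of a set $S$ is the integrated difference between the weighted in-set
rank ECDF and the uniform out-of-set ECDF:

$$ES(S) = \sum_{i=1}^{N}\left(
  \frac{\sum_{g \in S,\ \mathrm{pos}(g) \le i} R_g^{\alpha}}
       {\sum_{g \in S} R_g^{\alpha}}
  - \frac{\left|\{g \notin S,\ \mathrm{pos}(g) \le i\}\right|}{N - |S|}
\right)$$

with $\alpha = 0.25$, the canonical ssGSEA exponent. The implementation
uses the algebraically equivalent closed form
$ES = \sum_{g\in S} w_g u_g / \sum_{g\in S} w_g - \sum_{g\notin S} u_g/(N-|S|)$
with $w_g = R_g^\alpha$ and $u_g = N - \mathrm{pos}(g) + 1$, which the test
suite verifies against a literal running-sum implementation to $10^{-9}$.
Because the statistic depends on expression only through ranks, it is
invariant to any strictly increasing per-sample transform, which the suite
checks property-style.

Scores for a collection are normalized *jointly*: every raw enrichment
score is divided by the global range (max − min) over the whole
signatures-by-samples matrix. This matches the usual ssGSEA convention and
deliberately ties each sample's score to its cohort — the score of a single
sample in isolation is not defined, which is a known practical limitation
of the approach. The three IKC components are normalized in one call so
that their sum and difference live on a single scale; whether the original
analysis normalized jointly or separately is not documented, and joint
normalization is the choice that makes the composite arithmetic meaningful.

## The derivation pipeline

Starting from raw counts, a clinical table with RECIST responses
(responders = CR/PR, non-responders = SD/PD), and a signature library
(GMT), `deriveSignatures()` runs:

1. **Signature screen.** ssGSEA scores for every library signature; a
   Wilcoxon rank-sum test per signature (responders vs non-responders);
   the top 15 signatures per direction with $p < 0.05$, ordered by
   ascending $p$ (ties by absolute effect, then name).
2. **Gene pooling and re-screen.** The member genes of the selected
   signatures are pooled (deduplicated union) and re-screened
   gene-by-gene; all genes with $p < 0.05$ are kept.
3. **Differential expression.** Counts are normalized by median-of-ratios
   size factors; each gene gets a pseudocount fold change
   $\log_2((\bar x_R + 1)/(\bar x_{NR} + 1))$ and a rank-sum $p$-value
   (BH-adjusted values are reported alongside). Candidates need
   $p < 0.005$ and $|\log_2 FC| > 1$; the top 35 per direction by raw $p$
   are selected. The reference analysis used a negative-binomial Wald
   test here; this package substitutes the rank-sum test with
   median-of-ratios normalization — a documented, deliberately simpler
   stand-in that keeps the stage non-parametric and dependency-light.
   The stage is a plain function, so an external NB test can be swapped
   in by the caller.
4. **Union, pseudogene filter, final screen.** The union of stages 2 and
   3 is filtered against a user-supplied symbol-to-biotype table (any
   biotype containing "pseudogene" is removed; without a table the filter
   is skipped with a note — no network lookups, for reproducibility), and
   re-screened keeping the top 30 genes per direction.
5. **Pattern discovery.** The final genes are standardized to per-gene
   z-scores (sample sd) and clustered with K-means (Lloyd's algorithm,
   Euclidean distance, k-means++ initialization, best of 25 restarts by
   within-cluster sum of squares, empty clusters reseeded from the
   farthest point, deterministic given the seed) into $k = 5$ patterns.
   Each cluster is scored by its response association — the mean over
   member genes of (mean z in responders − mean z in non-responders) —
   and the argmax cluster is labeled the immune pattern, the argmin the
   keratin pattern. The original analysis labeled patterns by GO
   enrichment; enrichment analysis is out of scope here, and the response
   association is the property the downstream score actually exploits, so
   the labeling criterion is replaced, not imitated. An exact association
   tie is an error (rerun with another seed or k) rather than a silent
   arbitrary choice.

Raw (not BH-adjusted) $p$-values drive every "top $k$" ordering, because
the stages are defined by $p$-value order; adjusted values are always
reported alongside. Whether the 16 signature-derived genes and the 70
differential genes overlapped in the original cohort is unknowable from
the text; the union deduplicates regardless.

## Evaluation statistics

`evaluateProfile()` computes: AUC for responder status (rank/Mann-Whitney
formulation, exact under ties); the best survival cutoff by maximally
selected log-rank statistic over all midpoints of consecutive sorted
unique scores, constrained so both groups keep at least `minprop = 0.1`
of samples, ties resolved to the lower cutoff; Kaplan-Meier curves,
log-rank test and univariate Cox hazard ratios (Efron tie handling, Wald
95% CI) for the resulting high/low groups (a boundary sample goes to
"low"); and Spearman correlations (IKC vs TMB, keratin score vs tumor
purity). The log-rank $p$ at the selected cutoff is reported *uncorrected*
for the maximal selection and flagged as exploratory — the maxstat-style
correction is deliberately out of scope. Comparator AUCs use the clinical
PD-L1 TPS bins (level 0 < 1%, level 1 = 1–49%, level 2 ≥ 50%; binary
negative < 1%) and the TMB cutoff of 10 mut/Mb, with the boundary value
10 classed high per the FDA label convention.

## The synthetic cohort generator

No patient data ship with the package; `simulateCohort()` generates
cohorts with the statistical structure the pipeline assumes. Defaults
describe an NSCLC-like trial cohort: $n = 120$ tumors, 2000 genes with
baseline $\log_2$ means uniform on $[2, 10]$, negative-binomial counts
with dispersion 0.2 (variance $= \mu + 0.2\mu^2$), responder fraction
0.4, a 60-gene immune program shifted up by `effect_size` = 1.5 $\log_2$
units in responders, a 60-gene keratin program shifted up in
non-responders, and the 7 checkpoint genes co-regulated with the immune
program. Latent program activities are Gaussian around group means
separated by exactly `effect_size` (sd 0.3, checkpoint activity tracks
immune activity with sd 0.15), so `effect_size = 0` is a true null for
expression, score and survival alike. Progression-free survival is
exponential with hazard $0.05 \cdot e^{-1 \cdot \text{true score}}$ per
month — the negative coefficient makes high scores protective — censored
by an independent Bernoulli(0.3) mechanism (uniformly within the event
time), so the censoring fraction is exactly calibrated. PD-L1 TPS is a
noisy logistic transform of checkpoint activity; TMB is drawn
independently of the score, making the observed non-correlation a
designed, testable property; tumor purity co-varies with keratin
activity. The signature library contains 100 sets of 10–50 genes, 40 of
which draw at least half their members from a planted program.

The generator reproduces what the pipeline needs — planted differential
programs, outcome-linked survival, calibrated nulls — and deliberately
omits library-size artifacts, GC bias, batch effects and the correlation
structure of real co-expression networks. Passing tests therefore
demonstrate the pipeline's correctness and internal consistency, not its
clinical performance; with the default 5-sigma latent separation the
synthetic cohorts are *easier* than real ones (AUCs near 1), which is the
intended regime for verifying machinery rather than estimating power.

## Numerical choices and degenerate inputs

- Rank-sum $p$-values: exact enumeration when both groups have ≤ 8
  observations and no ties; otherwise normal approximation with tie and
  continuity corrections. Fully tied inputs carry no evidence and return
  $p = 1$.
- Duplicate gene rows are collapsed by their per-sample mean at load
  time; all symbols are upper-cased, and matching is exact string
  equality after alias mapping.
- Samples with missing response are retained for scoring but excluded
  from every responder-vs-non-responder test.
- Genes in a set but absent from a matrix are dropped with a warning
  (fixed sets are applied across platforms); a set with no overlap, or
  covering every gene, is an error.
- Constant genes are dropped (with a warning) before standardization;
  constant covariates and single-class label vectors are errors.
- Cox fits stop at $|\Delta\beta| <$ machine tolerance via the survival
  package's Newton-Raphson; monotone likelihoods (perfect separation)
  are reported as errors rather than huge finite hazard ratios.

## Known limitations

- The pattern-labeling step uses response association instead of GO
  enrichment, so the "immune"/"keratin" names describe the direction of
  association, not verified biology.
- With exactly two planted programs and $k = 5$ forced patterns, a
  WSS-minimizing K-means must split at least one program across clusters
  (five centers, two blobs); on the default cohorts each labeled pattern
  therefore captures roughly half of its program's selected genes, with
  the remainder in adjacent same-sign clusters. The package reports
  per-cluster association scores so such splits are visible; when the
  number of true programs is known, setting `k_patterns` to it recovers
  the programs exactly (this is tested).
- The DE stage is a rank-based substitution for a negative-binomial Wald
  test and will rank genes differently in small or highly dispersed
  cohorts.
- The best-cutoff $p$-value is not corrected for maximal selection.

## Reproducibility

All randomness flows from explicit integer seeds: the simulation config
seed drives cohort and library generation (library offset by +1), and the
pipeline config seed drives K-means restarts. RNG state is saved and
restored around every seeded computation, so package calls never perturb
the caller's stream. The test suite and the acceptance script run the
full pipeline at the default sizes above (about half a minute on one
CPU); the statistical engines are verified against independent oracles
(literal running-sum ssGSEA, pair-counting AUC, hypergeometric log-rank,
grid-maximized Efron partial likelihood, DESeq2 size factors) on small
random instances.
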