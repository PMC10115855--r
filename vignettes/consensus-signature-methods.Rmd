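---
title: "Deriving consensus drug-response signatures with consig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving consensus drug-response signatures with consig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consig)
```

## The problem

Tumours with very different mutational backgrounds can converge on the
same drug-response phenotype, which makes any single genomic marker of
chemosensitivity fragile. A transcriptomic alternative is to pool a
large, heterogeneous cell line panel characterised for both expression
and drug response (IC50, on a log2 µM scale, lower = more sensitive),
and to look for genes whose expression consistently marks the sensitive
state across that heterogeneity. `consig` implements such an extraction
pipeline and the battery of evaluations that go with it.

## The extraction pipeline

The pipeline has three layers, all exposed individually and wrapped by
`derive_signature()`:

1. **Fold-wise differential-expression consensus.** The panel is split
   into `n_folds` (default 5) seeded random folds; for each fold the
   retained samples' extreme responders (lowest and highest
   `extreme_fraction` = 20% of IC50) are compared gene by gene with
   three tests:
   * a **moderated t-test**: per-gene pooled-variance two-group model
     with an empirical-Bayes prior $(d_0, s_0^2)$ estimated by the
     method of moments on $\log s_g^2$; posterior variance
     $\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ and
     $\tilde t_g = \mathrm{lfc}_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$
     on $d_0 + d$ df. Significance requires unadjusted $p < 0.20$
     *and* $\mathrm{lfc} \ge 0.5$ (the fold-change gate applies to this
     branch only).
   * a **SAM permutation test**: $d_g = \mathrm{lfc}_g/(s_g + s_0)$,
     with the fudge factor $s_0$ the percentile of the standard errors
     minimising the coefficient of variation of $\mathrm{mad}(d)$
     across $s_g$ windows; the null comes from label permutations
     (default 10000; exhaustive enumeration whenever the number of
     label splits is at most `n_perm`), and per-gene q-values use the
     median false-call count with a quartile-rule estimate of the null
     proportion. Significance: $q \le 0.20$ and $d_g > 0$.
   * a **single-step minP test**: pooled-t raw p-values; a
     null-enforcing bootstrap (per-gene mean-centring within groups,
     resampling pooled columns; default 1000 iterations) yields the
     distribution of the most extreme statistic on the array, and the
     adjusted p-value of a gene is the fraction of iterations whose
     maximal $|t|$ beats the gene's observed $|t|$, clipped below at
     the raw p (the exact adjustment can never undercut it).
     Significance: adjusted $p \le 0.20$ and positive fold change.

   The fold's **seed genes** are the three-way intersection of the
   up-in-sensitive significant sets. Requiring all three tests trades
   recall for a much lower false-discovery burden before the network
   step.

2. **Connectivity filtering on a clinical cohort.** Cell line panels
   and tissue differ; to keep only genes that travel, each seed gene's
   Spearman correlation with every gene of a clinical expression cohort
   is computed (the **affinity** matrix, self-pairs excluded). The
   pooled top 5% of signed affinities become 1, everything else 0 —
   signed, so only positive co-expression survives. A gene's
   **connectivity score** is its mean binarized affinity over seeds
   (self-pairs excluded from the denominator), and the fold's
   **connectivity genes** are the seeds whose score lies strictly above
   the top-20% quantile taken over *all* genes. Both cuts use the
   type-7 (linear interpolation) quantile with a strict `>`, so ties
   fall below the threshold and the result is deterministic; both
   thresholds are pooled/global rather than per-seed or seed-only,
   matching the stated procedure read in order.

3. **Cross-fold consensus.** Genes present in at least
   `consensus_min_folds` (default 3 of 5) per-fold connectivity sets
   form the consensus signature, ordered by membership count then
   lexicographically.

## Scoring and its conventions

A sample's **signature score** is the median of the per-gene z-scored
expression of the signature genes, z-scored within the dataset at hand.
The z-score basis makes scores comparable across platforms; it is used
everywhere a score is computed. For log-axis display the scores are
shifted by $|\min| + 1$, which maps a non-positive minimum to exactly 1
(for an all-positive minimum the formula is applied verbatim and the
minimum lands above 1 — the formula, not the min-to-1 intent, is the
contract). Z-score clipping is a display convention only and never
enters computations.

## Quality control

`qc_metrics()` computes the named metric battery — intra-signature
correlation, mean/median and mean/PC1 Spearman correlations (PC1
sign-aligned to the mean), score SD and CV, the proportion of signature
genes in the top 10/25/50% of genome-wide variance, and score skewness.
Because the median z-score is centred near zero, the CV is computed on
the positively shifted scores; the SD on the raw scores. For radar
comparison (`qc_compare()`), correlations are clipped below at 0,
proportions pass through, SD and CV are min-max scaled across the
signatures being compared (a comparison-relative convention), and
skewness enters as $1/(1+|\mathrm{skew}|)$. The summary is the radar
polygon area divided by the full regular polygon's area.

## Persistence curves and null calibration

A **cell line persistence curve** is a Kaplan-Meier estimate with IC50
in lieu of survival time and every observation an event; with no
censoring it equals one minus the empirical CDF exactly, which the
tests assert at machine precision. Cohorts (top/bottom score quintiles)
are compared with the standard log-rank statistic (hypergeometric
variance for ties) and a proportional-hazards fit with Efron tie
handling; the hazard ratio is oriented so that HR > 1 means the
high-score cohort reaches its IC50 at lower concentrations (more
sensitive) — the reference level is the low-score cohort, stated in the
output. The HR is taken from a Cox fit rather than back-derived from
the log-rank statistic; with all-events data and moderate cohort sizes
the two agree closely, and the Cox route also provides a standard
error.

Because random gene sets of equal length can look deceptively
predictive, every metric can be calibrated against a null of
`n_null` random signatures drawn without replacement from the panel's
gene universe. Degenerate evaluations (constant predictions, undefined
correlations) are dropped and counted, and the observed percentile uses
a strict "less than", so ties with null values count against the
observed signature.

## Prediction models

`fit_predict_cv()` runs a model under outer 5-fold cross-validation:
score-input models use the signature score as single covariate,
per-gene models the z-scored expression of each signature gene, with
standardisation fitted on the training folds only (the data source did
not state a scaling convention; fitting it on the training fold
prevents leakage). Penalized models (elastic net with mixing 0.5, L1,
L2) tune the penalty by inner 10-fold CV on squared error /
misclassification; SVMs (linear and polynomial kernels) grid-search
cost and kernel coefficient over $10^{-3}..10^3$ and degree over
3–5; random forests grow 500 trees. Binary outcomes are "IC50 above
the group median", with exact-median samples labelled 0. The reported
`best_metric` is the best of the five outer folds — faithful to the
source convention but optimistic, so the mean and SD are always emitted
alongside. AUC is computed rank-based from decision values, so SVM
probability calibration is unnecessary. The quintile-subset variant
trains and tests only on the top/bottom score quintiles.

## Translation

Disease sites are ranked by median shifted score (sites under `min_n`
samples dropped — 25 by default for clinical cohorts, 0 for panels) and
compared across datasets by Spearman rank concordance. Mutation
associations use a median score split and per-gene 2×2 chi-square tests
with continuity correction; genes mutated in none or all samples are
untestable and excluded from the Bonferroni factor.

The survival workflow mirrors a train-on-treated design: candidate
genes pass a variance filter (sample variance ≥ 0.2; exact threshold
retained), then a univariate Cox screen keeping genes with coefficient
≤ 0.5. That printed rule is permissive — it keeps protective *and*
mildly hazardous genes — and the narrative reading ("increased
expression, improved survival") suggests protective-only, so
`mode = "protective"` (coefficient < 0) is available; the verbatim rule
is the default. The retained genes enter a joint Cox fit (Efron ties);
risk scores are the plain linear predictor $\eta_j = \sum_g \beta_g
x_{gj}$. Risk groups come from fixed splits (median, tertiles) or from
an exhaustive **optimal cutpoint** search over midpoints between
consecutive sorted unique scores (pairs of midpoints for two cuts),
subject to every group holding at least 4 patients, maximising the
log-rank chi-square; objective ties break toward the lowest
cutpoint(s). Midpoints avoid putting a sample exactly on a boundary.

## The synthetic study

`simulate_cellline_panel()` plants the structure the pipeline assumes:
a latent per-line sensitivity $u \sim N(0,1)$ drives IC50
($4 - 2u + \varepsilon$, noise SD 0.5) and a program of 25 genes with
loading 2 (expression SD units), so *high program expression marks the
sensitive state* — the direction conventions are testable end to end.
Background genes fall into 10 equicorrelated blocks (pairwise
correlation 0.5, a single factor per block — cheap, rank-stable, and
sufficient to exercise connectivity). Disease sites add a global
per-site expression shift (SD 0.3). The defaults — 250 lines, 2000
genes — are the study conditions of the recovery checks; the clinical
cohort (300 samples) shares the program loadings through its own latent
factor, assigns treatment Bernoulli(0.5), and gives treated patients an
exponential event hazard $h_0 e^{-\beta \cdot \mathrm{score}}$
($h_0 = 0.05$/month, $\beta = 1$) while untreated hazards ignore the
score; censoring is independent at rate 0.3. Mutation calls are
Bernoulli(0.2) except one positive-control gene tied to the latent
factor. A `cohort_seed` argument yields independent cohorts over the
same gene structure for honest train/test designs.

What the generator does *not* emulate: microarray probe effects,
library-size artefacts, realistic marginal distributions, cross-platform
batch structure, or correlated mutation processes. Passing tests
demonstrate the pipeline's correctness and direction conventions under
the planted model, not performance on real cohorts.

## Numerical choices and degenerate inputs

* Quantiles are type-7 throughout (R's default; stated because
  conventions differ across software).
* Z-scores use the sample SD (divisor $n-1$); constant genes are an
  error at scoring time and are excluded with a warning where a
  signature merely overlaps them.
* The SAM permutation machinery is vectorised: one matrix product
  against the label-membership matrix gives all permuted group means
  (the within-group sum of squares follows from permutation-invariant
  totals), and per-permutation exceedance counts come from histograms
  over the sorted observed statistics rather than per-permutation
  sorts. Exhaustive enumeration replaces sampling whenever
  $\binom{n}{n_1} \le$ `n_perm`.
* Fold assignment is unstratified by disease site; extreme-responder
  ties are resolved by one stable (IC50, sample id) ordering with the
  sensitive group at its head and the resistant group at its tail,
  which keeps the groups disjoint in every tie configuration.
* Empty seed sets, empty consensus signatures and degenerate null
  evaluations are warnings (with counts), not silent drops; complete
  separation in hazard-ratio fits and non-converging screen genes are
  diagnosed errors or warned drops.
* All stochastic steps (folds, permutations, bootstraps, null
  signatures, simulations) are seeded and reproducible; two runs with
  the same configuration are identical.

## Problem sizes used by the test suite

The recovery checks run the full pipeline at the generator defaults
(250 × 2000, five folds, 10000 permutations, 1000 bootstrap
iterations) over five seeds; null calibration uses 200 replicates of a
200-signature null on a 50 × 300 null panel; the translation check
trains on one cohort's treated arm and tests on an independent cohort
(20 seeds). These sizes are the package's documented study conditions
for its own evaluation.

## Known limitations

* The best-of-folds convention inflates headline metrics; use the mean
  ± SD alongside.
* The pipeline assumes a shared gene universe between panel and
  cohort; no cross-platform harmonisation is attempted beyond within-
  dataset z-scoring.
* Single drug-response column per run; no multi-drug batch mode.
* No weighted (soft-threshold) co-expression; the network is binary by
  construction.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 1)
panel <- simulate_cellline_panel(cfg)
clinical <- simulate_clinical_cohort(cfg)
der <- derive_signature(panel$expr, panel$response, clinical$expr,
                        pipeline_config(rng_seed = 1), verbose = TRUE)
signature_recovery(der$signature, panel$program_genes)

score <- signature_score(panel$expr, der$signature$genes)
q <- quintile_subset(score)
k <- length(q) / 2
logrank_test(panel$response, q[(k + 1):(2 * k)], q[1:k])
```
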