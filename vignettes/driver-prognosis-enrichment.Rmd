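---
title: "Dissecting driver-gene prognosis and family enrichment in PDAC cohorts"
author: "pdacdriver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting driver-gene prognosis and family enrichment in PDAC cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdacdriver)
```

## The problem

Pancreatic ductal adenocarcinoma (PDAC) carries four canonical driver
genes — *KRAS*, *TP53*, *SMAD4*, *CDKN2A* — and most patients are mutant
in two or more of them simultaneously.  A marginal survival comparison
for any one gene therefore mixes that gene's own effect with the effects
of whatever co-occurs with it.  `pdacdriver` implements a
mutation-exclusive stratification: patients are grouped by their *exact*
driver-mutation combination, each combination is compared against a
KRAS-only control by log-rank test, and each gene's marginal contrast is
recomputed after excluding TP53-mutant patients.  If a gene's marginal
association disappears under TP53 exclusion, the association was carried
by co-occurring TP53 mutations.

Downstream, the pipeline asks what distinguishes TP53-mutant expression:
a threshold DEG caller, followed by gene-family over-representation
statistics aimed at small coherent families (box H/ACA and box C/D
snoRNAs, Cajal-body RNAs) whose joint shift marks snoRNA-mediated rRNA
maturation, and a qPCR module quantifying unprocessed rRNA fractions.

## The survival model and the contrast battery

Kaplan–Meier estimation, the Mantel–Cox log-rank test (hypergeometric
variance at ties) and Cox partial-likelihood fits are delegated to the
`survival` package.  Per-variable significance in the multivariate fit is
the sequential likelihood-ratio table (`anova()` on the fitted model).
Median survival is the first time the KM curve reaches 0.5, and is
reported as undefined — not as maximum follow-up — when the curve never
crosses it.  Raw log-rank P values are reported with no multiple-testing
correction across the battery: the battery is a structured description of
one cohort, not a screening experiment.

The battery's control arm, "KRAS-only", means KRAS mutant with all of
TP53/SMAD4/CDKN2A wildtype; "no driver" means all four wildtype.
Patients who lack a KRAS mutation but carry another driver do not fit any
KRAS-conditioned contrast and are simply not used there (they remain in
the marginal and TP53-exclusion contrasts).  Contrasts with an empty arm
are returned as "not evaluable" rather than dropped, so the battery's
shape is stable across cohorts.

## The enrichment statistics

For a family with `m` genes in a background of `N`, and `k` DEGs of which
`a` fall in the family:

- **Fisher's exact test** on `[[a, m−a], [k−a, N−m−k+a]]` (two-sided,
  via `stats::fisher.test`), reported with the sample odds ratio
  `a(N−m−k+a)/((m−a)(k−a))` (0 when `a = 0`, infinite on a diverging zero
  cell) and the exact conditional CI.
- **Enrichment ratio** `(a/m) / ((k−a)/(N−m))`: the DEG fraction inside
  the family over the DEG fraction outside it.  This, rather than the
  sample or conditional-MLE odds ratio, is the package's headline
  effect-size statistic because it is the ratio that published
  family-level tables of this analysis reproduce to within a few tenths
  of a percent.
- **Permutation test**: each of `reps` (default 10^6) simulated datasets
  draws `k` genes uniformly without replacement from the background and
  records the family count.  The Monte-Carlo P is the raw
  `count ≥ a` fraction — the raw estimator, not `(count+1)/(reps+1)`,
  because a zero count is deliberately reported as the bound `< 1/reps`
  rather than a pseudo-P.  The permutation OR is `a` over the mean
  simulated count (which converges to `aN/(km)`), with a CI from the
  normal-approximation standard error of that mean.  Drawing the family
  count from the hypergeometric law is mathematically identical to
  sampling k-subsets and several orders of magnitude faster; a literal
  subset-sampling mode is retained and tested against it.

One-sided (enrichment) tails are the default; depletion is available via
`alternative = "less"`.  Increasing `a` at fixed margins can only shrink
both the Fisher upper-tail mass and the permutation P, a monotonicity the
test suite asserts.

## The DEG caller's conventions

The published decision rule fixes the thresholds (P ≤ 0.05,
|log2FC| ≥ 1, expressed in over 20% of samples, group means not both
below 5) but not the arithmetic around them.  The package's choices:

- "over 20%" and "below 5" are strict inequalities; a gene positive in
  exactly 20% of samples is removed, group means of exactly 5 are kept.
- The t-test is the classical equal-variance two-sample test computed on
  `log2(x + 1)`; the fold change is `log2((mean_A + 1)/(mean_B + 1))` on
  the raw scale.  Log-scale testing with a pseudocount is the standard
  stable treatment of normalized RNA-seq matrices containing zeros.
- "below 5 in both groups" is interpreted per group mean.
- No multiple-testing correction: the raw-P threshold *is* the rule.

The per-gene t statistics are computed vectorized (pooled-variance
formula with `pt`), and the suite cross-checks them against
`stats::t.test(var.equal = TRUE)` gene by gene.

## The synthetic cohort: what it emulates

The generator's defaults are the study conditions of the real combined
cohort where published, and a single documented choice where not:

- Marginal mutation frequencies: KRAS 90.43%, TP53 69.13%, SMAD4 23.21%,
  CDKN2A 20.66% — the observed frequencies in the 762-patient combined
  cohort.  The default cohort size is 762.
- Co-occurrence: SMAD4 and CDKN2A are Bernoulli draws whose logistic
  intercept is recalibrated (by root-finding) so the requested marginal
  is preserved while a log-odds shift (default +1.5) links them to TP53
  status; KRAS is independent.  One parameter reproduces the confounding
  pattern in which SMAD4/CDKN2A look prognostic only through TP53.
- Survival: exponential proportional hazards — rate =
  `baseline_hazard × ∏ HR_gene^status` — with independent exponential
  censoring.  This is the simplest generative model that supports
  log-rank and Cox parameter-recovery tests.  No published effect sizes
  exist for the survival curves, so the hazard ratios are free
  parameters; the defaults (TP53 = 2, SMAD4 = CDKN2A = 1,
  baseline 0.04/month, censoring 0.015/month) plant the qualitative
  conclusion — TP53 carries the signal — at a median survival scale
  (roughly 1–2 years) realistic for resected PDAC.
- Expression: log-normal values with point-mass dropout zeros and the
  family effect planted as a mean log2 shift in TP53-mutant samples —
  matching the log2FC-threshold analysis the matrix feeds.
- qPCR: the unprocessed amplicon sits `−log2(fraction)` cycles above the
  total amplicon before Gaussian Ct noise, so the noise-free round trip
  through the fraction estimator is exact.

What the generator does **not** emulate: batch structure across the three
source cohorts, tumor purity, panel-vs-WGS coverage differences,
multi-hit mutations in one gene, or realistic mutation co-occurrence
beyond the single TP53-linked log-odds.  Passing tests on synthetic data
therefore demonstrate that the statistics are implemented correctly and
calibrated (type-I error, CI coverage, planted-effect recovery), not that
any biological conclusion transfers to real cohorts.

## The qPCR fraction

One qPCR cycle is a two-fold quantity difference at 100% efficiency, so
the quantity ratio of amplicon X over Y is `2^(Ct_Y − Ct_X)` (replicates
averaged on the Ct scale first; efficiency configurable).  "Primer pair
4/3" is read as the single amplicon delimited by primers 4 and 3, so each
species' unprocessed fraction is the arithmetic mean of two
unprocessed-over-total amplicon ratios: pairs 4/3 and 6/5 over 2/1 for
18S, d/c and f/e over b/a for 28S.  The ratio construction makes the
fraction invariant to any additive Ct shift per sample, so no reference
gene is needed.  The module reports fractions and condition-vs-control
fold changes without asserting a biological direction, since published
figure legends and text disagree on which direction p53 pushes
processing.

## Numerical and design notes

- Cox per-variable P values come from the sequential likelihood-ratio
  table, so covariate order matters exactly as in any sequential ANOVA;
  the mutation-count covariate enters as an integer 0–4 by default (a
  categorical coding is a user choice away via `factor()`).
- The marginal-preserving co-occurrence intercept is solved by `uniroot`
  to 1e-12 on the probability scale.
- All randomness descends from explicit integer seeds; the pipeline
  runner derives one sub-seed per stage from the root seed and records
  MD5 checksums of every output in its JSON manifest, so reruns are
  verifiably byte-identical.
- Problem sizes used by the test suite (cohorts of 2000–5000 patients, 50
  replicate cohorts for the confounding battery, 10^5–10^6 permutation
  replicates, 1000 null simulations for calibration) were chosen so each
  stochastic check has at least ~3-sigma resolution against its stated
  bound while the whole suite stays interactive.

## Known limitations

- The package consumes pre-annotated mutation tables; it does not run
  annotation, handle genome coordinates, or re-call variant effects.
- The rank-based DE method whose gene lists the enrichment module accepts
  is consumed as an external file, not reimplemented.
- Gene-set enrichment is annotation-agnostic (any GMT); no live GO or
  pathway-database retrieval is performed.
- Real-cohort P values and curves are not reproducible without
  patient-level data and are deliberately out of scope; the package's
  claims about them are limited to the contingency-count statistics,
  which are fully determined by published counts.
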