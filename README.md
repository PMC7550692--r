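# pdacdriver

Which of the four recurrently mutated PDAC driver genes — *KRAS*, *TP53*,
*SMAD4*, *CDKN2A* — actually carries the prognostic signal?  Because most
pancreatic ductal adenocarcinoma patients carry two or more driver
mutations at once, a marginal survival comparison (mutant vs wildtype for
one gene) is confounded by co-occurring mutations in the others.
`pdacdriver` implements the analysis pipeline that dissects this
confounding and follows the signal downstream to snoRNA-family expression
and rRNA processing:

- **Mutation profiles** — parse annotated somatic-mutation tables, keep
  exonic variants, collapse to per-patient driver-gene status flags, and
  assign patients to mutation-exclusive strata (e.g. "KRAS+TP53-only" =
  KRAS and TP53 mutant, SMAD4 and CDKN2A wildtype).
- **Survival battery** — Kaplan–Meier curves, Mantel–Cox log-rank tests
  and multivariate Cox fits (via the `survival` package), organized into a
  fixed battery of contrasts: each exact mutation combination against the
  KRAS-only control, and each gene's marginal contrast recomputed after
  excluding TP53-mutant patients.  A gene whose marginal association
  vanishes under TP53 exclusion was confounded, not causal.
- **Differential expression** — the threshold DEG caller: genes expressed
  (value > 0) in more than 20% of samples, group means not both below 5,
  equal-variance two-tailed t-test on log2(x+1), called when
  P ≤ 0.05 and |log2FC| ≥ 1.
- **Gene-family enrichment** — for a family of m genes in an N-gene
  background with k DEGs of which a fall in the family: Fisher's exact
  test on the 2×2 table; the enrichment ratio
  (a/m) / ((k−a)/(N−m)); and a random-sampling permutation test drawing k
  genes from the background 10^6 times, giving a Monte-Carlo P
  (count ≥ a over reps), a permutation OR (a over the mean simulated
  count) and its normal-approximation CI.
- **rRNA processing** — unprocessed 18S/28S rRNA fractions from qPCR Ct
  tables: the quantity ratio of a spacer-containing amplicon over the
  total amplicon is 2^(ΔCt), and the species-level unprocessed fraction is
  the mean of its two unprocessed/total ratios.
- **Synthetic cohorts** — a generator planting known mutation frequencies,
  TP53 co-occurrence, hazard ratios, expression shifts and Ct noise, so
  every stage has a reproducible, download-free test surface.

## Worked example

```r
library(pdacdriver)

co <- simulate_cohort(cohort_params(n_patients = 2000, seed = 5))
pr <- build_profiles(filter_exonic(co$mutations), co$clinical)
frequency_summary(pr)$gene_freq
#>     gene n_mutant n_total   pct
#> 1   KRAS     1796    2000 89.80
#> 2   TP53     1373    2000 68.65
#> 3  SMAD4      466    2000 23.30
#> 4 CDKN2A      390    2000 19.50

b <- driver_battery(pr)
b[c(11, 12, 13), c("contrast", "n1", "n2", "p_value")]
#>                                  contrast   n1   n2      p_value
#> 11          E: SMAD4-mut vs SMAD4-wt (all)  466 1534 1.000878e-03
#> 12 E: SMAD4-mut vs SMAD4-wt (TP53-wt only)   53  574 8.164095e-01
#> 13                   F: TP53-mut vs TP53-wt 1373  627 3.247074e-33
```

The generator planted a hazard ratio of 2 on TP53 only, with SMAD4
co-occurring with TP53.  The battery shows exactly the confounding
signature: SMAD4 looks strongly prognostic marginally (P = 0.001), the
association disappears once TP53-mutant patients are excluded (P = 0.82),
and TP53 itself is decisive.

Enrichment of a gene family among DEGs, from contingency counts:

```r
tab <- contingency(a = 4, m = 48, k = 90, N = 16859)
enrichment_ratio(tab)
#> [1] 16.28973
permutation_enrichment(tab, reps = 1e6, seed = 1)$or
#> [1] 15.62622
```

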