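# lymphrisk

Discovery and application of transcriptomic high-risk signatures for early
clinical failure in diffuse large B-cell lymphoma (DLBCL).

Most DLBCL patients are cured by frontline immunochemotherapy, but the
subset who relapse, progress, need retreatment or die within 24 months of
diagnosis — failures of *event-free survival at 24 months* (EFS24) — have
very poor outcomes, and established molecular classifiers (cell of origin,
LymphGen-style genetic subtypes, microenvironment classes) were not designed
to find them. `lymphrisk` implements, end to end, a pipeline that derives a
high-risk expression signature from a discovery cohort and integrates it
with mutation data:

1. **Co-expression modules** — unsigned weighted network from soft-thresholded
   correlations, `a_ij = |cor(x_i, x_j)|^β`, augmented to the topological
   overlap similarity
   `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
   average-linkage clustering with a height cut, module eigengenes (first
   principal components) and Pearson module–trait correlation. The module
   most correlated (negatively) with EFS24 failure supplies signature genes.
2. **Dual differential-expression contrasts** — moderated-*t* tests
   (empirical-Bayes variance shrinkage) of EFS24 failures vs achievers and
   of relapsed/refractory tumors vs achievers, at FDR < 0.05
   (Benjamini–Hochberg). Genes significant and sign-concordant in both
   contrasts are intersected and united with the risk-module genes into a
   directional up/down signature.
3. **Single-sample scoring** — a rank-based bidirectional *totalscore* per
   sample: for each direction, the normalized mean rank
   `(r̄ − (s+1)/2)/(n − s) − 0.5` of the signature genes (descending ranks
   for the down set), summed to a score in [−1, 1]; cohort z-scaling and
   stratification into low / intermediate / high risk at ±1 SD.
4. **Survival association** — Kaplan–Meier curves, log-rank tests and Cox
   proportional-hazards models (Efron ties), unadjusted and adjusted for
   IPI and cell of origin.
5. **Mutation integration** — per-gene enrichment (Fisher/chi-square with
   Haldane-corrected odds ratios), candidate filtering
   (frequency ≥ 5%, OR > 1, chi-square P ≤ 0.15 for EFS24 association),
   L1-penalized logistic regression of failure on risk strata plus
   candidate mutations (10-fold cross-validated penalty), a union
   classifier (high-risk signature OR flagged mutation, e.g. *ARID1A*),
   and pathway mutation burden at a 1.3-fold rule.
6. **Classifier agreement** — pairwise Cohen's κ with asymptotic confidence
   intervals across classifier indicator columns.

A fully parameterized synthetic-cohort generator (`simulate_cohort()`)
emulates the assumed data structure — planted co-expression modules, one
negatively outcome-linked; exponential event times with class-specific
hazards; an ARID1A-like mutation carrying signal partially independent of
expression — so every stage is testable without access to restricted
patient data.

## Worked example

```r
library(lymphrisk)

cohort <- simulate_cohort(simulation_design(seed = 1))
res <- run_discovery(cohort, risk_config(random_seed = 1))
print(res)
#> Risk-signature discovery run
#>   samples: 320 nd + 140 rr; soft power 7
#>   modules: 6 (+ grey); risk module 'red' (r = -0.132 with EFS24 failure)
#>   signature: 136 genes (51 up, 85 down)
#>   risk groups: low=38, intermediate=235, high=47
```

The co-expression step recovers the six planted modules; the 40-gene `red`
module correlates negatively with EFS24 failure (r = −0.132), so its genes
enter the signature as "down" (lower expression in failing cases). The
signature unites them with the genes significant and sign-concordant in
both contrasts, 136 genes in total.

```r
tidy(res$survival$efs_cox)
#> # A tibble: 2 × 6
#>   term             estimate    hr ci_low ci_high        p
#>   <chr>               <dbl> <dbl>  <dbl>   <dbl>    <dbl>
#> 1 riskintermediate    0.129  1.14  0.727    1.78 5.72e- 1
#> 2 riskhigh            2.20   9.03  5.28    15.5  9.06e-16
```

High-risk samples (scaled totalscore > +1 SD) have about nine times the
event hazard of low-risk samples.

```r
res$integration$integrated$metrics[, c("classifier", "sensitivity",
                                       "specificity", "capture")]
#> # A tibble: 2 × 4
#>   classifier      sensitivity specificity capture
#> 1 expression_only       0.425       0.957   0.425
#> 2 integrated            0.563       0.863   0.563
```

The expression signature alone captures 42.5% of EFS24 failures; adding the
mutation flag through the union classifier raises capture to 56.3% at the
cost of some specificity — the sensitivity gain is guaranteed by the union
construction.

Each result type has `autoplot()` (score distributions, module–trait
heatmaps, survival curves, κ agreement heatmaps) and, where applicable,
broom-style `tidy()` / `glance()` methods. A frozen signature can be applied
to an external cohort with `run_apply()`, which polices gene coverage on the
new platform.

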