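# vlotclust

Data-driven stratification of multiple sclerosis (MS) patients by their
pattern of CNS volume loss over time (VLOT), measured with longitudinal
MRI volumetry of six regions: spinal cord, striatum, globus pallidus,
thalamus, cortical gray matter and brain white matter.

MS damages the central nervous system unevenly: some patients lose
spinal-cord and thalamic volume fast while their cortex is relatively
spared, others show predominant pallidal or white-matter loss, and a
small group even shows paradoxical volume *increases* in cord and cortex.
`vlotclust` turns per-visit volumes into per-patient atrophy-rate
profiles and clusters patients by that profile, for neurologists and
imaging scientists who want phenotype-independent, MRI-driven patient
subgroups.

## Method

For patient *i*, region *j*, with complete visits at times
*t₁ < t₂ < …*, the annualized rate is the mean of consecutive-pair
percent changes

```
r_ij = mean over pairs of  100 · (V(t+1) − V(t)) / (V(t) · Δt)     [%/year]
```

Rates are residualized on baseline age by per-region ordinary least
squares. The residual matrix enters a row-weighted covariance-metric PCA
(via SVD of the weight-scaled centered matrix); components are retained
by the smallest leading set reaching ≥ 90 % cumulative variance with the
last eigenvalue > 0.7 (broken-stick and scree-elbow results are attached
as diagnostics). Patients are clustered on the retained scores with
Ward's minimum-variance criterion (`ward.D2` semantics); singleton
clusters are flagged as outliers. Cluster stability is validated by
re-running PCA + clustering under perturbed patient weights (10 % of
patients at weight 0.0001, 10 % at 2, 80 % at 1) and scoring each rerun
against the reference partition with the adjusted Rand index (ARI) and
Meilă's variation of information (VI, base-10 logarithm, so the maximum
for *n* patients is log₁₀ *n*).

Because clinical cohort data of this kind are not openly deposited, the
package ships a synthetic-cohort generator (`generate_cohort()`) that
plants four latent groups with the published group sizes (14/59/141/11)
and per-group rate means/SDs, geometric volume trajectories,
multiplicative measurement noise, a linear age effect and session-level
missingness — with ground-truth labels for recovery testing.

## Worked example

```r
library(vlotclust)

cohort <- generate_cohort(cohort_config(seed = 42))
cohort
#> <ms_cohort> 225 patients, 947 visits
#>   group     n
#> 1 A        14
#> 2 B        59
#> 3 C       141
#> 4 D        11

result <- run_pipeline(cohort$visits, cohort$patients,
                       k = 4, n_reps = 500, seed = 42)
result
#> <vlot_pipeline> 223 patients analyzed (2 excluded), 5 components retained,
#>   k = 4 -> 4 groups + 0 outlier(s)
#> <stability_result> 500 repetitions at k = 4
#>   ARI 0.695 +/- 0.101 ; VI 0.224 +/- 0.072 (base 10)
```

Two of the 225 simulated patients were excluded because session-level
missingness left them with a single usable MRI. Five principal
components (93.5 % of the residual-rate variance) were retained, and the
k = 4 Ward cut produced groups of 154/58/8/3 patients. Over 500
weight-perturbed reruns the partition was reproduced with mean ARI 0.695
(1 = identical) and mean VI 0.224 (0 = identical), i.e. the grouping is
largely but not perfectly stable — as expected, since the two largest
planted groups have strongly overlapping rate profiles.

Per-variable PCA statistics come from `tidy(result$pca)` (coordinate,
squared cosine, contribution per component), the merge tree from
`tidy(result$tree)`, plots from `autoplot()` on the PCA, tree and
stability objects, and group-level summaries from
`result$group_summary` and `result$comparisons` (paired t-tests and
paired Cohen's *d* for all 15 region pairs within each group).

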