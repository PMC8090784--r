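---
title: "Clustering MS patients by patterns of CNS volume loss over time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering MS patients by patterns of CNS volume loss over time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlotclust)
```

## The problem

Multiple sclerosis produces neurodegeneration that is spatially uneven:
the relative pace of tissue loss in the spinal cord, deep gray matter
nuclei, cortex and cerebral white matter differs between patients, and
that *pattern* — not just the overall amount — may carry prognostic
information. `vlotclust` stratifies patients by their multivariate
atrophy-rate profile across six CNS regions measured with longitudinal
MRI volumetry, then quantifies how stable the resulting grouping is.

The pipeline is: annualized rates → age residualization → weighted
covariance PCA with explicit retention rules → Ward clustering →
weighted-resampling stability validation, plus downstream group
summaries (paired contrasts between regions, clinical transforms,
relapse rates, EDSS progression events).

## Rate estimation and its assumptions

A session is *complete* when all six region volumes are present; any
incomplete session is dropped whole, and patients with fewer than two
complete sessions are excluded (`exclusion_filter()`). For the
survivors, `annualized_rates()` averages the annualized percent change
over consecutive visit pairs:

$$r = \frac{1}{m}\sum_{i=1}^{m} 100\,
\frac{V_{i+1}-V_i}{V_i\,(t_{i+1}-t_i)} \quad [\%/\text{year}].$$

Consecutive (not all-pairs) differences are used, unweighted by interval
length: with roughly annual scans this reads each inter-scan change as
one observation of the patient's annual change, and under a geometric
trajectory $V_0(1+r/100)^t$ with annual spacing the estimator returns
$r$ exactly, which makes the simulator an exact oracle for this stage.
The estimator is invariant to per-region volume rescaling (so mm³ vs
cm³ never matters) and exactly covariant under time-unit changes.

Age effects on atrophy are removed by per-region OLS of rate on
*baseline* age (`age_residuals()`); residuals have zero mean and zero
sample covariance with age by construction. If all ages coincide the
residuals degrade to centered rates. At least three patients are
required; below that the regression is under-determined and the
function fails loudly.

## Weighted PCA and component retention

`weighted_pca()` performs covariance-metric (unstandardized) PCA of the
residual matrix with non-negative row weights, computed by SVD of
$\sqrt{w_i}\,(x_{ij}-\bar x_j^w)$ after normalizing weights to sum one.
Covariance rather than correlation PCA is deliberate: the published
eigenvalue-to-percent ratios of the reference analysis imply a total
inertia of about 6.9, which is impossible for a six-variable
correlation PCA, so the analysis being reproduced was evidently run on
unstandardized residuals. Consequences worth knowing:

* eigenvalues carry (%/year)² units and their sum equals the total
  weighted variance;
* the eigenvalue floor of 0.7 in the retention rule is applied as the
  printed absolute threshold, even though such rules conventionally
  presume unit-variance variables.

Variable coordinates use $c_{jk}=e_{jk}\sqrt{\lambda_k}$; the squared
cosine (quality of variable representation) and contribution are the
ratio forms $c_{jk}^2/\sum_k c_{jk}^2$ and
$100\,c_{jk}^2/\sum_j c_{jk}^2$, which are self-consistent regardless of
coordinate scaling. Eigenvector signs are fixed by making each
component's largest-magnitude loading positive, so output is
reproducible across linear-algebra backends.

`select_components()` retains the smallest leading set reaching
cumulative variance ≥ `cum_var_min` (default 0.90) whose last eigenvalue
exceeds `eigen_min` (default 0.7); when no count satisfies both, the
cumulative-variance rule wins with a warning. The broken-stick rule and
the scree elbow (maximum second difference, ties to the smaller index)
are computed but attached as *diagnostics only*: on the published
spectrum the first component's share (38.9 %) already falls below the
six-component broken-stick expectation (≈ 40.8 %) although it was
retained, so the stick cannot have been a hard filter.

## Ward clustering, the cut, and outliers

`ward_linkage()` delegates to `stats::hclust(method = "ward.D2")` on
Euclidean distances between retained component scores. This dialect
(Lance–Williams on squared distances, heights stored as square roots)
is the variant that genuinely minimizes within-cluster variance on
coordinates; two singletons merge at their Euclidean distance, and the
test suite verifies whole merge sequences against brute-force greedy
minimum-ESS agglomeration on small random datasets. hclust's own
deterministic tie-breaking is accepted as-is; exact ties have measure
zero on continuous scores.

The reference analysis cut its dendrogram visually. For
reproducibility the cut is either an explicit `k` (always available and
recommended) or `choose_k()`, which maximizes the gap between
successive merge heights with ties to the smaller k. Clusters smaller
than `min_size` (default 2) are flagged as outliers
(`flag_outliers()`), emulating the exclusion of a single unclassifiable
patient in the reference cohort; remaining groups are relabeled by
decreasing size with patient-id tie-breaks.

## Stability validation

`run_stability()` repeats PCA → retention → Ward → cut → outlier
flagging under perturbed row weights (default: 10 % of patients at
0.0001, a disjoint 10 % at 2, the rest at 1 — down-weighting uses
0.0001 rather than 0 so weighted means stay defined for everyone), and
scores each rerun against the reference partition with the adjusted
Rand index and the variation of information over the items non-outlier
in both partitions. Retention is re-evaluated inside every repetition,
so the retained count may differ from the reference; the cut, however,
is at the reference k, because the question is whether *that* group
structure survives perturbation. Per-repetition seeds are derived from
the master seed, so disjoint repetition ranges concatenate exactly to a
full run.

VI uses base-10 logarithms. This is forced by the reference analysis
equating the maximum disagreement for 225 patients with
log(225) = 2.35, which only holds in base 10 (natural log gives 5.42).
Weights perturb only the component estimation, not the clustering
itself, matching the wording that the contribution weights were
ascribed "to the principal component analysis".

## The synthetic cohort: what it emulates and what it does not

No patient-level data are available, so `generate_cohort()` provides
cohorts with the statistical structure the analysis assumes, plus
ground-truth labels. Defaults reproduce the reference cohort's
structure: four groups of 14/59/141/11 patients; per-group, per-region
rate means and SDs equal to the published annual volume changes;
per-group mean session counts (3.0/4.2/5.3/2.6, SD 1.4, clamped to 2–7
annual visits over at most 6 years); baseline volumes at the
cohort-weighted published means; baseline age 44.7 ± 10.7 years.
Parameters with no published value were fixed once at field-plausible
levels and are configuration, not fitting knobs:

* `noise_cv = 0.005` — multiplicative, mean-one log-normal measurement
  error; volume measurement error scales with structure size, and
  half-a-percent test–retest variability is typical of modern
  volumetry;
* `age_slope = -0.02` %/year of rate per year of age — a mild
  acceleration of loss with age, removed exactly by the
  residualization stage;
* `p_session_missing = 162/1271` — the reference study's own reported
  fraction of failed MRI sessions, applied as whole-session removal
  with baselines always kept;
* group relapse rates 0.25/0.20/0.15/0.20 events/year, in the range
  typical of treated relapse-onset MS cohorts.

Trajectories are geometric with a constant per-patient rate. Real rates
drift within patients; the simulator deliberately omits this (and any
treatment effect, lesion dynamics, or scanner drift), so passing
recovery tests demonstrates correctness of the estimation machinery,
not robustness to every real-data pathology. An optional
`outlier_archetype` flag injects one patient at least 4 SD from every
profile to exercise the outlier path.

One property of the defaults deserves emphasis: the published per-group
SDs describe the within-group spread of a partition that was *produced
by* clustering the real data. Gaussian groups resampled with those SDs
overlap substantially (especially the two largest groups), so no
clustering method can recover the planted labels near-perfectly under
these defaults — the package's recovery checks on the default profiles
therefore characterize attainable agreement, while exact-recovery
checks use explicitly well-separated profiles.

## Numerical choices and degenerate inputs

* Duplicate timepoints fail naming the patient; non-finite scores fail
  naming the patient.
* Rank-deficient residual matrices yield trailing zero eigenvalues
  without error; zero-variance variables get `NA` squared cosines with
  a warning.
* Paired contrasts with constant differences report the mean difference
  with `NA` t/p; a paired Cohen's d with zero-SD differences is 0 when
  the mean difference is 0 and an error otherwise.
* The EDSS log transform is `log(EDSS + 1)`: the scale includes 0, where
  a raw log is undefined.
* "No relapse in the last 12 months" is evaluated against the candidate
  progression visit's date; cohort tables record relapse counts per
  inter-visit interval, which the cohort-level wrapper places at the
  interval midpoint.
* Test problem sizes are kept intentionally modest (e.g. 100–500
  stability repetitions, brute-force Ward oracles at n ≤ 7, 10-seed
  recovery sweeps); all scale linearly to the published 10,000
  repetitions.

## Limitations

Upstream MRI processing (segmentation, head-size normalization, lesion
filling) is out of scope — inputs are assumed to be already-quantified,
already-normalized volumes. Standard inferential fits on the emitted
tables (ANCOVA, mixed-effect models, Cox regression) are left to stock
routines. The max-gap `choose_k()` heuristic is a reproducible
stand-in for a visual judgment and, on heavily overlapping groups,
tends toward the coarsest split; pass `k` explicitly when the target
granularity is known.
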