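---
title: "Methods: frequency-ranked radiomic biomarkers and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-ranked radiomic biomarkers and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(radstrat)
```

## The problem

In advanced non-small-cell lung cancer, patients with similar stage, age
and sex often have very different survival. Quantitative texture features
computed from routine CT — here 107 descriptors in seven families
(first-order intensity, shape, GLCM, GLSZM, GLRLM, NGTDM, GLDM) — may
capture tumor heterogeneity that clinical variables miss. Two statistical
obstacles stand in the way: the feature space is high-dimensional relative
to the cohort (hundreds of features, a few hundred patients), and the
features are strongly mutually correlated, so any single fitted model is an
unstable basis for declaring one feature "the" biomarker.

`radstrat` addresses both with a stability-first design: importance is
defined by how often a feature survives penalized selection across many
resampled fits and regularization settings, and redundancy among the
winners is resolved explicitly rather than left to the whim of one
coordinate-descent path.

## Selection-frequency ranking

For each Monte Carlo run, 80% of patients are drawn without replacement
(large enough to keep events in every cross-validation fold, small enough
to perturb the fit — the standard stability-selection compromise). For
each mixing value $\alpha \in \{0, 0.1, \dots, 1\}$ an elastic-net Cox
model is fitted:

$$\hat\beta(\alpha,\lambda) = \arg\min_\beta\;
-\ell(\beta) + \lambda\Big[\alpha\lVert\beta\rVert_1 +
\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\Big],$$

where $\ell$ is the Cox log partial likelihood with Breslow tie handling.
$\lambda$ is selected per fit by 10-fold cross-validated
partial-likelihood deviance over an internally generated geometric path,
with folds stratified by event status so every fold retains events; when
two path points tie, the larger (more parsimonious) $\lambda$ wins.
Features with $|\hat\beta| >$ `nonzero_tol` (default $10^{-8}$) count as
selected. Only the radiomic features enter the penalized model; clinical
covariates are reserved for downstream stratification.

With the default 100 runs, $100 \times 11 = 1100$ models are evaluated.
Two accounting conventions matter:

* **Ridge counting.** At $\alpha = 0$ no coefficient is exactly zero, so
  every retained feature counts as selected in those models. Counting is
  thus uniform in "non-zero coefficient" across the grid, and the
  discrimination between features comes from the sparse end of the grid.
* **Failure exposure.** A failed fit (e.g. cross-validation collapsing on
  a degenerate subsample) is recorded as lost exposure for every feature,
  never as silent non-selection: `count + failures + not_selected =
  total_models` holds per feature. This is also why a maximal observed
  count can legitimately fall short of the total.

Ranks are competition ("1224") ranks: tied counts share the better rank,
and the rank-1 tie group is carried forward as a set.

The penalized fits themselves are delegated to `glmnet`; the package's
contribution is the resampling × grid design, the counting and tie-aware
ranking, and their validation. `fit_penalized_cox()` exposes single fits
(used in tests against an independent Newton–Raphson oracle on the partial
likelihood); the λ path resolution (`nlambda`) is configurable, and the
experiments below use a coarse 10-point path, which we found preserves the
ranking while keeping repeated-fit designs tractable.

## Redundancy and the representative biomarker

Top-ranked radiomic features are typically interchangeable carriers of the
same signal: rank correlations within the leading tie group routinely
exceed 0.6. For the candidate set $C$ (the rank-1 tie group, or the top 5
by count when untied — five is the natural display size for a leading
group and matches common practice), each candidate gets a
representativeness strength score

$$\mathrm{RSS}(f) = \frac{1}{|C| - 1}\sum_{g \in C,\, g \ne f} |\rho_S(f, g)|,$$

the mean absolute Spearman correlation with the remaining candidates. The
maximal-RSS feature is the representative — the candidate that shares the
most information with the rest of the set, so collapsing the set onto it
discards the least. Ties break by selection frequency, then name. The
0.6 threshold is a descriptive redundancy flag (a warning fires when even
the best RSS falls below it), never a hard filter.

One subtlety: RSS is a tie-breaker, not a ranking override. When the top
count is genuinely tied, the tie group members are statistically
interchangeable and the most central one is the right single
representative. When the top is untied, the top-5 fallback set is
heterogeneous and its most central member may not be the most predictive
feature — so the pipeline stratifies by the representative only when it
resolved a real tie, and by the rank-1 feature otherwise. The redundancy
report is produced either way.

## Binary data mapping and stratification

* **Stage:** I and II form the Low-Stage class; IIIa and IIIb the
  High-Stage class.
* **Age and biomarker:** median splits, with the convention that values
  *at or below* the median go to the low group. This is deterministic,
  invariant under monotone transforms, and yields exact 199/199 splits for
  398 distinct values. The median is always computed from the data at
  hand, never hard-coded.
* **Gender:** Female/Male as recorded.

`build_strata()` crosses any list of binary factors into the full cell
grid with per-cell counts (the data behind subgroup count heatmaps); cells
are checked to partition the cohort.

## Kaplan–Meier, Greenwood bands, log-rank

The survival primitives are implemented from first principles (the
`survival` package serves only as an independent cross-check in the test
suite):

* Product-limit estimate $S(t) = \prod_{t_j \le t} (1 - d_j / n_j)$ over
  distinct event times, with censored observations at an event time kept
  at risk for that time (censoring after events at ties — consistent with
  Breslow handling in the Cox module).
* Greenwood variance accumulated as $\sum d_j / (n_j(n_j - d_j))$,
  turned into confidence bands on the complementary log–log scale so the
  bands stay inside $[0, 1]$; $S = 1$ segments get the degenerate band
  $[1, 1]$.
* Two-group log-rank test with hypergeometric variance, summed over
  distinct event times, referred to $\chi^2_1$. Reported p-values are
  displayed to two significant figures and floored at "<0.0001".

`compare_strata()` packages one figure panel: the two KM curves with
bands, group sizes, events, median survival, and the log-rank result,
optionally restricted to a stratum cell (e.g. "Low-Stage patients split by
biomarker"). Empty-after-restriction panels are skipped with a message.

## Survival-adapted SMOTE

Plain SMOTE is undefined for (time, event) pairs. The adaptation here:

* Generation happens within event-status strata of each minority class, so
  a synthetic row inherits its stratum's event status — no fractional
  event labels, and each class's censoring fraction is preserved up to
  rounding (within 1/min-stratum-size).
* Features, age and survival time are interpolated with the same uniform
  weight $w$ between a seed row and one of its $k = 5$ nearest minority
  neighbours (Euclidean distance on per-stratum standardized features;
  time and covariates are excluded from the metric so class geometry
  reflects the radiomic profile). Categorical covariates copy from the
  seed parent.
* Every synthetic row records its two parents and $w$, so convexity is
  verifiable after the fact.
* A stratum of size 1 cannot be interpolated; by default this is an error.
  The pipeline opts into `size_one = "skip"`, which reallocates that
  stratum's quota to the class's other strata with a warning — at
  realistic cohort sizes the smallest subgroup cells can contain a single
  censored patient, and aborting the whole exploratory stage for one
  unsynthesizable row would be disproportionate.

Balanced sets are exploratory only: they are generated after, and never
feed into, ranking and representative selection (the pipeline asserts this
ordering), and they are never used for hazard-ratio estimation.

## The synthetic cohort generator

The generator defines the study conditions for every test:

* **Features:** a Gaussian copula with exchangeable block structure —
  latent correlation 0.6 within each of the 7 category blocks
  (18/14/24/16/16/5/14 features; the NGTDM block carries its five real
  texture names, including Busyness) and 0.2 across blocks — pushed
  through $\exp(z/2)$ for positive, right-skewed, radiomic-like marginals.
  The within-block value reproduces the observed redundancy regime among
  top features; the cross-block value is a stand-in for the unreported
  inter-family correlation, chosen moderate so that cross-family
  redundancy exists without collapsing the block structure. Monotone
  transforms leave Spearman structure intact, so the latent correlations
  translate directly (Spearman $= \frac{6}{\pi}\arcsin(\rho/2) \approx
  0.58$ within blocks).
* **Survival:** Weibull proportional hazards (shape 1.1, scale 2.2 years,
  putting the overall median near 1.5 years) with linear predictor
  $0.8 \cdot \text{Busyness (per SD)}$ plus weak clinical effects. The
  clinical log-HRs (0.25 per age decade, 0.25 male, 0.05 high stage) were
  back-calculated once from the separation such variables show in
  published cohorts of this size — age clearly significant, gender
  marginal, stage not detectably prognostic at n = 398 — and are not
  tuning knobs.
* **Covariates:** age Normal(68.1, 10.1) truncated to [30, 95]; 68.6%
  male; stage probabilities 0.211/0.093/0.348/0.348 (the 69.6% stage-III
  mass split evenly across IIIa/IIIb, which the source table does not
  resolve). An optional `stage_coupling` parameter correlates the latent
  stage propensity with the planted feature for sensitivity experiments;
  the default 0 keeps stage uninformative about the radiomic profile.
* **Censoring:** independent exponential, its rate solved by `uniroot` so
  the expected censored fraction over the realized event times equals the
  target (11.8% by default). Single-parameter, independent of the event
  process, and verifiable by Monte Carlo.

What the generator does *not* emulate: real radiomic marginal shapes
beyond positivity and skewness, inter-feature correlation beyond the
two-level exchangeable structure, informative censoring, or any
image-level effect. Tests passing on these cohorts show the pipeline's
statistical machinery is correct and recovers planted structure under
realistic dimensions and censoring — not that any particular real-data
finding generalizes.

## Numerical choices and degenerate inputs

* Coordinate-descent convergence: single fits use `thresh = 1e-10`
  (tightened further in oracle tests); repeated CV fits inside the ranking
  use `1e-5` — selection decisions depend on which coefficients the path
  zeroes, not on their last digits, and correlated radiomic blocks make
  tight tolerances disproportionately expensive.
* Zero-variance features are dropped from a fit with a message and
  reported with coefficient 0; zero-variance features in a Spearman matrix
  yield flagged `NA` entries.
* All-identical values cannot be median-split (error); unknown stage
  tokens are rejected by name.
* Per-run and per-stage seeds derive deterministically from the global
  seed (sampled run-seed vector; fixed counter scheme in the pipeline), so
  any stage can be reproduced in isolation and full runs are byte-identical.
* Problem sizes in the test suite are scaled for repeated-fit designs:
  recovery experiments use 20 runs × 11 α at n = 398 over 20 replicates,
  protocol accounting uses the full 100 × 11 design on a 60-patient,
  20-feature cohort, and CV uses a 10-point λ path in both — sizes at
  which the ranking behaviour matches the full-resolution design on the
  cohorts we checked.

## Known limitations

* The Monte Carlo scheme (80% subsampling without replacement) and the
  per-(run, α) counting convention are one reasonable reading of
  "repeated resampling"; alternatives (bootstrap, per-run any-α counting)
  would change absolute counts though rarely the ordering.
* RSS is computed within the top tie group only; a broader candidate set
  (e.g. top 16) would weigh redundancy against more distant features.
* The SMOTE adaptation interpolates survival times linearly, which has no
  rigorous time-to-event justification; it is deliberately quarantined to
  exploratory balance checks.
* Competition ranking makes tie groups sensitive to single-count
  differences at small run counts; use more runs when tie-group
  membership matters.
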