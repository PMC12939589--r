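# radstrat

Radiomic texture features extracted from routine CT imaging carry prognostic
information that conventional clinical variables (tumor stage, age, sex) miss.
`radstrat` implements a survival-based workflow for finding and validating
such imaging biomarkers in right-censored cohorts of non-small-cell lung
cancer patients:

1. **Selection-frequency ranking.** For each of `R` Monte Carlo subsamples
   (80% of patients, without replacement) and each elastic-net mixing value
   `α ∈ {0, 0.1, …, 1}`, a penalized Cox proportional-hazards model

   `argmin_β  −ℓ(β) + λ [ α‖β‖₁ + (1−α)/2 ‖β‖₂² ]`

   is fitted (Breslow ties), with `λ` chosen by 10-fold cross-validated
   partial-likelihood deviance. Every feature with a non-zero coefficient is
   counted as selected; counts over all `R × 11` models rank the features.
   Stability across resamples and regularization settings — not a single
   optimized model — defines importance.
2. **Redundancy analysis.** Top-ranked features are usually strongly
   rank-correlated (|ρ| ≥ 0.6). Within the rank-1 tie group, each feature's
   representativeness strength score (RSS: mean |Spearman ρ| with the other
   candidates) is computed, and the maximal-RSS feature becomes the single
   representative biomarker.
3. **Hierarchical stratification.** Median dichotomization of the biomarker
   (and age), Low (I+II) vs High (IIIa+IIIb) stage, and gender define nested
   subgroups; from-scratch Kaplan–Meier curves with Greenwood log–log
   confidence bands and two-group log-rank tests quantify survival
   separation in every subgroup panel.
4. **Exploratory SMOTE balancing.** Small subgroups are rebalanced by a
   survival-adapted SMOTE (interpolation within event-status strata) to
   check that stratification patterns persist under balanced composition.
   Balanced data never feed the ranking or any hazard estimate.

A synthetic cohort generator (`cohort_spec()` / `generate_cohort()`)
emulates a Lung1-style table — 398 patients, 107 radiomic features in 7
correlated category blocks, ~12% censoring, and a planted prognostic NGTDM
"Busyness" feature — so the entire pipeline is testable without any data
download.

## Worked example

```r
library(radstrat)

spec <- cohort_spec(seed = 11)         # 398 patients, 107 features
cohort <- generate_cohort(spec)
freq <- rank_biomarkers(cohort, n_runs = 20, nlambda = 10, seed = 11)
print(freq, n = 5)
#> Elastic-net selection-frequency ranking
#>    20 runs x 11 alpha values = 220 models; 10 -fold CV lambda
#>  rank    feature category count total_models
#>     1   Busyness    NGTDM   220          220
#>     2 Coarseness    NGTDM   218          220
#>     3   GLSZM_10    GLSZM   185          220
#>     4    GLCM_05     GLCM   183          220
#>     5   Contrast    NGTDM   182          220

select_representative(freq, cohort)
#> Redundancy analysis of 5 candidate features
#>   |rho| >= 0.6 flags redundancy
#>     feature count   rss
#>  Coarseness   218 0.403
#>    Contrast   182 0.402
#>    Busyness   220 0.393
#>    GLSZM_10   185 0.245
#>     GLCM_05   183 0.208
#> Representative: Coarseness (RSS = 0.403)

f_stage <- binarize_stage(cohort$stage)
f_bio   <- binarize_biomarker(cohort, "Busyness")
compare_strata(cohort$time, cohort$event, f_bio,
               within = f_stage$labels == "Low")
#> KM panel: biomarker:Busyness
#>  group  n events median_survival
#>    Low 66     52           2.004
#>   High 58     56           0.792
#>   log-rank chi-square = 23.1, p = <0.0001

compare_strata(cohort$time, cohort$event, f_stage,
               within = f_bio$labels == "Low")
#> KM panel: stage
#>  group   n events median_survival
#>    Low  66     52           2.004
#>   High 133    111           2.209
#>   log-rank chi-square = 0.3881, p = 0.53
```

The planted biomarker tops the ranking (selected in all 220 models), its
correlated NGTDM block-mates rank alongside it, and the redundancy step
scores each rank-1-adjacent candidate by mean |Spearman ρ| (here the top
counts are untied, so the candidate set is the top 5 and the RSS
differences among the NGTDM members are small — a low-redundancy warning
flags that this set is more heterogeneous than a true tie group).
Downstream, the biomarker split separates survival sharply within a stage
level (median 2.00 vs 0.79 years, log-rank p < 0.0001), while the stage
split within a biomarker level stays non-significant (p = 0.53) — the
asymmetry the workflow is designed to expose. (Output from the exact
calls above; the same seeds reproduce the same numbers.)

`run_full_pipeline(pipeline_config(...))` executes every stage end to end
and writes all tables (frequency ranking, correlation matrix, stratum
counts, KM/log-rank panels, SMOTE-balanced panels) as CSV;
`make_report(dir)` summarizes a run.

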