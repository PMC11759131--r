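# cmforest

Which characteristics of child maltreatment (CM) — subtype, timing,
duration, frequency, subjective severity, multiplicity — are most strongly
associated with physical multimorbidity in adulthood? The derived survey
variables are intrinsically collinear (duration is the sum of the 18
per-age timing indicators; multiplicity is the sum of the four subtype
flags), so single-model coefficients are uninterpretable. `cmforest`
implements the analysis chain built for exactly this situation, for
epidemiologists working with retrospective maltreatment instruments:

* **Feature derivation** from ICAST-R-style records: subtype flags,
  multiplicity (0-4), per-age timing indicators `t_1..t_18`, duration
  (0-18), max-coded frequency/severity (0-3), and a 0-7 physical
  multimorbidity count.
* **A conditional-inference regression forest** (written from scratch,
  Rcpp core). Split variables are chosen by the asymptotic permutation
  p-value of the standardized linear statistic
  `T = Σ g(x_i) y_i`, standardized by its conditional permutation mean and
  covariance — selection is unbiased with respect to measurement scale and
  category count. Trees grow on subsamples drawn without replacement.
* **Permutation variable importance**, marginal or conditional (permuting
  within the partition each tree induces on correlated predictors), with
  10×10-fold cross-validated estimation, an outcome-reshuffling
  permutation null with add-one empirical p-values
  `p = (1 + #{null ≥ obs}) / (B + 1)`, and paired importance contrasts of
  type/timing predictors against the global scores.
* **Descriptives and sensitivity analyses**: stratified sample tables with
  χ²/Welch tests, multimorbidity means by multiplicity with 95% CIs, and
  OLS models `multimorbidity ~ exposure × age_group + covariates`.
* **A synthetic survey generator** with configurable ground truth,
  calibrated to published stratified sample characteristics (≈36.5% any-CM
  prevalence, subtype rates 6-24% with gendered sexual/physical contrasts,
  mean multimorbidity ≈0.6), so the entire chain is testable without any
  restricted survey data.

All user-facing functions take a data frame first and return tibbles;
fitted objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(cmforest)
library(dplyr)

cohort <- generate_cohort(sim_config(n_respondents = 1500, seed = 42))
feats  <- feature_matrix(cohort)

fc <- forest_config(n_trees = 100, alpha_split = 1, seed = 42)
cv <- cv_importance(feats, fc, folds = 5, repetitions = 2)

tidy(cv) |> filter(stratum == "woman") |> arrange(desc(importance)) |> head(6)
#> # A tibble: 6 × 5
#>   stratum predictor importance      sd reliability
#>   <chr>   <chr>          <dbl>   <dbl>       <dbl>
#> 1 woman   age          0.107   0.0220    0.00359
#> 2 woman   duration     0.00779 0.00424   0.000414
#> 3 woman   t_16         0.00291 0.00199   0.000227
#> 4 woman   t_11         0.00265 0.00177   0.0000749
#> 5 woman   severity     0.00140 0.00221   0.000712
#> 6 woman   t_10         0.00121 0.00118   0.000686

contrast_importance(cv, "duration", "multiplicity")
#> # A tibble: 2 × 8
#>   stratum focal    reference    statistic    df  p_value stars mean_difference
#>   <chr>   <chr>    <chr>            <dbl> <dbl>    <dbl> <chr>           <dbl>
#> 1 woman   duration multiplicity      5.66     9 0.000308 ***           0.00777
#> 2 man     duration multiplicity      6.57     9 0.000103 ***           0.0205
```

Reading this: in the women stratum the covariate age dominates, and
**duration** is the leading maltreatment characteristic — exactly the
structure this cohort was generated with (`beta_duration = 0.13` per year
on each disease's log-odds). The contrast row says duration's
cross-validated importance exceeds multiplicity's by a paired t of 5.7
across the 10 fold replicates (p < .001) for women, 6.6 for men. Out-of-
fold validity is in `glance(cv)` (here R² ≈ 0.17/0.21), and
`permutation_null(feats, fc, n_reshuffles = 5000)` attaches chance-based
p-values to each importance. `autoplot(cv)` draws the importance dot
plot; `fit_interaction_model(feats, "duration")` and
`predicted_surface()` give the age-interaction sensitivity analysis.

A full config-driven run — descriptive table, group means, CV importance,
contrasts, reshuffling null, sensitivity models, predicted surface, run
manifest, all as CSVs — is one call:

```r
run_pipeline("inst/extdata/demo_config.yaml", outdir = "results_demo")
```

Identical config + seed ⇒ byte-identical CSVs.

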