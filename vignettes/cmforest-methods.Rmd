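---
title: "Methods: conditional-inference forests for maltreatment characteristics and adult multimorbidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional-inference forests for maltreatment characteristics and adult multimorbidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmforest)
```

## The scientific problem

Retrospective surveys of child maltreatment (CM) record much more than a
yes/no exposure: which of four subtypes occurred (neglect, physical,
emotional, sexual abuse), at which ages between 1 and 18, for how many
years, how often, and how severely. The epidemiological question this
package addresses is which of these characteristics carries the strongest
association with a count of physical diseases in adulthood (overweight,
diabetes, cancer, hypertension, myocardial infarction, COPD, stroke; a 0-7
"physical multimorbidity" score).

The derived characteristics are, by construction, heavily collinear:
duration is the sum of the 18 per-age timing indicators; multiplicity is
the sum of the four subtype flags; frequency and severity are only defined
for exposed respondents. Coefficients of a single regression containing
all of them are therefore uninterpretable. The analysis chain implemented
here instead uses a conditional-inference regression forest with
permutation variable importance, an outcome-reshuffling null for
importance significance, paired contrasts of importance scores, and linear
age-interaction models as a sensitivity analysis — together with a
synthetic cohort generator with known ground truth so that the whole chain
is testable end to end.

## Feature derivation

A subtype counts as experienced when at least one of its five described
acts is affirmed; a declined answer counts as not affirmed (a strict
analyst can instead drop such respondents before derivation — the coding
rule itself is not configurable to keep the feature matrix reproducible).
The timing indicator `t_a` is 1 when age `a` appears in the exposure ages
of any subtype, duration is `sum(t_1..t_18)`, and multiplicity is the
number of experienced subtypes. Frequency and severity take the maximum of
the inverted follow-up answer codes on a 0-3 scale: higher means more
frequent or more severe, and 0 means unexposed. "Not at all" therefore
shares code 0 with unexposed respondents: the instrument's answer scale
has four points, an unexposed respondent has no answer at all, and merging
the two keeps a single ordinal column per characteristic. A respondent can
in principle affirm a subtype but report no ages (multiplicity > 0,
duration = 0); `derive_features()` permits this and reports it with a
message, while the generator never produces it.

Gender is a stratifier, never a predictor: every analysis runs separately
for women and men, mirroring how such survey results are tabulated.

## The forest

Each tree is a conditional-inference tree: at a node, `mtry` randomly
chosen candidate predictors are screened with the asymptotic permutation
test of the standardized linear statistic
\(T = \sum_i g(x_i)\,y_i\), with \(g\) the identity for numeric predictors
and one-hot level indicators for categorical ones. \(T\) is centred and
scaled by its conditional permutation mean and covariance and referred to
a chi-square distribution with df equal to the covariance rank. Because
the selection statistic is a p-value, predictors with many categories or
many distinct values gain no artificial advantage — the reason this tree
family is preferred over CART-style exhaustive search when variable
importance is the goal. For numeric predictors this statistic reduces to
\((n-1)r^2\); the tests verify the asymptotic p-values against exhaustive
enumeration of all permutations at \(n \le 8\).

Splitting uses the smallest Bonferroni-adjusted p-value among the
candidates; the cutpoint maximizes the standardized two-sample statistic
over all observed midpoints (ties broken toward the smaller left child,
making tree growth deterministic given the seed). Categorical splits order
the levels by mean outcome and scan prefix partitions. Trees are grown on
subsamples drawn *without replacement* (fraction 0.632), which the
unbiased-importance literature prescribes in place of bootstrap
resampling.

Two stopping rules exist. `forest_config()` defaults to
`alpha_split = 0.05`: a node becomes a leaf when no candidate reaches
Bonferroni-adjusted significance — the right default for a *single*
interpretable tree. For a *forest*, the field's practice is to disable the
significance stop (`alpha_split = 1`) and let node size (`min_node_size`,
default 20) limit growth: individual trees overfit mildly and averaging
removes the noise. At survey scale the difference is dramatic — with
alpha-stopping, most trees in a forest of subsamples are a single root
leaf and every importance collapses to exactly zero. `run_pipeline()`
therefore uses `alpha_split = 1` in its default forest block, and the
analyses below do the same. Remaining defaults (`n_trees = 500`,
`mtry = ceiling(sqrt(p))`) are ordinary forest defaults; nothing in the
package's conclusions is sensitive to them, only the Monte-Carlo noise of
the importance estimates.

## Permutation importance, marginal and conditional

Importance of predictor `v` is the mean over trees of the increase in that
tree's mean squared error after permuting `v` over the tree's evaluation
cases (out-of-bag rows, or a held-out fold during cross-validation).
Values can be negative; a predictor used by no tree has importance exactly
zero.

Marginal permutation breaks both the predictor-outcome association and the
predictor's correlation with other predictors, so a variable that is
merely correlated with a true risk factor still earns importance.
Conditional permutation, the pipeline default, permutes `v` only within
cells of a partition of its correlated companions (|Pearson r| > 0.2), so
importance reflects the contribution of `v` beyond what those companions
already explain. The conditioning partition is the one *each tree itself*
induces: the cutpoints the tree applies to the conditioning variables. An
alternative — one global grid of quartile bins over all conditioning
variables — degenerates at this problem's dimensionality: duration is
correlated with some twenty other columns, a quartile grid over twenty
variables puts nearly every case in its own cell, and the "permutation"
then moves nothing. The tree-based partition stays coarse by construction
and is what the conditional-importance literature defines.

## Cross-validated estimation and the reshuffling null

`cv_importance()` repeats k-fold cross-validation (10 repetitions of
10-fold by default): each forest is fit on the training folds and its
importance evaluated on the held-out fold; the mean and SD over all
fold-fits estimate each predictor's importance and its sampling
variability, and the SD of the per-repetition means measures the
reliability of the random fold split. Out-of-fold MSE and R-squared are
recorded per fit as estimation validity.

Significance comes from an outcome-reshuffling null
(`permutation_null()`): the outcome column is permuted, the forest refit
on the full stratum and importance recomputed — 5000 times by default
(reduced in tests and in the demo pipeline; the scale only affects p-value
resolution, never the observed importance, which the tests pin). The
empirical p-value uses the add-one estimator
\(p = (1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)\), which can never
return zero and is valid (super-uniform) under the null by exchangeability
of the observed and reshuffled fits. The null loop deliberately refits on
the full stratum without an inner cross-validation: the null targets the
sampling distribution of the importance statistic, and nesting the full
CV inside 5000 reshuffles would multiply cost by two orders of magnitude
for no change in the comparison.

Contrasts of "type and timing" predictors against the global scores
(multiplicity, duration, severity) are paired t statistics across the
fold replicates of `cv_importance()` (`contrast_importance()`). The
statistic is antisymmetric in its arguments; its absolute scale depends on
the CV shape and is not comparable across studies — only sign and
significance are interpreted.

## The synthetic cohort generator

`generate_cohort()` emulates the record structure of a general-population
retrospective CM survey. Its defaults are calibrated, once, to published
stratified sample characteristics of such a survey and then frozen:

* 36.5% of respondents report at least one subtype; pooled subtype
  prevalences 16.7% (neglect), 21.2% (physical), 22.9% (emotional), 9.4%
  (sexual), with sexual abuse twice as frequent among women and physical
  abuse 1.3 times as frequent among men (multipliers renormalized so the
  pooled rates are preserved).
* Subtype co-occurrence comes from one shared Gaussian liability with
  latent correlation 0.4 and per-subtype thresholds; draws in which an
  "exposed" respondent activates no subtype are rejected and redrawn, and
  the thresholds are solved by a fixed-point calibration so the
  *post-rejection* marginal rates hit their targets exactly.
* Exposure is a contiguous episode: onset age from a frozen distribution
  over ages 1-18 and geometric length with mean 6 years, clipped to 1-18
  and shared by all active subtypes. The onset distribution and episode
  mean were obtained jointly by deconvolving the published per-age
  exposure prevalence profile against the geometric survival curve — a
  shorter episode mean cannot reproduce that profile with any proper
  onset distribution. The implied overall mean duration (~1.79 years)
  matches the published 1.71/1.80. A `multi_episode` flag unions a second
  independent episode for non-contiguous exposure histories.
* Follow-up frequency/severity answers come from cumulative-logit models
  whose probability of higher categories increases with episode length
  (slope 0.25 per year); intercepts were set so the follow-up score means
  match the published means.
* Disease indicators are independent Bernoulli draws given a logistic
  linear predictor in duration (`beta_duration`, default 0.13 per year),
  a timing window (`beta_timing_window`, default ages {4, 11} at 0.10),
  current age (0.055 per year) and standardized income (-0.15).
  Per-disease intercepts are calibrated at generation time so marginal
  disease prevalences match published values (hence mean multimorbidity
  ~0.63); passing `beta0` overrides this. `beta_duration = 0.13` makes
  the multiplicity-multimorbidity correlation ~0.17, the published value.
  `beta_duration_old_mult` multiplies the duration coefficient in the
  oldest within-cohort age tertile to plant an age-modified effect.

What the generator does *not* emulate: survey weights and regional
stratification, nonresponse, residual disease-disease correlation beyond
the shared linear predictor, any dependence of subtype on timing or
severity beyond episode length, and recall error. Tests passing on this
generator therefore show that the analysis chain recovers a known
duration-driven structure under realistic marginals — not that any real
survey's effect estimates are correct.

## Sensitivity models

`fit_interaction_model()` fits, per stratum, the OLS model
`multimorbidity ~ exposure * age_group + covariates` with age grouped into
within-stratum tertiles by default (decades or custom cut points are
available) and the youngest group as reference. The default covariate set
is the four subtype flags plus frequency and severity, pruned of whatever
is collinear with the chosen exposure (the subtype flags sum exactly to
multiplicity, so they are dropped when multiplicity is the exposure).
Rank-deficient designs are an error naming the collinear columns rather
than a silent drop. Standardized coefficients are reported as
`estimate * sd(x)/sd(y)`; the headline "interaction beta" is the
standardized coefficient of exposure-by-oldest-group, which is invariant
to affine rescaling of the exposure. `predicted_surface()` evaluates the
fitted linear predictor over an exposure grid per age group with
covariates at stratum means.

## Numerical and design choices

* **Chi-square tests without continuity correction** in descriptive
  tables: the uncorrected Pearson statistic is the one that reproduces
  published two-by-two statistics from their printed counts, and the test
  suite pins one such value to three decimals. Welch's t is the default
  two-sample test (survey strata rarely share variances); the pooled
  Student test is available.
* **Percentages** are displayed rounded half-up to one decimal with the
  stratum size as denominator; full precision is retained in count
  columns.
* **Determinism.** Every stochastic stage takes a seed. `run_pipeline()`
  fans one global seed out via a string-keyed substream scheme
  (`child_seed(seed, stage_name)`), so adding a stage never perturbs the
  randomness of existing stages; two runs with the same config produce
  byte-identical CSVs, and the C++ forest uses its own seeded generator so
  forests and importances are bit-reproducible.
* **Degenerate inputs.** Constant predictors or outcomes give association
  p = 1 (never NaN); groups of one observation report an undefined CI and
  are flagged; empty multiplicity groups are absent from group-mean
  output, never fabricated; exposure ages outside 1-18 are an error.
* **Problem sizes in the shipped tests** are scaled to what the chain
  needs statistically, not to the full published analysis: forests of
  15-100 trees, 2-5 folds with 1-2 repetitions, 200 reshuffles, cohorts
  of 320-2500 (20 000 for convergence checks). The type-I property of the
  add-one estimator is exact by exchangeability at any forest size, so it
  is checked with a deliberately small forest (25 trees, `min_node_size`
  50) under an always-split configuration — with alpha-stopped trees a
  global-null forest is almost always a single root leaf, every
  importance ties at exactly zero, and the empirical p-values degenerate
  to 1.

## Known limitations

Absolute importance values depend on outcome variance, forest shape and
CV geometry; they are comparable within one run, not across studies — the
package's reproduction targets are rankings, signs and significance
behaviour, never published absolute importance or contrast values. The
asymptotic chi-square p-values of the association test are rough below
n of about 10 (the tests quantify this against exhaustive enumeration);
exact small-sample inference is not implemented because node sizes in any
realistic fit are far larger. The interaction models are linear in a
bounded count outcome; count-model alternatives are out of scope.
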