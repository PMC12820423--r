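---
title: "Measuring and decomposing inequality in screening uptake: methods"
author: "screenineq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing inequality in screening uptake: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenineq)
```

## The problem

Clinical breast examination (CBE) is India's recommended breast-cancer
screening modality for women aged 30--65, yet uptake in national survey
data is below one percent and strongly patterned by wealth, education and
caste. Quantifying that patterning, and attributing it to the structural
and access-related factors that mediate it, requires three ingredients:

1. a **concentration index (CI)** — the standard summary of
   socioeconomic-rank-related inequality in a health outcome;
2. a **classifier** for uptake, because with a ~0.5% outcome and strong
   non-linear mediation, a flexible learner captures gradients a linear
   model misses; and
3. an **attribution and decomposition** layer that splits the inequality
   in the model's predicted uptake into per-feature contributions.

`screenineq` implements that pipeline end to end, together with a
synthetic survey generator whose inequality structure is known exactly,
so every stage can be validated against an oracle without access to
registration-gated microdata.

## The synthetic survey generator

`generate_survey()` draws one record per woman from a logistic
data-generating process (DGP):

$$\Pr(y_i = 1 \mid x_i) = \operatorname{logit}^{-1}\Big(\beta_0 +
\textstyle\sum_j \beta_j x_{ij}\Big),$$

with ordinal covariates entering as integer scores, binary covariates as
0/1 indicators, per-state normal offsets, and ethnicity offsets relative
to the caste reference. Three structural choices matter:

* **Exact margins with dependence.** Wealth quintile and education level
  are generated through a Gaussian copula (default correlation 0.5): the
  marginal shares are hit exactly while the two rank variables remain
  realistically correlated.
* **A tunable mediation pathway.** Each binary access covariate (meeting
  a community health worker, distance or transport problems, safe water,
  sanitation, money for treatment, ...) is produced by thresholding
  $d_j m s_i + \sqrt{1 - m^2}\,\varepsilon_{ij}$, where $s_i$ is the
  latent socioeconomic score behind wealth and education, $d_j \in
  \{+1, -1\}$ the loading direction and $m \in [0,1]$ the
  `mediation_strength`. The threshold is the normal quantile of the
  item's target prevalence, so the marginal rates are stable while the
  covariate--wealth correlation scales linearly with $m$; $m = 0$ makes
  access independent of socioeconomic position.
* **Survey weights.** Weights are lognormal (default log-SD 0.5,
  normalised to mean 1) and independent of the covariates, mimicking the
  positive right-skewed design weights of DHS surveys without building a
  household/cluster hierarchy.

The health-seeking **autonomy index** (two binary permission items, sum
score 0--2) and the **perceived quality of care (PQC) index** (four
binary items, sum score 0--4) are built by `build_autonomy_index()` and
`build_pqc_index()` from generated items, and `cronbach_alpha()` measures
their internal consistency exactly as one would on real data.

### The NFHS-like preset

`nfhs_like_preset()` freezes one configuration emulating the NFHS-5
(2019--21) sample of women aged 30--49: wealth shares
29.19/20.60/16.73/16.27/17.21 percent, education shares
31.39/13.54/38.95/16.12, ethnicity shares 74.82/19.75/4.97/0.46, twenty
states, mediation strength 0.5, and coefficients calibrated once so the
weighted uptake is about 0.5% overall, rising from roughly 0.3% in the
poorest quintile to roughly 0.85% in the richest and from roughly 0.25%
(no education) to roughly 1% (higher education). Its Monte-Carlo implied
wealth CI is about +0.22. The calibration targeted only the prevalence
profile and margins; it was fixed before any downstream estimate was
examined and is not revisited.

`implied_ci()` is the package's parameter-recovery oracle: it computes
the concentration index of the *true* event probabilities over a rank
variable on a large fresh Monte-Carlo draw, so its only error is
Monte-Carlo (reported as a 20-batch standard error).

### What the generator does not emulate

No household/cluster sampling structure (hence no design-effect
inflation of variances), no missing data, no informative weights, and no
attempt at the full NFHS joint distribution beyond the stated margins,
copula dependence and mediation pathway. Tests passing on this generator
therefore validate the *estimators and their contracts* — rank
construction, index arithmetic, additivity, recovery of a known gradient
— not distributional fidelity to any real survey.

## Preprocessing, class balance and splits

`encode_features()` maps the table to a numeric matrix: ordinals as
integer scores, nominals (`ethnicity`, `state`) one-hot, with an
invertible `encoding_map` that later lets one-hot blocks be treated as a
single feature.

With a ~0.5% outcome, classifiers degenerate to the majority class, so
the minority class is oversampled by SMOTE (`smote_oversample()`): each
synthetic record is $x + u(x' - x)$, $u \sim U(0,1)$, with $x'$ one of
the $k = 5$ nearest minority neighbours. Numerical choices: neighbour
distances are Euclidean on z-scored columns (so no single covariate
dominates by scale); equidistant neighbours are broken by lowest row
index (determinism); interpolated one-hot blocks are rounded back to the
arg-max level so synthetic records stay decodable; synthetic records get
weight 1 while original records keep their survey weights.

Two pipeline designs are exposed because the weight--SMOTE interaction
is a genuinely open choice. The default oversamples the full table
*before* the train/test split — the design whose near-ceiling test
metrics this package reproduces — which leaks synthetic copies of test
minority cases into training; accuracy and AUROC around 0.995 should be
read as a property of that design, not of generalisation. The
`smote_in_folds` flag instead oversamples inside each training fold
only, giving honest out-of-fold metrics. Both are first-class, tested
paths.

`make_splits()` produces a stratified 80:20 holdout plus stratified
10-fold assignments of the training records, all seeded.

## Classifiers and evaluation

`fit_model()` exposes five families behind one contract — logistic
regression (`glm`), Gaussian naive Bayes (`e1071`), a decision tree
(`rpart`), a random forest (`ranger`) and gradient-boosted trees
(`xgboost`) — each returning calibrated-scale probabilities via
`predict()`. Hyperparameters are fixed, documented defaults (100 trees
for the ensembles, near-unpruned tree with `cp = 1e-4`, unpenalised
logistic): with no tuning protocol to reproduce, fixed defaults beat
guessed searches for reproducibility. Record weights go to the fitting
routine natively where supported; naive Bayes, which has no weight
interface, replicates records in proportion to rounded weights.

The *base* model uses only the three socioeconomic rank factors; the
*final* model adds the access covariates. On mediated synthetic data the
final model's cross-validated AUROC exceeds the base model's (about
0.975 to 0.997 at the preset scale), the signature of an access-mediated
gradient.

`evaluate()` reports accuracy, precision, recall and F1 at a fixed 0.5
threshold plus rank-based AUROC (ties counted one half); metrics with
zero denominators are returned as flagged `NA`s, never silent zeros.
`stability_analysis()` refits each learner across repeated seeded
splits and reports per-metric means and SDs — the guard against
sample-dependent performance.

## Attribution

`shap_values()` computes per-record, per-feature Shapley contributions
under the interventional (marginal-expectation) value function: a
coalition's value is the mean prediction over a background sample with
coalition features set to the explained record's values. One-hot blocks
are one player each, so attributions land on survey variables, not
indicator columns.

Two regimes, both satisfying **local accuracy exactly** (base value +
contributions = prediction, asserted for every record at $10^{-6}$):

* **Exact** (up to 12 players): full $2^p$ coalition enumeration with
  Shapley kernel weights.
* **Permutation sampling** (beyond 12): marginal contributions are
  accumulated along sampled player orderings. Each ordering's
  contributions telescope from the base value to the record's own
  prediction, so additivity is exact by construction and sampling only
  perturbs the split between features.

`brute_force_shapley()` is an independent oracle implementing the
textbook per-feature coalition-weight sum; the exact explainer matches
it to $10^{-6}$ on tree models and both reduce to closed forms on
additive models ($\phi_j = x_j - \bar b_j$).

`permutation_importance()` measures the mean AUROC drop over
within-column permutations (blocks permuted jointly); AUROC is the drop
metric because discrimination is the quantity the pipeline optimises
for. `shap_mean_abs()` gives the mean-|SHAP| importance whose normalised
version (summing to 1) feeds the product-rule decomposition — chosen
over permutation importance there because the published decomposition's
importance column sums to one, which is the mean-|SHAP| convention.

## Concentration indices

`fractional_rank()` orders records by the rank variable and assigns
weighted fractional ranks $R_i = (\text{cum. weight before } i + w_i/2)
/ \sum w$; all records tied at a level share their group's weighted
mid-rank, so the weighted mean of $R$ is exactly one half. The index is

$$CI = \frac{2\,\mathrm{cov}_w(y, R)}{\mu},$$

positive when uptake concentrates among the advantaged.
`ci_convenient_regression()` computes the same number as the WLS slope
of $2\sigma^2_R\, y_i/\mu$ on $R_i$ — algebraically identical to the
covariance form (the package asserts agreement to $10^{-10}$) — and
supplies a heteroskedasticity-robust (HC1) standard error and normal
confidence bounds. `ci_from_predictions()` applies the same machinery to
classifier-predicted probabilities; on synthetic data these
model-predicted indices carry the same sign as, and typically smaller
magnitude than, the observed-outcome indices, because the learner
absorbs part of the gradient into non-linear access effects.

Design choices that were genuinely open:

* **Ethnicity ordering.** The caste ordering behind a signed ethnicity
  CI is not a convention the field fixes. The default orders tribe →
  no-caste → don't-know → caste (most disadvantaged first), the only
  ordering under which a negative ethnicity CI reads as concentration
  among marginalised groups; `rank_spec()` accepts any explicit
  ordering.
* **Confidence level** is a parameter (default 95%); inequality tables
  sometimes report 90% intervals for weakly identified rank variables.
* **Weights in the CI.** Survey weights are used throughout (ranks,
  covariance, regression); unweighted analysis is the special case
  $w_i \equiv 1$.
* **Erreygers correction.** For bounded outcomes the plain CI's
  attainable range depends on the mean; `erreygers_index()` applies
  $E = 4\mu\,CI$ as an option, while defaults report plain indices to
  match standard practice.

Significance stars follow the inequality-literature convention
*** $p<0.001$, ** $p<0.05$, * $p<0.1$.

`chi2_independence()` (Pearson, no continuity correction) and
`bivariate_association()` provide the weighted descriptive
cross-tabulations that precede modelling.

## Two decompositions

**Product rule.** `product_decomposition()` reports, per feature and
rank variable, $D_j = I_j \cdot CI_j$: normalised importance times the
feature's own concentration index over that rank variable
(`feature_ci()`: ordinal features by integer score; nominal features by
prevalence-weighted aggregation of per-level indicator CIs; zero-mean
features mean-shifted by +1 and flagged, since a CI needs $\mu \neq 0$;
constant features return an exact 0 with zero SE). The same importance
vector is reused across rank variables — only the feature CIs change.
The SE of $D_j$ treats $I_j$ as fixed. This rule has **no additivity
guarantee**: the residual $\sum_j D_j - CI(\hat y)$ is always computed
and reported, never hidden. Reported tables round half away from zero
to 3 decimals (4 where a published table prints 4).

**Shapley-rank decomposition.** `shap_rank_decomposition()` computes
$c_j = 2\,\mathrm{cov}_w(\phi_{\cdot j}, R)/\mu_{\hat y}$. Because local
accuracy writes $\hat y_i = \phi_0 + \sum_j \phi_{ij}$ and the weighted
covariance is linear with constants contributing nothing,
$\sum_j c_j = CI(\hat y)$ **exactly** (residual below $10^{-6}$ is a
contract; violation of local accuracy aborts the decomposition). This is
the package's preferred decomposition: it inherits the learner's
non-linearities record by record and is exactly additive by
construction.

`bootstrap_uncertainty()` supplies nonparametric-bootstrap SEs and
percentile bounds for any pipeline statistic (records resampled with
their weights; failed replicates dropped and counted).

### The published worked example

`decomposition_reference()` ships the 60-row published decomposition
table (three rank variables × twenty features) as a plain-text fixture.
The test suite recomputes every $D_j$ from the printed $(I_j, CI_j)$
pairs: 56 of 60 printed cells reproduce exactly at the printed rounding.
Four cells are internally inconsistent with their own printed factors
(for example $0.138 \times (-0.067) = -0.009$ against a printed
$-0.001$ whose own printed bounds are $[-0.010, -0.009]$, and
$0.060 \times 0.2583 = 0.0155 \to 0.015$ against a printed $0.016$,
presumably rounded from unrounded factors); those rows are flagged in
the fixture and the tests assert the recomputed value instead of the
typo.

## Problem sizes and runtime choices

The package validates at the study scale where it matters and small
scale elsewhere: parameter recovery and the base-vs-final AUROC
comparison run on 50,000-record draws (five seeds for recovery; the
Monte-Carlo oracle uses 200,000 draws); estimator-equivalence and metric
oracles use hundreds of records over many random repetitions; the
Shapley oracle comparison uses 8 grouped features × 50 records × a
25-row background, the largest size at which $2^p$ enumeration is
comfortable. Pipeline smoke tests run at 2,500 records with reduced
explanation samples. At 0.5% prevalence the sampling SE of a single
50,000-record wealth CI is ≈ 0.028, so recovery is asserted on the
five-seed mean (SE ≈ 0.0125), with the sign checked in every seed.

## Known limitations

* The default resampling design (oversample before splitting) inflates
  test metrics by construction; use `smote_in_folds` for honest
  generalisation estimates.
* Product-rule contributions are a heuristic: they do not sum to the
  total CI, and their SEs condition on the importance weights.
* Sampling-mode SHAP splits are Monte-Carlo estimates; only additivity
  is exact. Increase `n_perm` for tighter per-feature values.
* The feature CI of a nominal variable depends on the chosen
  aggregation (prevalence-weighted per-level indices here); a different
  collapse rule yields different — equally defensible — numbers.
* Generator realism is deliberately limited (see above); conclusions
  about real surveys require real microdata.
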