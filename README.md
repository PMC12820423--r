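# screenineq

Measuring and decomposing socioeconomic inequality in the uptake of a
rare preventive health service — clinical breast examination (CBE) among
women aged 30–49 in NFHS/DHS-style survey microdata — with
machine-learning prediction and Shapley-value attribution.

The package is for health-equity researchers and biostatisticians who
want to go beyond a single concentration index: to predict uptake from
socioeconomic and healthcare-access covariates, quantify how much of the
wealth/education/ethnicity gradient the model reproduces, and attribute
that gradient to individual structural factors. Because the motivating
microdata (NFHS-5) are registration-gated, the package includes a
synthetic survey generator with a *known* inequality structure, so every
estimator ships with an oracle it is tested against.

## The statistics at the core

For outcome $y$ with weighted mean $\mu$ and weighted fractional ranks
$R$ over a socioeconomic rank variable (wealth quintile, education
level, ethnicity; ties share their group's weighted mid-rank):

* **Concentration index**: $CI = 2\,\mathrm{cov}_w(y, R)/\mu$, also
  obtained as the slope of the convenient regression
  $2\sigma_R^2\, y_i/\mu = \alpha + CI \cdot R_i + \varepsilon_i$
  (WLS, HC1 robust SE). Positive = concentrated among the advantaged.
* **Model-predicted CI**: the same index computed on classifier-predicted
  probabilities $\hat y$ — a non-linear, mediation-aware counterpart of
  the observed-outcome index.
* **Product-rule decomposition**: per feature $j$,
  $D_j = I_j \cdot CI_j$ (normalised mean-|SHAP| importance × the
  feature's own concentration index over that rank variable).
* **Shapley-rank decomposition**:
  $c_j = 2\,\mathrm{cov}_w(\phi_{\cdot j}, R)/\mu_{\hat y}$ over SHAP
  contribution columns $\phi$; by local accuracy
  $\sum_j c_j = CI(\hat y)$ *exactly*.

Around these sit the supporting stages: Levesque-framework access
indices with Cronbach's α, SMOTE class balancing, five classifier
families (logistic, naive Bayes, decision tree, random forest, gradient
boosting) under one contract with stability analysis, permutation
importance, and an exhaustive-enumeration Shapley oracle.

## Worked example

```r
library(screenineq)

# 20,000 synthetic women from the NFHS-like preset
tab <- generate_survey(nfhs_like_preset(20000, seed = 1))
round(100 * tapply(tab$y, tab$wealth_quintile, mean), 2)
#>    1    2    3    4    5
#> 0.15 0.50 0.54 0.86 0.76

# observed wealth-related inequality in uptake
R <- fractional_rank(tab$wealth_quintile, tab$w, rank_spec("wealth_quintile"))
ci_convenient_regression(tab$y, R)
#> Concentration index (observed-conventional) by wealth_quintile: 0.2620***
#>   SE 0.0615  95% CI [0.1414, 0.3826]  (n = 20000, mu = 0.004953)
```

Uptake rises from 0.15% in the poorest quintile to ~0.8% in the richest,
and the concentration index of +0.26 (SE 0.06) says uptake is strongly
concentrated among wealthier women ("pro-rich").

The full pipeline — encode, oversample, split, fit, attribute, estimate
and decompose — is one call:

```r
res <- run_pipeline(run_config(n_records = 20000, seed = 1, n_splits = 3,
                               k = 5, n_explain = 100, n_background = 60,
                               n_perm = 15))
res
#> Screening-inequality pipeline result
#>   base-model CV AUROC 0.984 -> final-model CV AUROC 0.997
#>    rank_variable observed_ci predicted_ci
#>  wealth_quintile  0.26199359   0.15115118
#>  education_level  0.28236591   0.30054183
#>        ethnicity  0.04974718   0.02634764
```

The jump from base (rank factors only) to final (plus access covariates)
cross-validated AUROC signals the access-mediated pathway; the
decision-tree-predicted wealth CI (0.151) is attenuated relative to the
observed one (0.262), the usual signature of non-linear mediation. The
exactly additive Shapley-rank decomposition then names the mediators:

```r
res$shap_decomposition$wealth_quintile
#> Shapley-rank CI decomposition by wealth_quintile (total CI 0.2119, residual -2.8e-17)
#> ... money_for_treatment 0.0450, education_level 0.0758, met_chw 0.0327, ...
#> ... distance_problem -0.0042, transport_problem -0.0029 (pro-poor offsets)
```

With `out_dir` set, `run_pipeline()` writes every table (bivariate
associations, metrics, stability, importance, concentration indices, one
decomposition table per rank variable) as CSV plus a consolidated
`results.json`. A thin command-line wrapper lives at
`inst/scripts/run-pipeline.R`.

The published 60-row decomposition table whose arithmetic the package
reproduces is available as `decomposition_reference()`.

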