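# hfmdgbt

Gradient boosted tree (GBT) risk analysis for **severe hand-foot-mouth
disease (HFMD)** in children. Severe HFMD — enteroviral infection
complicated by neurological or cardiorespiratory involvement — can be
anticipated from admission clinical measurements and early MRI findings.
This package provides the complete modelling chain for quantifying which
predictors matter and how they interact, for biostatisticians and
epidemiologists working on paediatric infectious-disease severity:

- a from-scratch boosting core for binary outcomes (Bernoulli deviance)
  with per-split squared-error improvement bookkeeping
  (`fit_gbt()`, `gbt_config()`, `select_n_trees()`);
- Friedman **relative importance** — per-variable summed squared split
  improvements, averaged over trees, normalised so the maximum is 100
  (`relative_importance()`);
- partial dependence and the Friedman–Popescu pairwise **H-statistic**,
  `H in [0, 1]`, the share of two-way partial-dependence variance not
  explained additively (`partial_dependence()`, `h_statistic()`);
- **outcome-permutation tests** with the add-one rank rule and
  percentile-**bootstrap CIs** for H (`permutation_test_importance()`,
  `permutation_test_h()`, `bootstrap_ci_h()`);
- stratified 10-fold **cross-validation** with optional majority-class
  down-sampling, accuracy/sensitivity/specificity and rank-statistic AUC
  (`make_folds()`, `downsample_training()`, `cross_validate()`);
- a **synthetic cohort generator** calibrated to published mild/severe
  HFMD group marginals (345 mild / 185 severe; flag prevalences; age and
  temperature moments), with a mechanistic logistic mode for planting
  known main effects and pairwise interactions (`cohort_spec()`,
  `generate_cohort()`, `derive_clinical_flags()`);
- descriptive group-comparison statistics reproducing published-table
  conventions (`chi_square_2x2()`, `percent_of_group()`,
  `summary_t_test()`, `cohort_group_table()`);
- end-to-end orchestration with a provenance manifest
  (`run_full_analysis()`).

## The model

The fitted predictor is additive on the log-odds scale,

    F_M(x) = F0 + nu * sum_{m=1..M} T_m(x),        P(severe | x) = plogis(F_M(x))

where `F0` is the log-odds of the training prevalence and each depth-limited
regression tree `T_m` is fitted to the pseudo-residuals `y - p` with terminal
values replaced by the one-step Newton estimate `sum(y - p) / sum(p(1 - p))`.
Interaction strength between predictors j and k is

    H^2 = sum_i [F_jk(x_ij, x_ik) - F_j(x_ij) - F_k(x_ik)]^2 / sum_i F_jk(x_ij, x_ik)^2

over centred partial dependences at the observed points; `H = sqrt(H^2)`.
See `vignettes/severe-hfmd-gbt-methods.Rmd` for assumptions, defaults and
design choices.

## Worked example

```r
library(hfmdgbt)

# calibrated synthetic cohort: 345 mild / 185 severe
cohort <- generate_cohort(cohort_spec(seed = 3))
mf <- cohort_model_frame(cohort)          # 14 predictors + binary outcome

ens <- fit_gbt(mf, gbt_config(n_trees = 100, shrinkage = 0.1, seed = 5))
head(relative_importance(ens), 3)
#>          variable       raw  relative
#> 1     elevated_wbc 0.9740817 100.00000
#> 2  mri_spinal_cord 0.7033851  72.21007
#> 3  fever_ge_3_days 0.3080286  31.62246

feats <- mf[, setdiff(names(mf), "outcome")]
h_statistic(ens, "elevated_wbc", "mri_spinal_cord", feats)
#> H(elevated_wbc, mri_spinal_cord) = 0.2378

cv <- cross_validate(mf, gbt_config(n_trees = 100, shrinkage = 0.1),
                     k = 5, balance = "downsample", seed = 2)
cv
#> 5-fold cross-validation (balance: downsample, threshold 0.50)
#>   accuracy 0.860  sensitivity 0.843  specificity 0.870  AUC 0.938 (pooled 0.935)
```

Elevated WBC count dominates the importance ranking (scaled so the top
variable is 100), spinal-cord involvement comes second, and the
down-sampled 5-fold AUC of 0.94 says the 14 admission/MRI predictors
separate severe from mild cases well on this cohort. The H-statistic of
0.24 means about a quarter of the joint partial-dependence variation of
the WBC/spinal-cord pair is non-additive.

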