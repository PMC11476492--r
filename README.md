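# perisk

Preeclampsia (PE) risk prediction from routine clinical variables and
placental growth factor (PlGF), with bi-platform assay calibration,
class-aware missing-data imputation, and imbalance-aware evaluation.

## The problem

PE is a pregnancy syndrome of new-onset hypertension with organ involvement;
low circulating PlGF is its best single biomarker. Screening cohorts are
awkward for off-the-shelf machine learning in four ways this package
addresses head on:

1. **Two assay platforms.** PlGF may be measured on SiMoA or on Elecsys;
   the scales are not interchangeable, and typically only a couple of dozen
   paired samples exist for calibration. `perisk` fits pools of tiny
   1–2–1 sigmoidal regression networks under repeated 3-fold
   cross-validation in both directions and deploys the *median-performance*
   model of the better direction: with a pool of MSEs
   `P_1, …, P_{rounds·folds}`, the deployed model is the one achieving
   `P_median = median{P_i}` — neither a lucky nor an unlucky split.
2. **Missing data (~1/4 of cells).** Training records carry labels, so
   independent features are imputed by the *intra-class* median; unlabeled
   test records use the overall training median. Two feature pairs are
   strongly dependent — (pre-pregnancy weight, current weight) and
   (diastolic, systolic pressure) — and a missing member is instead
   predicted from the present one through relation networks fitted on
   complete pairs (per gestational stratum for the weight pair). Only when
   both members are missing do medians apply.
3. **Case–control imbalance.** Classifiers expose a continuous risk score;
   the decision cut is searched on a grid by out-of-fold F1 rather than
   fixed at 0.5.
4. **Small cohorts.** Performance is reported as the median ± deviation over
   repeated k-fold cross-validation, with all preprocessing refit inside
   every training fold.

A synthetic-cohort generator with the same statistical structure (class
shifts, dependent pairs, platform transfer, MCAR missingness) makes every
stage testable without access to any clinical data. It also powers
replications of three directional findings: calibrated bi-platform fusion
beats mono-platform training; non-early-pregnancy records lift
early-pregnancy prediction; and testing on augmented (SMOTE-style)
partitions inflates metrics that vanish on real-only test partitions — the
"virtually high" performance phenomenon.

## Worked example

```r
library(perisk)

spec   <- cohort_spec(n_cases = 30, n_controls = 90, seed = 1)
cohort <- generate_cohort(spec)
table(cohort$label)
#> control    case
#>      90      30            # ~26% of maskable cells are missing

pairs <- generate_calibration_set(24, seed = 1)
cal   <- fit_calibrators(pairs, rounds = 20, folds = 3, seed = 1)
#> direction elecsys_to_simoa, MSE forward 40.6, backward 23.1
```

The backward (Elecsys → SiMoA) pool has the smaller median MSE, so SiMoA is
the reference scale and Elecsys values are mapped through the selected
network — the configuration a screening service would deploy.

```r
cfg <- predictor_config("rf", list(ntree = 100), seed = 1)
res <- repeated_cv(cohort, cfg, rounds = 3, folds = 5, seed = 1)
#> AUC_ROC 0.766 ± 0.005 | TPR 0.333 | FPR 0.044 | F1 0.435 | error 0.217
```

At the default 0.5 cut only a third of cases are caught (TPR 0.333) despite
a healthy AUC — the imbalance problem. Searching the cut by out-of-fold F1:

```r
optimize_threshold(cohort, cfg, rounds = 3, folds = 5, seed = 1)
#> optimal threshold: 0.26 ± 0.0200
```

Feature importance from the forest recovers the clinical picture (PlGF
deficit and blood-pressure elevation dominate):

```r
enc <- encode(cohort)
enc <- fit_normalizer(impute_train(enc, fit_imputer(enc, seed = 1)))
head(feature_importance(train_model(enc, cfg)), 5)
#>   plgf  diastolic_pressure  map  systolic_pressure  pre_pregnancy_weight
#>  0.193               0.129 0.123             0.100                0.071
```

End-to-end experiment harnesses (five of them: `model_comparison`,
`bi_platform_fusion`, `threshold_search`, `early_prediction`,
`augmentation_study`) write JSON + aligned-text reports:

```r
run_experiment("bi_platform_fusion", out_dir = "reports")
```

or from the shell:

```sh
Rscript inst/cli/perisk.R experiment --name bi_platform_fusion --out reports --seed 0
```

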