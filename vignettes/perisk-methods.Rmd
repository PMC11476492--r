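---
title: "perisk: models, numerical choices and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{perisk: models, numerical choices and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`perisk` implements a complete preeclampsia (PE) risk-prediction pipeline
for cohorts in which placental growth factor (PlGF) is measured on either of
two immunoassay platforms (SiMoA, Elecsys): feature encoding, dual-strategy
missing-data imputation, cross-platform PlGF calibration, imbalance-aware
classification with output-threshold search, repeated and modified
cross-validation protocols, and interpolation-based minority oversampling
with a leakage-aware evaluation. Because the clinical data the design
targets are private, the package ships a synthetic-cohort generator that
reproduces the *structure* of such data; every empirical statement in this
vignette is one the test suite computes.

## Feature encoding

Fourteen collected variables expand to a fixed 22-column design matrix:
age; five one-hot ethnicity indicators (Han, Uygur, Kazak, Hui, other);
height; pre-pregnancy and current weight; pre-pregnancy BMI, current BMI
and BMI increase rate; five history codes (pregnancy, fertility, PE,
family-PE, hypertension); gestational day; diastolic and systolic pressure;
mean arterial pressure (MAP); and PlGF.

Choices the source design leaves open, fixed here once:

* **MAP** = (SBP + 2·DBP)/3, the standard clinical estimate (the weighted
  average over a cardiac cycle, two thirds of which is diastole).
* **BMI increase rate** = (current BMI − pre-pregnancy BMI) /
  pre-pregnancy BMI, i.e. a relative gain; the name alone does not fix a
  formula, and a relative rate is unit-free across statures.
* **Gestational day** = 7·weeks + days, used instead of gestational week.
* Unknown ethnicity levels map to *other* with a warning; non-positive
  height is a record-level error.

Min–max normalization rescales every feature **except PlGF** to [0, 1]
using training extremes. Test values outside the training range are clipped
to [0, 1] (the alternative — extrapolating outside the unit interval — would
hand the classifiers values no training column ever contained). Constant
training columns are left unscaled with a warning. Normalization (and the
imputation model) is refit inside **every** cross-validation training fold;
fitting it once globally would leak held-out information, and the per-fold
choice is the conservative resolution of a protocol the source leaves
unstated.

## Missing-data imputation

Two strategies by feature type, two by data role:

* **Independent features, training role**: intra-class median — the median
  over non-missing training values *of the record's own class*. Blood
  pressure is genuinely class-dependent, so an over-class median would bias
  imputed cases toward controls.
* **Independent features, test role**: overall training median (test
  records have no label, and must not behave as if they did; the test-time
  transform provably never consults a label).
* **Dependent pairs**: (pre-pregnancy weight, current weight) and
  (diastolic, systolic pressure). A missing member with a present partner is
  predicted from it by a relation network — a 1-input, 2-sigmoidal-hidden,
  1-linear-output perceptron fitted on rows where both members are present.
  Training-role networks are class-specific; test-role networks are pooled
  (label-free) refits, resolving the ambiguity of reusing class-specific
  models on unlabeled records. Only when both members are missing do
  medians apply.
* The weight pair is additionally stratified over five gestational
  intervals (11–13+6, 14–18+6, 19–23+6, 24–28+6, 29–33+6 weeks), because
  current weight grows with gestational age; the pressure pair is not
  gestationally stratified. Records outside the intervals use the nearest
  stratum.

Numerical details: the median of an even count is the mean of the two
middle order statistics; a relation-network cell needs at least
`min_pairs = 10` complete pairs, otherwise it falls back to medians (below
ten points a 9-parameter network is not meaningfully constrained);
imputation operates on encoded but pre-normalization values, and the
derived features (BMIs, BMI increase rate, MAP) are recomputed from their
imputed parents so they stay internally consistent. A feature missing in an
entire class falls back to the overall median with a warning. PlGF, which
has no partner, is treated as independent.

The relation networks standardize input and target (z-scores) and train
full-batch by BFGS with analytic gradients; `n_starts` random restarts keep
the best training loss (a 9-parameter sigmoid network can stall in a
shallow local optimum — the tests use extra restarts where they assert
sub-percent recovery of a noiseless relation).

## PlGF calibration

With only ~24 paired samples, a single train/validation split selects an
unstable regressor. Instead, for each direction (SiMoA→Elecsys,
Elecsys→SiMoA) the package trains `rounds × folds` networks (default
100 × 3 = 300) of the same 1–2–1 architecture, each scored by held-out MSE,
and deploys the model whose MSE equals the pool median — the
median-performance model, robust against both lucky and unlucky splits.
The direction with the smaller selected-model MSE fixes the **reference
platform**: values measured there pass through unchanged; values from the
other platform are mapped through the selected network.

Open points fixed here:

* MSEs are computed on the **raw pg/mL scale** (both directions are
  compared on their own output scales; standardized MSEs would hide the
  asymmetry the direction choice is meant to expose). The identity-transfer
  test normalizes by the output variance before asserting near-zero error,
  making it scale-free.
* The median of an **even** pool is the lower-middle rank `n/2` — a single
  concrete model must be returned, and of the two middle models the better
  one is kept. Ties keep the earliest pool index.
* A direction tie prefers Elecsys→SiMoA, the configuration deployed in the
  motivating study; the package nevertheless *computes* the comparison on
  every dataset rather than hard-coding it.
* Inputs/targets are standardized before fitting (a sigmoid layer cannot
  operate on raw pg/mL scales) and back-transformed for prediction.

## Risk prediction

All classifiers expose a continuous risk score in [0, 1]; a record is
called a case iff its score ≥ the threshold.

* **Random forest** (primary): bootstrap-aggregated CART grown by a small
  compiled engine; `floor(sqrt(d))` candidate features per **split**,
  node size 1, 500 trees by default. Importance is the impurity decrease
  summed over all splits, normalized to 1, ties broken by column order.
* Comparators, reproduced structurally: a logistic-output perceptron, a
  linear squared-hinge soft-margin machine (no kernel machinery is
  available in the target environment), gradient boosting with
  Newton-leaf updates (depth 3, shrinkage 0.1, L2 = 1), and discrete
  AdaBoost on stumps. Hyperparameters are pinned in
  `predictor_config()` defaults.

**Threshold search**: per cross-validation round, out-of-fold scores are
pooled and the grid threshold (step 0.01 over [0.01, 0.99]) maximizing F1
is recorded; ties break to the smallest threshold, the most sensitive cut
at equal F1 — the clinically safer side. The search is summarized as median
± deviation across rounds, treating the optimum as a per-round statistic
(a single global threshold would hide its sampling variability).

## Evaluation

Threshold metrics derive from the pooled out-of-fold confusion matrix of a
round (pooling, rather than averaging fold-level metrics, keeps tiny
single-digit-case folds from dominating). AUC_ROC is the Mann–Whitney
statistic with ties counting one half; AUC_PRC is step-wise average
precision without interpolation (interpolated precision–recall areas are
optimistically biased on imbalanced data). TNR = 1 − FPR and FNR = 1 − TPR
hold identically by construction and are asserted, not derived twice.

* **Deviation** is the median absolute deviation about the median (no
  consistency constant): a spread measure "calculated from the median",
  robust in the same sense as the location statistic it accompanies.
* **Micro-F1** is the F1 of the round-averaged confusion matrix; **macro-F1**
  the harmonic mean of round-averaged precision and recall. Both collapse
  to plain F1 for a single round, and both aggregate across *rounds* —
  matching presentations that print single micro/macro values without a ±.
* Fold assignment is simple random by default (a `stratified` option
  exists but is off, preserving the plain protocol); assignments that
  would leave a training fold single-class are redrawn.

Two modified protocols:

* **Early-enriched CV**: folds partition only the early-pregnancy set
  (gestational age 11w+0d–13w+6d; the ambiguous shorthand "11 − 3 + 6
  weeks" is read as 11 through 13+6, the standard first-trimester screening
  window). Each training fold is 9/10 of the early set plus *all* non-early
  records; each test fold is early records only. With an empty non-early
  set the protocol reduces exactly to standard repeated CV, by
  construction.
* **Augmented CV with real-only test partitions**: the real set is
  preprocessed once, oversampled as a whole, and folded; each held-out part
  is scored twice — over all rows and over its real rows only. Augmenting
  *before* splitting deliberately reproduces the leaky protocol that
  creates the "virtually high" phenomenon (synthetic rows are convex
  combinations of real rows that end up in training folds); a leakage-safe
  variant (`safe = TRUE`) augments inside training folds only and is off by
  default because the point of the experiment is to expose the leak.

## Minority oversampling

Plain SMOTE (interpolation between a minority row and one of its k = 5
nearest minority neighbours) and a cluster-aware variant (k-means on the
minority rows, `round(sqrt(n))` clusters by default, interpolation within a
cluster) are implemented natively; other published variants plug in through
the function-augmenter interface. The target is
`minority = round(1.2 × majority)` after augmentation — the study's "ratio
of 1.2 cases to controls" read literally, cases overshooting controls.
Synthetic rows never leave the minority bounding box, never carry the
majority label, and are always flagged by origin.

## The synthetic world

The generator states one world and the tests live in it:

* Default shapes mirror the study's five dataset roles (e.g. 145 cases /
  559 controls for the SiMoA set; 169/525 Elecsys; 65/190 first-trimester;
  130/892 test), with ~1/4 of maskable cells missing completely at random
  (label, platform and gestational age are never masked).
* Continuous features are truncated normals in physiologic ranges; history
  codes Bernoulli/binomial with class-dependent rates; ethnicity
  multinomial over five levels.
* Class shifts (case − control): PlGF −150 pg/mL (placental dysfunction),
  diastolic +12 mmHg (with systolic following its relation), pre-pregnancy
  weight +6 kg (≈ +2.3 BMI units at 1.60 m), age +1 y. Magnitudes are
  chosen to be clinically plausible and large enough that a forest on a
  few hundred records detects them — the regime the pipeline targets.
* Dependent pairs are generated from known ground truth: systolic =
  1.1·diastolic + 38 + noise (clamped to ≥ diastolic + 2); current weight =
  pre-pregnancy weight + 0.045 kg/day of gestation + noise (≈ 10 kg at
  33 weeks).
* PlGF is generated on the SiMoA-native scale; Elecsys-tagged records
  report `1.3·s + 10 + noise`, so calibration ground truth is known and the
  better direction is genuinely the backward one.
* The paired calibration set defaults to 24 samples.

What the generator does **not** emulate: the real cohort's covariance
structure beyond the stated shifts, informative missingness, gestational
drift of PlGF itself, platform-specific measurement-error shapes, or
diagnostic adjudication. A green directional test therefore establishes
that the *pipeline* reproduces a phenomenon in a world where it must hold —
not that the phenomenon's published effect sizes are recovered; the
original performance tables come from a private cohort and are not
reproduced numerically anywhere in this package.

## Reduced scales

The paper-scale protocol (100 rounds of 10-fold CV; 100×3 calibration) is
available through configuration, but defaults and tests run at desk scale:
experiments default to 10 rounds; acceptance tests use 20 seeded replicates
with 1×4-fold CV, forests of 40–60 trees, cohorts of 48–160 records, and
20×3 calibration rounds. These reductions trade variance, not correctness:
every structural and oracle check is exact at any scale.

## Known limitations

* The relation networks and calibrators are tiny by design; they cannot
  represent non-monotone transfers (none are expected between these
  platforms).
* The CART engine samples candidate features per split like a classical
  forest but grows depth-limited (30 levels) trees; on degenerate
  constant-feature nodes it stops rather than splitting randomly.
* `augment()` interpolates one-hot and count columns like any numeric
  column (as matrix-level SMOTE does); a categorical-aware variant is out
  of scope.
* Config files are JSON rather than YAML: the target environment
  guarantees a JSON parser but not a YAML one.
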