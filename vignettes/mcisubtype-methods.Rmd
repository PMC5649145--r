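---
title: "Classifying MCI subtypes from morphometric MRI features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying MCI subtypes from morphometric MRI features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mcisubtype)
library(dplyr)
```

## The problem

Mild cognitive impairment (MCI) is a transitional state between normal
cognition and dementia, and its two clinical subtypes — amnestic (aMCI,
memory-predominant) and non-amnestic (naMCI) — are thought to differ in
etiology and outcome. This package implements a complete, leakage-safe
machine-learning pipeline for separating the three diagnostic groups (CN,
aMCI, naMCI) pairwise from tables of MRI-derived morphometric measurements:
per-subject scalar features in five families (sulcal measures, regional
cortical thickness, regional cortical gray-matter volume, subcortical
volumes, and regional white-matter-hyperintensity volumes; 12 + 68 + 68 +
14 + 16 = 178 features per timepoint). With scans at baseline and a 2-year
follow-up ("wave-2"), a longitudinal feature set of per-feature means and
changes doubles the width to 356.

Three difficulties shape the design:

1. **p ≫ n.** A community cohort contributes ~184 subjects against 178–356
   features, so naive wrapper selection has enormous variance.
2. **Class imbalance.** The affected groups are small (42 aMCI, 27 naMCI
   against 115 CN at wave-2 in the reference design), which biases both
   classifiers and accuracy as a metric.
3. **Double-dipping.** With so few subjects it is easy to let test data leak
   into feature selection and inflate accuracy; the pipeline's fold contract
   forbids it structurally.

## The pipeline

Per cross-validation fold the training half goes through four stages, and
the test half is only ever transformed and predicted:

**0–1 scaling.** All features are min-max scaled with training-set minima
and maxima (`fit_scaler()`/`apply_scaler()`); test values reuse the training
statistics and may legitimately fall outside [0, 1]. Scaling first matters
because the feature units are incommensurate (mm vs mm³): Euclidean
clustering or margin-based classification on raw values would be dominated
by the large-unit volume families. Constant training columns map to 0.

**Hybrid rebalancing** (`rebalance()`). The minority class of size $N_s$ is
repeatedly clustered into $k = \max(1, \lfloor N_s/3\rfloor)$ k-means
clusters and the $k$ centroids are appended as synthetic samples, centroids
and originals together feeding the next iteration, until the minority
reaches $\lceil \tfrac{2}{3} M\rceil$ where $M$ is the original majority
size (overshoot from the floor recursion is kept, so 27 vs 115 follows
27 → 36 → 48 → 64 → 85). The majority is then reduced by k-medoids (PAM),
whose cluster centers are actual data points, to the final minority size.
The undersampling target is not uniquely determined by the 2/3 stopping
rule alone; we default to a balanced output (`undersample_target =
"balanced"`) because undersampling to $\tfrac{3}{2}$ of the minority would
be a near no-op once the minority has already reached $\tfrac{2}{3}M$. Both
alternatives remain available (`"ratio_3_2"`, `"none"`).

**Stability feature selection** (`run_subsampling()`,
`choose_optimal_set()`). The (rebalanced) training set is subsampled 100
times; each iteration splits it into stratified halves A and B, ranks
features on A by the two-group ANOVA F statistic keeping the top 100, and
reduces those candidates to 20 on B by SVM recursive feature elimination.
Per-feature selection frequencies over the 100 iterations (each in
[0, 100]) rank the features. The final set size $N_f \in \{10, 9, 8\}$ is
chosen by refitting an RBF-kernel SVM on the top-$N_f$ features over 5
stratified 50/50 splits of the training data and picking the $N_f$ with the
best mean *recall* of the positive class — recall rather than accuracy, so
the choice is not dominated by the majority class. The final set never
exceeds 10 features. Selected features are additionally summarized by
two-sided Welch t-tests.

**Weighted soft voting** (`fit_voting()`, `majority_predict()`). Three
components — an RBF-kernel SVM, L2-regularized logistic regression, and a
random forest, all at library-default hyperparameters — are fitted on the rebalanced,
dimension-reduced training set, and their class probabilities are combined
as $p = \sum_c w_c p_c / \sum_c w_c$ with weights 1:4:1 (SVM:LR:RF). The
whole of the above (rebalance → select → fit) runs three times per fold
with independent seeds, and the three voting models decide test labels by
majority vote; the ROC score for AUC is the mean of the three combined
positive-class probabilities, since a majority label alone defines no
ranking.

**Evaluation** (`run_experiment()`). Ten stratified shuffle-split
("Monte Carlo") cross-validation iterations at a 9:1 train:test ratio;
accuracy, sensitivity, specificity and rank-based AUC (ties counted ½) are
averaged over iterations, with metrics undefined in a single-class test
fold recorded as missing and excluded from means. Selection frequencies are
summed over the 3 resamples × 10 iterations, giving a per-feature maximum
of 3 × 100 × 10 = 3,000; the top-10 features by aggregated frequency form
the ranked-biomarker report with Welch p-values computed on the full
two-group sample.

## Design choices where the procedure was under-determined

Several points are deliberate package decisions, fixed once and
config-exposed where reasonable:

- **RFE's internal estimator is a linear SVM.** Elimination needs
  per-feature weights ($w_j^2$ ranking), which an RBF kernel cannot supply;
  the RBF kernel is used where probabilities or recall-validation are
  computed, not inside RFE. The elimination step defaults to 1 feature per
  refit; `rfe_step` accepts a fraction of the current feature count for
  large runs (the package's own test and acceptance runs use 0.5).
- **Stratification.** Random half-splits and the $N_f$-validation 50/50
  splits are stratified by class; unstratified halves of a 27-subject
  minority can lose a class entirely.
- **Positive class.** The clinically affected (and minority) class: aMCI in
  aMCI-vs-CN, naMCI in naMCI-vs-CN and naMCI-vs-aMCI. This orients recall,
  sensitivity and AUC.
- **Tie-breaks.** Equal mean recall across $N_f$ goes to the smaller set
  (parsimony); equal selection frequency between features goes to the
  larger full-training ANOVA F. Constant features receive $F = 0$ rather
  than an error.
- **Scaling before resampling.** The scaler is fitted on the full training
  set, then resampling, selection and model fitting all operate in scaled
  space.
- **Regularized logistic component.** Rebalanced, dimension-reduced
  training sets are frequently completely separated, under which an
  unpenalized logistic fit diverges to an arbitrary separating hyperplane
  with saturated 0/1 probabilities — observable as chance-level specificity
  next to near-perfect AUC. The logistic component is therefore ridge
  (L2) logistic regression at cost C = 1 (`glmnet`, `lambda = 1/(C n)`),
  the conventional default parameterization of this estimator in the
  machine-learning stacks this pipeline mirrors.
- **Probability calibration.** Soft voting needs probabilities from all
  three components. The SVM's decision values are mapped through a
  Platt-style sigmoid (a binomial GLM fitted on the training decision
  values). We calibrate on the training data directly rather than via
  internal cross-validation because the latter (as implemented in libsvm)
  draws from a non-reseedable random stream and would break the package's
  bit-reproducibility guarantee; on near-separable training sets the
  sigmoid simply saturates.
- **Longitudinal convention.** `change = wave2 − baseline` (atrophy is
  negative), `mean` is the arithmetic mean, and longitudinal labels are the
  wave-2 diagnoses, which are the diagnostic ground truth of the design.
  Subjects present at only one timepoint are rejected, and missing feature
  values are not imputed — QC-failed scans are excluded upstream.
- **Seeding.** One master seed spawns child seeds per fold, and per
  resample within folds, so changing `n_resamples` does not perturb fold
  membership. Every stochastic step (half-splits, k-means++ seeding, random
  forest growth) draws from a seed in this tree; PAM is deterministic and
  needs none. Identical seeds give bit-identical reports.

## The synthetic cohort generator

The study cohort is not public, so `generate_cohort()` provides
known-ground-truth data with the statistical structure the analysis
assumes. Per subject $i$, feature $j$, on a standardized latent scale:

$$z^{(1)}_{ij} = \delta_{g(i),j} + u_{ij}, \qquad
  z^{(2)}_{ij} = \delta_{g(i),j} + s_{g(i),j} + \rho\, u_{ij} +
  \sqrt{1-\rho^2}\, u'_{ij}$$

where $g(i)$ is the diagnostic group, $\delta$ the planted cross-sectional
shifts (Cohen's d units), $s$ the planted 2-year slopes, and $\rho$ the
within-subject correlation between timepoints (default 0.8, a typical
test-retest figure for morphometrics). The noise $u$ carries an optional
within-family equicorrelation (default 0.3) standing in for the unknown
anatomical covariance: correlated nuisance features are precisely what
stresses a selection procedure. Observed values are affine family
transforms $x = \mu_f + \sigma_f z$ (thickness ≈ 2.5 ± 0.16 mm, gray-matter
volumes ≈ 11,000 ± 1,400 mm³, …), so downstream 0–1 scaling is non-trivial.

Defaults follow the reference design: wave-2 group sizes 115/42/27 and the
178-feature five-family layout. The default planted pattern places moderate
atrophy (d = −0.8, slope −0.4/2y) for aMCI on subcortical and
temporal/frontal-like thickness features, and smaller scattered shifts
(d = −0.5, slope −0.3/2y) for naMCI across all families, mirroring the
amnestic-focal vs scattered atrophy distinction; CN carries no effect.

Three fixtures freeze useful corners: `"separable"` (90 subjects, 150
features, 5 planted features at |d| = 2.5 with opposite signs for aMCI and
naMCI — linearly separable by a hard-margin SVM, though with family-correlated
noise its aMCI-vs-CN Bayes error is small but nonzero), `"null"` (80
subjects, 60 features, no effects), and `"imbalanced"` (the study's
115/42/27 sizes).

**What the generator does not emulate:** realistic spatial covariance of
cortical anatomy beyond the equicorrelation block, scanner/site effects,
non-Gaussian tails (e.g., skewed WMH loads), and missing data. Passing
recovery tests on this generator therefore shows the machinery works under
the assumed statistical structure, not that the reported biomarkers of any
real cohort would be reproduced.

## Numerical choices and degenerate inputs

- k-means uses k-means++ seeding with the run seed, 300 iterations maximum;
  if a minority set has fewer distinct points than requested clusters, the
  distinct rows are recycled as centroids so the size recursion is
  unaffected (three identical points oversample to copies of that point).
- PAM undersampling at `target = n` is the identity; `target` must be in
  `[1, n]`.
- Welch t-tests on doubly-constant features report p = 1 (equal means) or
  p = 0 (unequal), flagged `degenerate`, instead of erroring.
- Test values outside the training min-max range are not clipped.
- Single-class test folds yield `NA` sensitivity/specificity/AUC, excluded
  from averages with the fold count unchanged.
- AUC uses midranks, so tied scores contribute ½.

## Problem sizes used in tests

The package's own verification runs use the fixtures above: full
10-iteration × 3-resample × 100-subsample experiments on the 90-subject,
150-feature separable fixture and on 80-subject, 60-feature null cohorts
(10 master seeds each), with `rfe_step = 0.5`; unit tests use smaller
configurations down to the hand-checkable toy examples. At the full
184 × 178 reference scale a single experiment takes on the order of minutes
on one CPU with a fractional RFE step.

## A worked miniature

```{r example, eval = FALSE}
fx <- make_fixture("separable")
validate_schema(fx$baseline)$counts

ex <- run_experiment(
  fx$baseline,
  config = experiment_config(
    task = "aMCI_vs_CN", feature_set = "baseline",
    selection = selection_config(rfe_step = 0.5),
    seed = 42
  )
)
glance(ex)
ex$top_features
plot_selection_frequencies(ex)
```

On this fixture the run recovers all five planted features at or near the
3,000 frequency cap and holds mean held-out accuracy above 0.9; on null
cohorts the same pipeline averages chance-level AUC, and permuting test
labels changes no trained artifact byte — the three properties the test
suite asserts.

## Known limitations

- Binary tasks only: the three pairwise contrasts, not 3-way
  classification; rebalancing is defined for two classes.
- The voting weights (1:4:1) are taken as given and config-exposed; no
  weight search is implemented.
- No hyperparameter tuning or nested CV; components run at library
  defaults by design.
- The generator's family covariance is an equicorrelation stand-in, not an
  estimate of real morphometric covariance.
- Real-cohort results depend on a private sample and are out of the
  package's verification scope.
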