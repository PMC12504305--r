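---
title: "Estimating heterogeneous effects of midwife-led continuity care on low birth weight"
author: "cfrlbw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heterogeneous effects of midwife-led continuity care on low birth weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Low birth weight (LBW, under 2,500 g) is a leading correlate of neonatal
mortality. Midwife-led continuity care (MLCC) — the same midwife or small
midwife team following a woman through pregnancy, birth, and the postnatal
period — is believed to protect against LBW, but in quasi-experimental
settings (hospitals, not individual mothers, choose the care model) the
treated and control groups differ systematically, and the benefit is
unlikely to be uniform: the effect for a mother with meconium-stained
delivery or a preterm gestation need not equal the population average.

`cfrlbw` implements the full analysis chain for this question on tabular
mother/newborn cohorts: chi-square association screening, a three-stage
variable-selection cascade, a small perceptron risk classifier, and a zoo
of causal estimators headed by representation-balancing counterfactual
regression, all evaluated against a synthetic cohort generator with known
ground truth.

## Potential outcomes and estimands

Each mother has two potential outcomes $Y(1), Y(0) \in \{0, 1\}$ (1 = normal
birth weight under MLCC / other-professional care); only the one selected
by her treatment $T$ is observed. The package works on the probability
scale: with $\mu_k(x) = P(Y(k) = 1 \mid X = x)$,

* ITE: $\tau(x) = \mu_1(x) - \mu_0(x)$,
* ATE: $E[\tau(X)]$,
* PEHE (root form): $\sqrt{E[(\hat\tau - \tau)^2]}$, reported alongside
  the absolute ATE error $|\hat{ATE} - ATE|$ and the mean absolute ITE
  error.

Because averaging is a contraction, the root-PEHE always dominates the ATE
error; `metric_report()` asserts this on every evaluation.

## The synthetic cohort generator

No individual-level data from the motivating study is public, so the
generator is the package's test bed. It draws covariates independently
from their marginal prevalences, which for the fifteen shipped covariates
are the published cohort margins (n = 1,166): meconium aspiration 64/1166,
pregnancy-induced hypertension 73/1166, urban residence 930/1166,
iron/folic-acid supplementation 1122/1166, antenatal-visit and
maternal-age categories at their printed counts, and so on. Prevalences
never printed — perinatal death (0.045), gestational-age category
(term/preterm/post-term 0.80/0.14/0.06), previous surgery (0.08) — were
fixed once at values typical for Ethiopian hospital cohorts and are not
tuning knobs.

Treatment and both potential outcomes follow logistic models:

$$P(T = 1 \mid x) = \sigma(\gamma_0 + x^\top\gamma), \qquad
  \mu_0(x) = \sigma(\beta_0 + x^\top\beta), \qquad
  \mu_1(x) = \sigma(\beta_0 + x^\top\beta + \delta_0 + x^\top\delta).$$

This is the minimal structure that supports both confounding (treatment
depends on residence, care-seeking, age, and hypertension) and effect
heterogeneity (the additive log-odds shift $\delta$ loads on meconium
aspiration and preterm gestation, so MLCC helps vulnerable strata more).
The two intercepts were calibrated once, by large-sample root finding over
the covariate distribution, so the default cohort reproduces the study's
treated fraction (582/1166) and observed normal-birth-weight rate
(508/1166); the implied true ATE is about +0.13 on the probability scale.
Categorical covariates are one-hot encoded against their first level, in
the declared level order.

Covariates, treatment, and the two potential-outcome vectors are drawn
from four independent RNG streams fanned out from the master seed, so
changing the treatment model never perturbs $Y(0)/Y(1)$ — ablations stay
counterfactually comparable. `true_ite` is $\mu_1 - \mu_0$ (probability
scale), and consistency ($y_{obs} = Y(T)$) holds row by row.

What the generator does *not* emulate: the joint dependence structure of
the real covariates (only marginals are published), site-level cluster
effects, missing data, and continuous birth weight in grams. Passing tests
therefore demonstrate correctness of the machinery under a known
generating process, not fidelity to the North Shoa cohort.

```{r, eval = FALSE}
library(cfrlbw)
cohort <- generate_cohort(default_mlcc_config(n = 1166, seed = 1))
cohort
true_ate(cohort)
```

## Association screening

`pearson_chi_square()` is the uncorrected Pearson statistic with expected
counts from the margins. No Yates correction and no exact test are
applied: the uncorrected statistic is the convention that reproduces every
verifiable published screening value for this cohort (e.g. 9.496 for
meconium aspiration, 3.62 for pregnancy-induced hypertension) to three
decimals. Missing rows are dropped per table (complete case) and counted.
Odds ratios and multiplicity corrections are deliberately out of scope;
the screen's p-values are the computed upper-tail values even where a
published p-value disagrees with its own statistic.

## Variable selection

The cascade mirrors common epidemiological practice: a univariate screen
(chi-square for discrete features, rank-sum for continuous; default
$\alpha = 0.05$), an L1-penalized logistic regression on the survivors
(penalty by 5-fold cross-validated deviance with seeded folds — the
one-standard-error rule), then recursive feature elimination down to
$k = 7$ predictors, the size of the final published predictor set. Each
stage consumes the previous stage's survivors, so the cascade is monotone.
RFE importance for the default linear model is the absolute standardized
coefficient; ties eliminate the earlier feature in declared order, making
runs reproducible. `permutation_importance()` provides the model-agnostic
ranking (mean AUC drop over seeded column shuffles, normalized to a
maximum of 1) used for the published-style importance figure; it replaces
ensemble-specific importances by design.

## The perceptron classifier

The risk classifier is a 7-input, 5-hidden, 2-output perceptron with
logistic activations throughout. The two output units are *independent*
sigmoids — one scores normal birth weight, one low birth weight — rather
than a softmax pair; the published worked example's two probabilities
(0.196 and 0.882) do not sum to one, which identifies the architecture.
Training minimizes per-unit binary cross-entropy with full-batch Adam
(default 500 epochs, learning rate 0.05), deterministic given the seed;
classification uses the normal-birth-weight unit at threshold 0.5, with
no class reweighting (a documented limitation under the cohort's 44/56
class split). `confusion_summary()` reports overall and per-class percent
correct at one decimal; `roc_auc()` delegates the ROC sweep and
trapezoidal AUC to pROC and is cross-checked in the tests against
explicit Mann–Whitney pair counting.

## Integral probability metrics

Balancing penalties need a distance between the treated and control
representation samples.

* **MMD²** with the Gaussian kernel
  $k(x, y) = \exp(-\lVert x-y\rVert^2 / 2\sigma^2)$; bandwidth defaults to
  the pooled median pairwise distance. The biased V-statistic is
  nonnegative; the unbiased U-statistic (uniform weights only) may dip
  below zero near the null.
* **Wasserstein-1** with Euclidean ground cost. Exact mode solves the
  discrete optimal-transport program by a transportation simplex
  (northwest-corner start, u–v duals, cycle pivots, with a tiny mass
  perturbation against degeneracy) and is restricted to supports of at
  most 64 points; it is validated against exhaustive assignment
  enumeration. Entropic mode runs log-domain Sinkhorn iterations and
  reports the transport cost of the regularized plan, which approaches
  the exact value as $\varepsilon \to 0$ (default
  $\varepsilon = 0.1 \times$ median cost).

During network training the entropic mode is used (differentiable, with
envelope-theorem gradients through the fixed plan); the exact simplex is
the evaluation oracle.

## Counterfactual regression

`fit_cfr()` trains a shared representation $\Phi$ (default two ReLU layers
of 32 units) with two arm-specific heads (one hidden layer of 16), by
minibatch Adam on

$$\frac{1}{n}\sum_i w_i \,\ell(h_{t_i}(\Phi(x_i)), y_i)
  \;+\; \alpha \cdot IPM(\Phi \mid T = 1, \; \Phi \mid T = 0),$$

with inverse arm-frequency weights $w_i$, cross-entropy $\ell$, and
arm-stratified batches so every batch contains both arms. $\alpha = 0$
with no penalty is TARNet; the Wasserstein and MMD penalties give
CFR-WASS and CFR-MMD. Defaults (300 epochs, batch 128, learning rate
0.01, $\alpha = 1$) were chosen once at desk scale and are all exposed in
`cfr_config()`. Training logs the factual loss and per-batch IPM per
epoch; `representation_ipm()` measures post-hoc imbalance of a fitted
representation, and the test suite verifies that switching the penalty on
reduces it on the confounded default cohort.

## Baseline estimators

* **Bayesian ridge** (`fit_bayesian_ridge()`): conjugate linear-Gaussian
  model with prior and noise precisions set by evidence maximization;
  closed-form posterior. Effects come from per-arm fits by default
  (`fit_bayesian_ridge_ite()`; a treatment-as-feature mode is provided),
  with predictions truncated to [0, 1] for the binary outcome.
* **Lasso outcome model**: glmnet on $[X, T, X \cdot T]$; toggling $T$
  yields the two potential-outcome predictions. The penalty-to-infinity
  limit gives identically zero effects.
* **Bagging**: arm-stratified bootstrap ensemble of per-arm logistic
  regressions, predictions averaged; the member resamples are stored so
  single-member ensembles are exactly reproducible.
* **Propensity scores and matching**: logistic or perceptron propensity
  model with scores clipped to $[10^{-3}, 1-10^{-3}]$ and an optional
  held-out calibration slope; `psm_ate()` performs greedy 1:1
  nearest-neighbor matching without replacement within a caliper,
  processing treated units in descending score order with seeded tie
  breaks (the deterministic variant of the matching contract; a fully
  randomized match order was the alternative and was rejected for
  reproducibility).

Every estimator returns an `effect_estimate` whose `ate_hat` is exactly
the mean of its `ite_hat`.

## Bootstrap aggregation

`bootstrap_mean_se()` resamples the rows of a per-row evaluation frame
and reports the mean and standard deviation of the metric replicates.
For the published-style mean ± SE grids the fitted predictions are held
fixed while rows are resampled; refitting every estimator (including the
networks) inside the bootstrap loop would be prohibitive, and the
row-resampling bootstrap captures the evaluation uncertainty the grid is
meant to convey. For cheap closed-form estimators the test suite also
runs a full refit bootstrap. For the network estimators the test suite
measures uncertainty empirically across independent seeded cohorts, which
includes refit variability.

## Pipeline

`run_pipeline()` composes the stages on an 80/20 split stratified on
treatment-by-outcome cells (preserving the near-balanced allocation and
the 43.6% normal-birth-weight rate in both parts; a stratum smaller than
two falls back to treatment-only stratification with a warning). No
fitting stage receives held-out rows — estimators are handed train-row
slices only, a contract the tests probe with poisoned held-out outcomes.
One master seed fans out to per-stage seeds by fixed offsets; a manifest
records seed, package version, and input hash, and a fixed-seed run is
byte-identical. A thin command-line front end
(`inst/cli/cfrlbw`: `simulate`, `validate`, `screen`, `run-all`) wraps
these functions for shell use.

## Numerical choices and degenerate inputs

* Logistic saturation is handled by `plogis`; cross-entropy clips
  probabilities at $10^{-12}$.
* The worked-example accumulator `weighted_sum()` uses Kahan-compensated
  summation.
* Degenerate tables (constant variable, zero margin), single-class
  labels, single-arm data, empty matches, and non-finite training losses
  raise informative errors rather than propagating NaNs; Sinkhorn
  non-convergence warns and flags the result.
* Zero-variance features are dropped (with a warning) by the Bayesian
  ridge; perfect separation in propensity models warns and clips.

## Problem sizes used by the test suite

The suite favors many medium-sized seeded replicates over single massive
runs: calibration and recovery checks use cohorts of 1,166–4,000 mothers
(20 seeds for the null suite, 10 for the balancing property), the exact
ATE integration check enumerates a 3-covariate generating process against
a 200,000-row simulation, and the selection-recovery study uses 20
replicates of n = 2,000. These sizes were chosen so the full suite
documents the statistical properties at conventional 3-standard-error
tolerances while remaining desk-runnable.

## Known limitations

* Covariates are simulated independently; real maternal covariates are
  correlated, and none of the tests speak to performance under strong
  covariate dependence.
* The binary-outcome probability scale bounds all effects in [-1, 1];
  continuous birth weight is out of scope.
* The class imbalance of the cohort is not reweighted in the perceptron,
  matching the analysis this package mirrors rather than best practice.
* Exact optimal transport is limited to 64 support points per side;
  larger evaluations subsample or use the entropic mode.
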