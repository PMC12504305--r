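# cfrlbw

Causal machine learning for **low birth weight (LBW)** outcomes under a
**midwife-led continuity care (MLCC)** intervention. The package is aimed at
biostatisticians and epidemiologists analyzing quasi-experimental maternal
cohorts: one row per mother/newborn, binary covariates (meconium aspiration,
pregnancy-induced hypertension, gestational-age category, ...), a binary
treatment (MLCC vs care by other professional groups), and a binary outcome
(normal birth weight ≥ 2,500 g = 1, LBW = 0).

At its core is **representation-balancing counterfactual regression**: a
shared representation Φ with two arm-specific outcome heads, trained on

    factual cross-entropy + α · IPM( Φ(x) | T=1 , Φ(x) | T=0 )

where the integral probability metric (IPM) is the Wasserstein-1 distance
(CFR-WASS) or the Gaussian-kernel squared maximum mean discrepancy
(CFR-MMD); α = 0 recovers TARNet. With potential outcomes Y(1), Y(0) and
μₖ(x) = P(Y(k)=1 | x), the estimands and headline metrics are

    ITE  τ(x) = μ₁(x) − μ₀(x)          ATE = E[τ(X)]
    PEHE = √E[(τ̂ − τ)²]               εATE = |ÂTE − ATE|

Around that core the package provides the full analysis chain:

* a **synthetic cohort generator** with logistic treatment/outcome models,
  known per-row ground truth (μ₀, μ₁, τ, propensity), and default
  marginals matching the published study cohort (n = 1,166);
* uncorrected **Pearson chi-square screening** (reproduces the published
  contingency statistics exactly);
* a **selection cascade**: univariate screen → L1 logistic → recursive
  feature elimination, plus permutation importance;
* a 7-input / 5-hidden / 2-output **perceptron classifier** with
  independent sigmoid output units, confusion-matrix summaries, and ROC/AUC;
* **exact discrete optimal transport** (transportation simplex) and
  log-domain **Sinkhorn** iterations, Gaussian **MMD²** (biased/unbiased);
* baselines: Bayesian ridge (evidence maximization), lasso with treatment
  interactions, bagged per-arm logistic learners, propensity estimation
  and greedy caliper matching;
* PEHE/ATE/ITE and classification **metrics** with bootstrap mean ± SE;
* a reproducible **pipeline** (80/20 stratified split, report bundle,
  manifest) and a thin CLI (`inst/cli/cfrlbw`).

## Worked example

```r
library(cfrlbw)

cohort <- generate_cohort(default_mlcc_config(n = 1166, seed = 1))
cohort
#> Synthetic cohort: 1166 mothers, 19 encoded covariates
#>   treated (MLCC): 562 (48.2%); NBW rate: 0.437
#>   true ATE (prob. scale): +0.1288

screen <- association_screen(cohort)
head(screen[order(screen$p_value), c("variable", "statistic", "df", "p_value")], 3)
#>                 variable statistic df      p_value
#>  gestational_age.preterm 20.207474  1 6.948094e-06
#>                apgar_low 12.819337  1 3.430553e-04
#>     vacuum_resuscitation  8.091993  1 4.446125e-03

idx <- split_cohort(cohort, 0.8, seed = 1)
fit <- fit_cfr(cohort$X[idx$train, ], cohort$t[idx$train], cohort$y_obs[idx$train],
               cfr_config(ipm = "wass", alpha = 1, epochs = 150, seed = 1))
est <- estimate_effects(fit, cohort$X[idx$test, ])
metric_report(est, cohort$true_ite[idx$test], cohort$y_obs[idx$test], cohort$t[idx$test])
#> PEHE (rmse) 0.0450 | ATE error 0.0293 | ITE error 0.0418
#> factual: mse 0.2402 r2 0.024 acc 0.579 auc 0.602

round(est$ate_hat, 4)
#> [1] 0.1559   # true test-set ATE: 0.1266
```

Reading the numbers: the generator's default MLCC effect is protective —
it raises the probability of normal birth weight by ~0.13 on average, more
in the meconium-aspiration and preterm strata. On 234 held-out mothers the
CFR-WASS network estimates the average effect to within 0.03 on the
probability scale and the per-mother effects with a root-PEHE of 0.045.
The factual AUC is modest by construction: the simulated covariates carry
realistic (weak) signal for the outcome itself.

The classical screening statistics are reproduced from printed counts:

```r
pearson_chi_square(matrix(c(492, 16, 610, 48), 2))$statistic  # meconium aspiration
#> [1] 9.4961...
confusion_summary(list(tn = 28, fp = 139, fn = 14, tp = 636))$overall_pct
#> [1] 81.3
```

An end-to-end run, from a shell:

```sh
Rscript inst/cli/cfrlbw run-all --seed 1 --outdir results/run1
```

writes `association.csv`, `importance.json`, `mlp_confusion.csv`,
`roc.csv`, `metrics.csv` (estimator × metric grid), `metrics_boot.csv`
(bootstrap mean ± SE grid), and `manifest.json`.

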