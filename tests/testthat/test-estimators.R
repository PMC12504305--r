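test_that("effect estimates keep ATE equal to the mean ITE and bound probabilities", {
  est <- effect_estimate(c(0.2, 0.4, 0.5), c(0.3, 0.8, 0.4))
  expect_identical(est$ate_hat, mean(est$ite_hat))
  expect_equal(est$ite_hat, c(0.1, 0.4, -0.1), tolerance = 1e-12)
  expect_error(effect_estimate(c(0.2, 1.4), c(0.1, 0.5)), "\\[0, 1\\]")
  expect_error(effect_estimate(0.5, c(0.1, 0.2)), "length")
})

test_that("Bayesian ridge recovers known weights within posterior uncertainty", {
  set.seed(31)
  n <- 10000
  p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  w_true <- c(1.5, -0.8, 0.3, 0, 2.0)
  y <- drop(X %*% w_true) + rnorm(n, sd = 1)
  fit <- fit_bayesian_ridge(X, y)
  post_sd <- sqrt(diag(fit$sigma))
  expect_true(all(abs(fit$coefficients - w_true) <= 3 * post_sd))
  expect_lt(abs(1 / sqrt(fit$alpha_noise) - 1), 0.05)  # noise sd approx 1

  # null response
  fit0 <- fit_bayesian_ridge(X[1:500, ], rep(0, 500))
  expect_lt(max(abs(fit0$coefficients)), 1e-6)
})

test_that("Bayesian ridge shrinks monotonically with the prior precision", {
  set.seed(32)
  X <- matrix(rnorm(600), 200, 3)
  y <- drop(X %*% c(1, -1, 0.5)) + rnorm(200, sd = 0.5)
  norms <- vapply(c(1, 100, 10000), function(lam) {
    sqrt(sum(fit_bayesian_ridge(X, y, lambda = lam)$coefficients^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[3], 0.2)
})

test_that("Bayesian ridge drops constant columns with a warning", {
  set.seed(33)
  X <- cbind(a = rnorm(100), flat = rep(1, 100))
  expect_warning(fit <- fit_bayesian_ridge(X, rnorm(100)), "zero-variance")
  expect_identical(names(fit$coefficients), "a")
})

test_that("ridge-based effect estimates work in both modes", {
  co <- generate_cohort(tiny_config(3000, seed = 41))
  for (mode in c("per_arm", "treatment_feature")) {
    fit <- fit_bayesian_ridge_ite(co$X, co$t, co$y_obs, mode = mode)
    est <- estimate_effects(fit, co$X)
    expect_identical(est$ate_hat, mean(est$ite_hat))
    expect_true(all(est$mu0_hat >= 0 & est$mu1_hat <= 1))
  }
})

test_that("lasso outcome model collapses to zero effects at extreme penalty", {
  co <- generate_cohort(tiny_config(800, seed = 43))
  fit <- fit_lasso_outcome(co$X, co$t, co$y_obs, penalty = 5)
  est <- estimate_effects(fit, co$X)
  expect_true(all(abs(est$ite_hat) < 1e-10))
})

test_that("lasso recovers effects on a known generating process", {
  co <- generate_cohort(tiny_config(6000, seed = 44))
  fit <- fit_lasso_outcome(co$X, co$t, co$y_obs, seed = 3)
  est <- estimate_effects(fit, co$X)
  se <- sd(co$true_ite) / sqrt(length(co$true_ite)) + 0.02
  expect_lt(abs(est$ate_hat - true_ate(co)), 3 * max(se, 0.02))
})

test_that("bagging with one member equals its base learner on the stored resample", {
  co <- generate_cohort(tiny_config(700, seed = 45))
  bag <- fit_bagging(co$X, co$t, co$y_obs, n_estimators = 1L, seed = 12)
  base <- cfrlbw:::fit_arm_logistic(co$X, co$t, co$y_obs, bag$resamples[[1]])
  expect_equal(estimate_effects(bag, co$X)$ite_hat,
               estimate_effects(base, co$X)$ite_hat, tolerance = 1e-12)
})

test_that("bagging stabilizes the ATE across resampling seeds", {
  co <- generate_cohort(tiny_config(600, seed = 46))
  ates <- function(k) {
    vapply(1:10, function(s) {
      estimate_effects(fit_bagging(co$X, co$t, co$y_obs, n_estimators = k,
                                   seed = s), co$X)$ate_hat
    }, numeric(1))
  }
  expect_lt(var(ates(25)), var(ates(1)))
})

test_that("propensity estimation behaves on randomized and structured cohorts", {
  rnd <- generate_cohort(default_mlcc_config(n = 3000, seed = 47,
                                             randomized = TRUE))
  ps <- fit_propensity(rnd$X, rnd$t)
  expect_lt(abs(mean(ps$scores) - mean(rnd$t)), 0.02)
  expect_true(all(ps$scores >= 1e-3 & ps$scores <= 1 - 1e-3))

  # recovery of the true generating propensity at large n
  big <- generate_cohort(tiny_config(20000, seed = 48))
  ps2 <- fit_propensity(big$X, big$t, holdout = 0.25, seed = 2)
  expect_lt(mean(abs(ps2$scores - big$propensity)), 0.02)
  expect_lt(abs(ps2$calibration_slope - 1), 0.35)

  # constant covariates give constant scores
  flat <- matrix(1, 400, 2)
  t <- rbinom(400, 1, 0.5)
  psf <- fit_propensity(flat, t)
  expect_lt(diff(range(psf$scores)), 1e-12)
})

test_that("perceptron propensity model produces usable scores", {
  co <- generate_cohort(tiny_config(1500, seed = 52))
  ps <- fit_propensity(co$X, co$t, model = "mlp", seed = 3)
  expect_true(all(ps$scores > 0 & ps$scores < 1))
  expect_lt(mean(abs(ps$scores - co$propensity)), 0.1)
})

test_that("caliper matching follows the greedy nearest-neighbor contract", {
  # hand-built 4-unit cohort: only the 0.2 <-> 0.21 pair is in caliper
  scores <- c(0.2, 0.8, 0.21, 0.5)
  t <- c(1, 1, 0, 0)
  y <- c(1, 1, 0, 1)
  res <- psm_ate(y, t, scores, caliper = 0.05, seed = 1)
  expect_identical(res$n_pairs, 1L)
  expect_identical(res$pairs$treated, 1L)
  expect_identical(res$pairs$control, 3L)
  expect_identical(res$n_unmatched, 2L)
  expect_equal(res$ate_hat, 1)

  # infinite caliper: as many pairs as the smaller arm
  wide <- psm_ate(y, t, scores, caliper = 0.999, seed = 1)
  expect_identical(wide$n_pairs, 2L)

  expect_error(psm_ate(y, t, c(0.1, 0.1, 0.9, 0.9), caliper = 0.01), "caliper")

  # identical score distributions, zero effect: estimate near zero
  set.seed(54)
  n <- 2000
  s <- runif(n, 0.3, 0.7)
  tt <- rbinom(n, 1, 0.5)
  yy <- rbinom(n, 1, 0.4)
  null <- psm_ate(yy, tt, s, caliper = 0.05, seed = 2)
  expect_lt(abs(null$ate_hat), 3 * sqrt(2 * 0.4 * 0.6 / null$n_pairs))
})
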