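test_that("covariate and coefficient validation catches malformed configs", {
  expect_error(covariate_spec("x", "binary", 1.2), "probability")
  expect_error(covariate_spec("x", "categorical", c(0.5, 0.4),
                              levels = c("a", "b")), "sum to 1")
  covs <- list(covariate_spec("a", "binary", 0.5))
  expect_error(
    cohort_config(10, covs,
                  treatment_coefs = list(intercept = 0, coef = c(0, 0)),
                  outcome_base_coefs = list(intercept = 0, coef = 0),
                  effect_coefs = list(intercept = 0, coef = 0)),
    "length"
  )
  expect_error(
    cohort_config(10, list(covs[[1]], covs[[1]]),
                  treatment_coefs = list(intercept = 0, coef = c(0, 0)),
                  outcome_base_coefs = list(intercept = 0, coef = c(0, 0)),
                  effect_coefs = list(intercept = 0, coef = c(0, 0))),
    "unique"
  )
})

test_that("generated cohorts satisfy consistency, overlap, and reproducibility", {
  cfg <- tiny_config(500, seed = 7)
  co <- generate_cohort(cfg)
  expect_identical(co$y_obs, ifelse(co$t == 1L, co$y1, co$y0))
  expect_true(min(co$propensity) > 0 && max(co$propensity) < 1)
  expect_true(all(co$true_ite >= -1 & co$true_ite <= 1))
  expect_identical(generate_cohort(cfg), co)

  def <- generate_cohort(default_mlcc_config(seed = 3))
  expect_true(min(def$propensity) > 0 && max(def$propensity) < 1)
})

test_that("potential-outcome draws are invariant to the treatment model", {
  cfg_a <- tiny_config(300, seed = 11, treatment_slope = 0.8)
  cfg_b <- tiny_config(300, seed = 11, treatment_slope = -1.5)
  co_a <- generate_cohort(cfg_a)
  co_b <- generate_cohort(cfg_b)
  expect_identical(co_a$X, co_b$X)
  expect_identical(co_a$y0, co_b$y0)
  expect_identical(co_a$y1, co_b$y1)
  expect_false(identical(co_a$propensity, co_b$propensity))
})

test_that("zero effect term gives exactly zero true ITE everywhere", {
  co <- generate_cohort(tiny_config(200, seed = 2, effect_intercept = 0))
  # effect covariate coefs are nonzero in tiny_config; build a fully null one
  co0 <- generate_cohort(default_mlcc_config(n = 200, seed = 2,
                                             null_effect = TRUE))
  expect_identical(co0$mu0, co0$mu1)
  expect_identical(mean(co0$true_ite), 0)
})

test_that("default MLCC config matches the study marginals", {
  cfg <- default_mlcc_config(n = 1166L, seed = 5)
  prev <- sapply(cfg$covariates, function(cv) cv$prevalence[1])
  names(prev) <- sapply(cfg$covariates, function(cv) cv$name)
  expect_equal(unname(prev["meconium_aspiration"]), 64 / 1166)
  expect_equal(unname(prev["pregnancy_induced_hypertension"]), 73 / 1166)
  expect_equal(unname(prev["residence_urban"]), 930 / 1166, tolerance = 1e-12)
  for (cv in cfg$covariates) {
    expect_true(all(cv$prevalence > 0 & cv$prevalence < 1))
  }
  co <- generate_cohort(cfg)
  se3 <- 3 * sqrt(0.5 * 0.5 / 1166)
  expect_lt(abs(mean(co$t) - 582 / 1166), se3)
})

test_that("simulated true ATE matches exact integration over the covariate support", {
  cfg <- tiny_config(200000L, seed = 19)
  co <- generate_cohort(cfg)
  exact <- tiny_true_ate_exact(cfg)
  mc_se <- sd(co$true_ite) / sqrt(cfg$n)
  expect_lt(abs(true_ate(co) - exact), 3 * mc_se)
})

test_that("true_ate is the mean of mu1 - mu0", {
  co <- generate_cohort(tiny_config(50, seed = 4))
  co$mu1 <- co$mu0
  expect_identical(true_ate(co), 0)
  co$mu1 <- co$mu0 + 0.1
  expect_equal(true_ate(co), 0.1, tolerance = 1e-12)
  co2 <- generate_cohort(tiny_config(50, seed = 9))
  expect_equal(true_ate(co2), sum(co2$mu1 - co2$mu0) / 50, tolerance = 1e-12)
})

test_that("randomized variant: difference in means recovers the true ATE", {
  cfg <- default_mlcc_config(n = 50000L, seed = 21, randomized = TRUE)
  co <- generate_cohort(cfg)
  dim_est <- mean(co$y_obs[co$t == 1]) - mean(co$y_obs[co$t == 0])
  se <- sqrt(var(co$y_obs[co$t == 1]) / sum(co$t) +
               var(co$y_obs[co$t == 0]) / sum(1 - co$t))
  expect_lt(abs(dim_est - true_ate(co)), 3 * se)
})

test_that("cohort CSV and config JSON round-trip", {
  cfg <- tiny_config(40, seed = 6)
  co <- generate_cohort(cfg)
  main <- tempfile(fileext = ".csv")
  truth <- tempfile(fileext = ".csv")
  write_cohort(co, main, truth)
  back <- read_cohort(main)
  expect_identical(back$t, co$t)
  expect_identical(back$y_obs, co$y_obs)
  expect_equal(unname(back$X), unname(co$X))
  chk <- validate_cohort_csv(main)
  expect_identical(chk$n, 40L)

  js <- tempfile(fileext = ".json")
  write_cohort_config(cfg, js)
  cfg2 <- read_cohort_config(js)
  expect_identical(generate_cohort(cfg2), co)

  bad <- data.frame(a = 1:3, treatment = c(0, 1, 2), outcome = c(0, 1, 0))
  badf <- tempfile(fileext = ".csv")
  write.csv(bad, badf, row.names = FALSE)
  expect_error(validate_cohort_csv(badf), "0/1")
})
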