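make_noise_frame <- function(n, p, seed) {
  set.seed(seed)
  df <- as.data.frame(matrix(rbinom(n * p, 1, 0.5), n, p))
  names(df) <- sprintf("f%02d", seq_len(p))
  df$outcome <- rbinom(n, 1, 0.5)
  df
}

test_that("univariate screen keeps perfect predictors and honors alpha", {
  df <- make_noise_frame(300, 5, seed = 1)
  df$hit <- df$outcome
  expect_true("hit" %in% univariate_screen(df, alpha = 0.05))
  expect_setequal(univariate_screen(df, alpha = 1),
                  setdiff(names(df), "outcome"))
})

test_that("univariate screen false-inclusion rate is calibrated at alpha", {
  n_rep <- 300L
  p <- 20L
  included <- 0L
  for (r in seq_len(n_rep)) {
    df <- make_noise_frame(300, p, seed = 1000 + r)
    included <- included + length(univariate_screen(df, alpha = 0.05))
  }
  rate <- included / (n_rep * p)
  se <- sqrt(0.05 * 0.95 / (n_rep * p))
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("lasso selection shrinks fully at extreme penalty and recovers truth", {
  # full shrinkage
  df <- make_noise_frame(200, 8, seed = 3)
  big <- l1_logistic_select(df, penalty = 10)
  expect_length(big$selected, 0)

  # recovery of 3 true predictors among 15, penalty by cross-validation
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    set.seed(200 + r)
    X <- matrix(rbinom(2000 * 15, 1, 0.4), 2000, 15)
    colnames(X) <- sprintf("x%02d", 1:15)
    eta <- -0.5 + 1.2 * X[, 1] - 1.0 * X[, 5] + 0.9 * X[, 11]
    df <- as.data.frame(X)
    df$outcome <- rbinom(2000, 1, plogis(eta))
    sel <- l1_logistic_select(df, seed = r)$selected
    if (all(c("x01", "x05", "x11") %in% sel)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("duplicated informative feature is not doubly selected at moderate penalty", {
  dropped_dup <- 0L
  for (r in 1:5) {
    set.seed(40 + r)
    x <- rbinom(1500, 1, 0.5)
    df <- data.frame(x1 = x, x1_copy = x,
                     x2 = rbinom(1500, 1, 0.5))
    df$outcome <- rbinom(1500, 1, plogis(-0.3 + 1.5 * x))
    sel <- l1_logistic_select(df, penalty = 0.05)$selected
    if (sum(c("x1", "x1_copy") %in% sel) <= 1L) dropped_dup <- dropped_dup + 1L
  }
  expect_gte(dropped_dup, 4L)
})

test_that("RFE keeps strong features and matches brute-force refitting", {
  df <- make_noise_frame(400, 4, seed = 5)
  df$hit <- df$outcome
  expect_identical(
    recursive_feature_elimination(df, k = length(names(df)) - 1L)$selected,
    setdiff(names(df), "outcome")
  )
  expect_identical(recursive_feature_elimination(df, k = 1)$selected, "hit")
  expect_error(recursive_feature_elimination(df, k = 99), "between")

  # elimination order equals an independent refit-every-round oracle
  set.seed(17)
  n <- 600
  X <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
  colnames(X) <- paste0("v", 1:5)
  y <- rbinom(n, 1, plogis(-0.2 + 1.5 * X[, 2] + 0.7 * X[, 4] - 0.3 * X[, 5]))
  df <- as.data.frame(X)
  df$outcome <- y
  res <- recursive_feature_elimination(df, k = 1)

  current <- paste0("v", 1:5)
  oracle_order <- character()
  while (length(current) > 1L) {
    fit <- glm(y ~ ., data = data.frame(X[, current, drop = FALSE]),
               family = binomial())
    cf <- coef(fit)[-1]
    imp <- abs(cf) * apply(X[, current, drop = FALSE], 2, sd)
    drop_f <- current[which.min(imp)]
    oracle_order <- c(oracle_order, drop_f)
    current <- setdiff(current, drop_f)
  }
  expect_identical(res$trace$dropped, oracle_order)
  expect_identical(res$selected, current)
})

test_that("permutation importance isolates the informative feature", {
  set.seed(23)
  n <- 800
  X <- cbind(strong = rbinom(n, 1, 0.5), noise1 = rbinom(n, 1, 0.5),
             noise2 = rbinom(n, 1, 0.3))
  y <- rbinom(n, 1, plogis(-1 + 2.5 * X[, "strong"]))
  df <- as.data.frame(X)
  df$outcome <- y
  fit <- glm(y ~ ., data = df[, 1:3], family = binomial())
  model <- list(predict = function(M) {
    predict(fit, newdata = as.data.frame(M), type = "response")
  })
  for (s in 1:5) {
    rk <- permutation_importance(df, "outcome", model, n_repeats = 5, seed = s)
    expect_identical(rk$feature[1], "strong")
    expect_equal(rk$normalized_importance[1], 1)
    expect_true(all(rk$normalized_importance >= 0 &
                      rk$normalized_importance <= 1))
    expect_lt(max(rk$normalized_importance[rk$feature != "strong"]), 0.5)
  }
  # degenerate scorer: all drops zero -> all importances zero
  flat <- permutation_importance(df, "outcome",
                                 list(predict = function(M) rep(0.5, nrow(M))),
                                 n_repeats = 3, seed = 1,
                                 score = function(s, y) 0)
  expect_true(all(flat$normalized_importance == 0))
})

test_that("selection cascade stages are nested subsets", {
  co <- generate_cohort(default_mlcc_config(n = 1166, seed = 31))
  res <- feature_selection_cascade(co, alpha = 0.3, k = 7, seed = 2)
  expect_true(all(res$l1 %in% res$univariate))
  expect_true(all(res$selected %in% res$l1))
  expect_lte(length(res$selected), 7L)
})
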