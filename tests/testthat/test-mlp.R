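test_that("logistic activation has the textbook properties and values", {
  expect_identical(logistic(0), 0.5)
  z <- c(-3.2, -0.5, 0.4, 2.2)
  expect_equal(logistic(-z), 1 - logistic(z), tolerance = 1e-12)
  expect_true(all(logistic(c(-30, 30)) > 0 & logistic(c(-30, 30)) < 1))
  expect_identical(logistic(c(-800, 800)), c(0, 1))  # saturates, never NaN
  # published feed-forward example (second unit prints 0.882 at 3 d.p.)
  expect_equal(round(logistic(2.01009), 3), 0.882)
})

test_that("weighted_sum reproduces the printed pre-activation sums", {
  terms <- worked_example_terms()
  expect_equal(round(weighted_sum(terms$z1), 3), -1.413)
  expect_equal(weighted_sum(terms$z2), 2.01009, tolerance = 1e-12)
  expect_identical(weighted_sum(c(0, 0, 0)), 0)
  expect_error(weighted_sum(numeric()), "nonempty")
})

test_that("mlp_forward matches pencil arithmetic and handles shapes", {
  # 2-input / 1-hidden toy computed by hand
  w <- mlp_weights(matrix(c(0.3, -0.2), 2, 1), 0.1,
                   matrix(c(0.5, -0.4), 1, 2), c(0.05, -0.05))
  x <- c(1, 0.5)
  h <- plogis(0.3 * 1 - 0.2 * 0.5 + 0.1)
  out <- mlp_forward(w, x)
  expect_equal(out$hidden, h, tolerance = 1e-12)
  expect_equal(out$p_nbw, plogis(0.5 * h + 0.05), tolerance = 1e-12)
  expect_equal(out$p_lbw, plogis(-0.4 * h - 0.05), tolerance = 1e-12)

  zero <- mlp_weights(matrix(0, 7, 5), rep(0, 5), matrix(0, 5, 2), c(0, 0))
  res <- mlp_forward(zero, rep(1, 7))
  expect_identical(c(res$p_nbw, res$p_lbw), c(0.5, 0.5))
  expect_error(mlp_forward(zero, rep(1, 6)), "length")
})

test_that("mlp_forward is invariant to consistent hidden-unit permutation", {
  set.seed(5)
  w <- mlp_weights(matrix(rnorm(35), 7, 5), rnorm(5),
                   matrix(rnorm(10), 5, 2), rnorm(2))
  perm <- c(3, 1, 5, 2, 4)
  wp <- mlp_weights(w$input_hidden[, perm], w$hidden_bias[perm],
                    w$hidden_output[perm, ], w$output_bias)
  x <- rnorm(7)
  expect_equal(mlp_forward(wp, x)$p_nbw, mlp_forward(w, x)$p_nbw,
               tolerance = 1e-12)
  expect_equal(mlp_forward(wp, x)$p_lbw, mlp_forward(w, x)$p_lbw,
               tolerance = 1e-12)
})

test_that("training learns separable structure and is deterministic", {
  set.seed(9)
  n <- 400
  X <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
  y <- as.integer(X[, "a"] == 1)   # linearly separable
  fit <- train_mlp(X, y, hidden = 3, seed = 2, epochs = 300, split = 0.8)
  acc <- confusion_summary(fit$train_confusion)$overall_pct
  expect_gte(acc, 95)
  expect_true(all(diff(range(fit$loss)) > 0))

  fit2 <- train_mlp(X, y, hidden = 3, seed = 2, epochs = 300, split = 0.8)
  expect_identical(fit2$weights, fit$weights)

  expect_error(train_mlp(X, rep(1L, n)), "single class")
})

test_that("permuted labels give chance-level test AUC", {
  co <- generate_cohort(default_mlcc_config(seed = 41))
  X <- co$X[, 1:7]
  aucs <- vapply(1:50, function(s) {
    yperm <- cfrlbw:::with_seed(900 + s, sample(co$y_obs))
    fit <- train_mlp(X, yperm, seed = s, epochs = 60, split = 0.8)
    scores <- predict(fit, X[fit$test_idx, ])
    roc_auc(scores, yperm[fit$test_idx])$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("confusion summaries reproduce the published percent-correct cells", {
  train_cm <- list(tn = 28, fp = 139, fn = 14, tp = 636)
  test_cm <- list(tn = 8, fp = 54, fn = 11, tp = 276)
  str <- confusion_summary(train_cm)
  ste <- confusion_summary(test_cm)
  expect_equal(str$overall_pct, 81.3)
  expect_equal(ste$overall_pct, 81.4)
  expect_equal(unname(str$per_class_pct["positive"]), 97.8)
  expect_equal(unname(ste$per_class_pct["positive"]), 96.2)
  perfect <- confusion_summary(list(tn = 5, fp = 0, fn = 0, tp = 7))
  expect_equal(perfect$overall_pct, 100)
  expect_error(confusion_summary(list(tn = 0, fp = 0, fn = 0, tp = 0)), "empty")
})

test_that("confusion counts are conserved", {
  set.seed(3)
  scores <- runif(200)
  labels <- rbinom(200, 1, 0.4)
  cm <- confusion_matrix(scores, labels)
  expect_identical(cm$tn + cm$fp + cm$fn + cm$tp, 200L)
  expect_identical(cm$fn + cm$tp, sum(labels))
})

test_that("AUC equals pair counting and is invariant to monotone transforms", {
  expect_equal(roc_auc(c(0, 1, 0, 1, 1), c(0, 1, 0, 1, 1))$auc, 1)
  hand <- roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
  expect_equal(hand$auc, 0.75)

  set.seed(8)
  scores <- round(runif(300), 1)   # ties on purpose
  labels <- rbinom(300, 1, 0.5)
  expect_equal(roc_auc(scores, labels)$auc, auc_pair_oracle(scores, labels),
               tolerance = 1e-12)
  expect_equal(roc_auc(qlogis(pmin(pmax(scores, 1e-3), 1 - 1e-3)), labels)$auc,
               roc_auc(scores, labels)$auc, tolerance = 1e-12)

  set.seed(13)
  null_auc <- roc_auc(runif(10000), rbinom(10000, 1, 0.5))$auc
  expect_lt(abs(null_auc - 0.5), 0.02)
  expect_error(roc_auc(runif(5), rep(1, 5)), "one class")
})

test_that("perceptron weights survive the CSV round-trip", {
  set.seed(6)
  w <- mlp_weights(matrix(rnorm(35), 7, 5,
                          dimnames = list(paste0("in", 1:7), NULL)),
                   rnorm(5), matrix(rnorm(10), 5, 2), rnorm(2))
  path <- tempfile(fileext = ".csv")
  write_mlp_weights(w, path)
  w2 <- read_mlp_weights(path)
  expect_equal(unname(w2$input_hidden), unname(w$input_hidden))
  expect_equal(w2$hidden_bias, w$hidden_bias)
  expect_equal(unname(w2$hidden_output), unname(w$hidden_output))
  expect_equal(w2$output_bias, w$output_bias)
})
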