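test_that("sample sets validate weights and dimensions", {
  expect_error(sample_set(matrix(1, 2, 1), weights = c(0.6, 0.6)), "sum to 1")
  expect_error(sample_set(matrix(1, 2, 1), weights = c(-0.5, 1.5)),
               "nonnegative")
  expect_error(mmd_squared(matrix(1, 2, 1), matrix(1, 2, 2)), "dimension")
  expect_error(wasserstein(matrix(1, 2, 1), matrix(1, 2, 2)), "dimension")
})

test_that("MMD^2 matches closed-form kernel sums on tiny instances", {
  expect_lt(abs(mmd_squared(sample_set(c(0, 1)), sample_set(c(0, 1)),
                            bandwidth = 1)), 1e-12)
  # {0,0} vs {1,1}: all within-set kernels are 1, all cross kernels e^{-1/2}
  got <- mmd_squared(sample_set(c(0, 0)), sample_set(c(1, 1)), bandwidth = 1)
  expect_equal(got, 2 - 2 * exp(-1 / 2), tolerance = 1e-12)
  # general 2x2 double sums at bandwidth 1
  a <- c(0.2, 1.4)
  b <- c(-0.3, 0.9)
  k <- function(x, y) exp(-(x - y)^2 / 2)
  manual <- mean(outer(a, a, k)) + mean(outer(b, b, k)) - 2 * mean(outer(a, b, k))
  expect_equal(mmd_squared(sample_set(a), sample_set(b), bandwidth = 1),
               manual, tolerance = 1e-12)
})

test_that("unbiased MMD^2 is near zero under the null", {
  set.seed(4)
  x <- rnorm(500)
  y <- rnorm(500)
  obs <- mmd_squared(sample_set(x), sample_set(y), estimator = "unbiased")
  # permutation null
  pooled <- c(x, y)
  nulls <- vapply(1:100, function(i) {
    idx <- sample(1000, 500)
    mmd_squared(sample_set(pooled[idx]), sample_set(pooled[-idx]),
                estimator = "unbiased")
  }, numeric(1))
  expect_lt(abs(obs - mean(nulls)), 3 * sd(nulls))
  expect_error(mmd_squared(sample_set(c(0, 1)), sample_set(c(2, 3)),
                           estimator = "unbiased"), NA)
  expect_error(mmd_squared(sample_set(c(0, 1), weights = c(0.3, 0.7)),
                           sample_set(c(2, 3)), estimator = "unbiased"),
               "uniform")
})

test_that("biased MMD^2 is nonnegative and symmetric", {
  set.seed(11)
  for (r in 1:20) {
    A <- matrix(rnorm(8), 4, 2)
    B <- matrix(rnorm(6), 3, 2)
    m1 <- mmd_squared(sample_set(A), sample_set(B))
    m2 <- mmd_squared(sample_set(B), sample_set(A))
    expect_gte(m1, 0)
    expect_equal(m1, m2, tolerance = 1e-12)
  }
})

test_that("Wasserstein handles the textbook cases", {
  expect_lt(wasserstein(sample_set(c(0.3, 0.7)), sample_set(c(0.3, 0.7))),
            1e-8)
  expect_equal(wasserstein(sample_set(0), sample_set(2.5)), 2.5,
               tolerance = 1e-8)
  expect_equal(wasserstein(sample_set(c(0, 1)), sample_set(c(2, 3))), 2,
               tolerance = 1e-8)
  big <- matrix(rnorm(65), 65, 1)
  expect_error(wasserstein(sample_set(big), sample_set(big), mode = "exact"),
               "64")
})

test_that("exact Wasserstein equals exhaustive assignment enumeration", {
  set.seed(77)
  for (r in 1:100) {
    k <- sample(2:5, 1)
    d <- sample(1:3, 1)
    A <- matrix(rnorm(k * d), k, d)
    B <- matrix(rnorm(k * d), k, d)
    w <- wasserstein(sample_set(A), sample_set(B))
    expect_equal(w, wasserstein_enum_oracle(A, B), tolerance = 1e-6)
    expect_equal(wasserstein(sample_set(B), sample_set(A)), w,
                 tolerance = 1e-8)
    expect_gte(w, 0)
  }
})

test_that("exact Wasserstein handles unequal sizes and nonuniform weights", {
  # all mass at 0 split to {2, 4} with weights 1/2 each:
  # cost = 0.5 * 2 + 0.5 * 4 = 3
  w <- wasserstein(sample_set(matrix(0), weights = 1),
                   sample_set(matrix(c(2, 4), 2, 1), weights = c(0.5, 0.5)))
  expect_equal(w, 3, tolerance = 1e-8)
  # 1-D optimal transport equals the quantile-coupling cost
  set.seed(5)
  x <- sort(rnorm(6))
  y <- sort(rnorm(6))
  expect_equal(wasserstein(sample_set(x), sample_set(y)),
               mean(abs(x - y)), tolerance = 1e-8)
})

test_that("entropic Wasserstein approaches the exact value as epsilon shrinks", {
  set.seed(21)
  A <- matrix(rnorm(10), 5, 2)
  B <- matrix(rnorm(12), 6, 2)
  exact <- wasserstein(sample_set(A), sample_set(B))
  errs <- vapply(c(0.5, 0.1, 0.02), function(eps) {
    abs(as.numeric(wasserstein(sample_set(A), sample_set(B),
                               mode = "entropic", epsilon = eps,
                               max_iter = 20000)) - exact)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("non-convergent Sinkhorn warns and flags", {
  set.seed(2)
  A <- matrix(rnorm(10), 5, 2)
  B <- matrix(rnorm(10), 5, 2)
  expect_warning(
    res <- wasserstein(sample_set(A), sample_set(B), mode = "entropic",
                       epsilon = 0.001, max_iter = 3),
    "Sinkhorn"
  )
  expect_false(attr(res, "converged"))
})
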