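# Baseline causal estimators compared against the CFR networks: Bayesian
# ridge, lasso outcome model with treatment interactions, bagging of
# per-arm logistic learners, propensity-score estimation, and greedy
# caliper matching.

#' Per-unit effect estimate container
#'
#' @param mu0_hat,mu1_hat Predicted outcome probabilities under control and
#'   treatment, one per unit, in `[0, 1]`.
#' @return An object of class `effect_estimate` with `ite_hat = mu1_hat -
#'   mu0_hat` and `ate_hat = mean(ite_hat)`.
#' @export
effect_estimate <- function(mu0_hat, mu1_hat) {
  if (length(mu0_hat) != length(mu1_hat)) {
    stop("`mu0_hat` and `mu1_hat` must have the same length", call. = FALSE)
  }
  if (any(mu0_hat < -1e-9 | mu0_hat > 1 + 1e-9) ||
      any(mu1_hat < -1e-9 | mu1_hat > 1 + 1e-9)) {
    stop("predicted outcome probabilities must lie in [0, 1]", call. = FALSE)
  }
  mu0_hat <- pmin(pmax(mu0_hat, 0), 1)
  mu1_hat <- pmin(pmax(mu1_hat, 0), 1)
  ite <- mu1_hat - mu0_hat
  structure(list(mu0_hat = mu0_hat, mu1_hat = mu1_hat,
                 ite_hat = ite, ate_hat = mean(ite)),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Effect estimate for %d units: ATE = %+.4f (ITE range %.4f .. %.4f)\n",
              length(x$ite_hat), x$ate_hat, min(x$ite_hat), max(x$ite_hat)))
  invisible(x)
}

#' Write per-unit effect estimates to CSV
#' @param estimate An [effect_estimate()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_effect_estimate <- function(estimate, path) {
  write.csv(data.frame(row = seq_along(estimate$ite_hat),
                       mu0_hat = estimate$mu0_hat,
                       mu1_hat = estimate$mu1_hat,
                       ite_hat = estimate$ite_hat),
            path, row.names = FALSE)
  invisible(path)
}

#' Predict potential outcomes and effects for new units
#'
#' Generic over fitted causal estimators; every method returns an
#' [effect_estimate()] whose `ate_hat` equals the mean of its `ite_hat`.
#'
#' @param fit A fitted estimator.
#' @param X Covariate matrix for the units to score.
#' @param ... Method-specific arguments.
#' @return An [effect_estimate()].
#' @export
estimate_effects <- function(fit, X, ...) UseMethod("estimate_effects")

#' @export
estimate_effects.cfr_fit <- function(fit, X, ...) {
  pr <- predict(fit, X)
  effect_estimate(pr$mu0_hat, pr$mu1_hat)
}

# ---- Bayesian ridge ------------------------------------------------------

#' Bayesian ridge regression with evidence maximization
#'
#' Linear-Gaussian model `y = X w + e` with an isotropic Gaussian prior on
#' the weights. The prior precision `lambda` and noise precision
#' `alpha_noise` are set by maximizing the marginal likelihood (iterating
#' the effective-degrees-of-freedom updates); the posterior over weights is
#' then available in closed form. Predictors and response are centered
#' internally; zero-variance predictors are dropped with a warning.
#'
#' @param X n x p numeric matrix.
#' @param y Numeric response.
#' @param max_iter,tol Evidence-maximization iteration controls.
#' @param lambda,alpha_noise Optional fixed values for the prior and noise
#'   precisions; when supplied the corresponding evidence update is skipped
#'   and the posterior is conditioned on the given value.
#' @return An object of class `bayesian_ridge`: posterior mean
#'   `coefficients` (named), `intercept`, posterior covariance `sigma`,
#'   precisions `lambda` and `alpha_noise`, and `n_iter`.
#' @export
fit_bayesian_ridge <- function(X, y, max_iter = 300L, tol = 1e-8,
                               lambda = NULL, alpha_noise = NULL) {
  fixed_lambda <- !is.null(lambda)
  fixed_alpha <- !is.null(alpha_noise)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  keep <- apply(X, 2L, sd) > 0
  if (!all(keep)) {
    warning("dropping zero-variance features: ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - ybar
  XtX <- crossprod(Xc)
  Xty <- crossprod(Xc, yc)
  ev <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  if (!fixed_lambda) lambda <- 1
  if (!fixed_alpha) alpha_noise <- 1 / max(var(yc), 1e-12)
  m <- numeric(p)
  for (it in seq_len(max_iter)) {
    A <- alpha_noise * XtX + diag(lambda, p)
    m_new <- drop(solve(A, alpha_noise * Xty))
    gamma <- sum(alpha_noise * ev / (lambda + alpha_noise * ev))
    lambda_new <- if (fixed_lambda) lambda else gamma / max(sum(m_new^2), 1e-12)
    rss <- sum((yc - Xc %*% m_new)^2)
    alpha_new <- if (fixed_alpha) alpha_noise else
      max(n - gamma, 1e-12) / max(rss, 1e-12)
    done <- max(abs(m_new - m)) < tol &&
      abs(lambda_new - lambda) < tol * (1 + lambda) &&
      abs(alpha_new - alpha_noise) < tol * (1 + alpha_noise)
    m <- m_new
    lambda <- lambda_new
    alpha_noise <- alpha_new
    if (done) break
  }
  A <- alpha_noise * XtX + diag(lambda, p)
  sigma <- solve(A)
  coefs <- stats::setNames(m, colnames(X))
  structure(list(coefficients = coefs,
                 intercept = ybar - sum(xbar * m),
                 sigma = sigma, lambda = lambda,
                 alpha_noise = alpha_noise, n_iter = it,
                 features = colnames(X)),
            class = "bayesian_ridge")
}

#' @export
predict.bayesian_ridge <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(X))) {
    X <- X[, object$features, drop = FALSE]
  }
  drop(X %*% object$coefficients) + object$intercept
}

#' Treatment effects from Bayesian ridge outcome models
#'
#' Either one Bayesian ridge fit per treatment arm (default) or a single
#' fit with the treatment indicator as a feature, toggled to produce the
#' two potential-outcome predictions. Predictions are truncated to
#' `[0, 1]` since the outcome is binary.
#'
#' @param X Covariate matrix.
#' @param t Binary treatment vector.
#' @param y Binary outcome vector.
#' @param mode `"per_arm"` or `"treatment_feature"`.
#' @return Class `bayesian_ridge_effect`; use [estimate_effects()].
#' @export
fit_bayesian_ridge_ite <- function(X, t, y,
                                   mode = c("per_arm", "treatment_feature")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  t <- as.integer(t)
  if (length(unique(t)) < 2L) stop("both arms required", call. = FALSE)
  fits <- if (mode == "per_arm") {
    list(arm0 = fit_bayesian_ridge(X[t == 0L, , drop = FALSE], y[t == 0L]),
         arm1 = fit_bayesian_ridge(X[t == 1L, , drop = FALSE], y[t == 1L]))
  } else {
    list(joint = fit_bayesian_ridge(cbind(X, ..treatment.. = t), y))
  }
  structure(list(mode = mode, fits = fits), class = "bayesian_ridge_effect")
}

#' @export
estimate_effects.bayesian_ridge_effect <- function(fit, X, ...) {
  X <- as.matrix(X)
  clip01 <- function(v) pmin(pmax(v, 0), 1)
  if (fit$mode == "per_arm") {
    effect_estimate(clip01(predict(fit$fits$arm0, X)),
                    clip01(predict(fit$fits$arm1, X)))
  } else {
    effect_estimate(
      clip01(predict(fit$fits$joint, cbind(X, ..treatment.. = 0L))),
      clip01(predict(fit$fits$joint, cbind(X, ..treatment.. = 1L)))
    )
  }
}

# ---- lasso outcome model -------------------------------------------------

#' L1-penalized logistic outcome model with treatment interactions
#'
#' Fits `y ~ X + t + X:t` with the lasso penalty; potential outcomes come
#' from toggling the treatment indicator (and its interactions).
#'
#' @param X Covariate matrix.
#' @param t Binary treatment vector.
#' @param y Binary outcome vector.
#' @param penalty Lasso penalty; `NULL` for 5-fold cross-validated choice.
#' @param seed Seed for the fold assignment.
#' @return Class `lasso_outcome`; use [estimate_effects()].
#' @export
fit_lasso_outcome <- function(X, t, y, penalty = NULL, seed = 1L) {
  X <- as.matrix(X)
  t <- as.numeric(t)
  design <- function(X, t) cbind(X, trt = t, X * t)
  D <- design(X, t)
  if (is.null(penalty)) {
    foldid <- with_seed(fanout_seed(seed, 43L),
                        sample(rep_len(1:5, nrow(D))))
    cv <- glmnet::cv.glmnet(D, y, family = "binomial", alpha = 1,
                            foldid = foldid)
    penalty <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(D, y, family = "binomial", alpha = 1,
                          lambda = penalty, thresh = 1e-10, maxit = 1e6)
  }
  structure(list(fit = fit, penalty = penalty, design = design),
            class = "lasso_outcome")
}

#' @export
estimate_effects.lasso_outcome <- function(fit, X, ...) {
  X <- as.matrix(X)
  p0 <- predict(fit$fit, fit$design(X, rep(0, nrow(X))), s = fit$penalty,
                type = "response")[, 1L]
  p1 <- predict(fit$fit, fit$design(X, rep(1, nrow(X))), s = fit$penalty,
                type = "response")[, 1L]
  effect_estimate(p0, p1)
}

# ---- bagging -------------------------------------------------------------

# per-arm logistic base learner on a row subset
fit_arm_logistic <- function(X, t, y, rows = seq_along(t)) {
  Xr <- X[rows, , drop = FALSE]
  tr <- t[rows]
  yr <- y[rows]
  fit_one <- function(arm) {
    Xa <- Xr[tr == arm, , drop = FALSE]
    ya <- yr[tr == arm]
    suppressWarnings(glm.fit(cbind(1, Xa), ya, family = binomial()))
  }
  structure(list(arm0 = fit_one(0L), arm1 = fit_one(1L)),
            class = "arm_logistic")
}

#' @export
estimate_effects.arm_logistic <- function(fit, X, ...) {
  X <- as.matrix(X)
  pr <- function(f) {
    cf <- f$coefficients
    cf[is.na(cf)] <- 0
    plogis(drop(cbind(1, X) %*% cf))
  }
  effect_estimate(pr(fit$arm0), pr(fit$arm1))
}

#' Bagged per-arm outcome learners
#'
#' Bootstrap ensemble of per-arm logistic regressions: each member is fit
#' on an arm-stratified bootstrap resample and the predicted potential
#' outcome probabilities are averaged over members.
#'
#' @param X Covariate matrix.
#' @param t Binary treatment vector.
#' @param y Binary outcome vector.
#' @param n_estimators Number of bootstrap members (>= 1).
#' @param seed RNG seed for the resamples.
#' @return Class `bagging_fit`; the bootstrap row indices of each member
#'   are kept in `$resamples`. Use [estimate_effects()].
#' @export
fit_bagging <- function(X, t, y, n_estimators = 10L, seed = 1L) {
  if (n_estimators < 1L) stop("`n_estimators` must be >= 1", call. = FALSE)
  X <- as.matrix(X)
  t <- as.integer(t)
  i1 <- which(t == 1L)
  i0 <- which(t == 0L)
  if (!length(i1) || !length(i0)) stop("both arms required", call. = FALSE)
  resamples <- with_seed(fanout_seed(seed, 47L), {
    lapply(seq_len(n_estimators), function(k) {
      c(sample(i1, length(i1), replace = TRUE),
        sample(i0, length(i0), replace = TRUE))
    })
  })
  members <- lapply(resamples, function(rows) fit_arm_logistic(X, t, y, rows))
  structure(list(members = members, resamples = resamples),
            class = "bagging_fit")
}

#' @export
estimate_effects.bagging_fit <- function(fit, X, ...) {
  preds <- lapply(fit$members, function(m) estimate_effects(m, X))
  mu0 <- rowMeans(vapply(preds, function(p) p$mu0_hat, numeric(nrow(as.matrix(X)))))
  mu1 <- rowMeans(vapply(preds, function(p) p$mu1_hat, numeric(nrow(as.matrix(X)))))
  effect_estimate(mu0, mu1)
}

# ---- propensity scores and matching --------------------------------------

#' Estimate propensity scores
#'
#' `P(t = 1 | X)` by logistic regression or by the perceptron classifier.
#' Scores are clipped to `[1e-3, 1 - 1e-3]` (perfect separation produces a
#' warning rather than degenerate scores). When `holdout > 0` a calibration
#' slope — the coefficient of the logit score in a held-out logistic
#' recalibration — is reported (1 means well calibrated).
#'
#' @param X Covariate matrix.
#' @param t Binary treatment vector.
#' @param model `"logistic"` or `"mlp"`.
#' @param holdout Held-out fraction for the calibration slope (0 disables).
#' @param seed Seed (holdout split; MLP training).
#' @return List with `scores`, `calibration_slope` (or `NA`), and `fit`.
#' @export
fit_propensity <- function(X, t, model = c("logistic", "mlp"),
                           holdout = 0, seed = 1L) {
  model <- match.arg(model)
  X <- as.matrix(X)
  t <- as.integer(t)
  if (length(unique(t)) < 2L) stop("both arms required", call. = FALSE)
  n <- nrow(X)
  if (holdout > 0) {
    idx <- split_indices(strata = t, fraction = 1 - holdout,
                         seed = fanout_seed(seed, 53L))
    fit_rows <- idx$train
    cal_rows <- idx$test
  } else {
    fit_rows <- seq_len(n)
    cal_rows <- integer()
  }
  if (model == "logistic") {
    fit <- suppressWarnings(
      glm.fit(cbind(1, X[fit_rows, , drop = FALSE]), t[fit_rows],
              family = binomial())
    )
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    scores <- plogis(drop(cbind(1, X) %*% cf))
    if (!fit$converged) {
      warning("propensity model did not converge (possible separation); scores clipped")
    }
  } else {
    fit <- train_mlp(X[fit_rows, , drop = FALSE], t[fit_rows], hidden = 5L,
                     seed = seed, epochs = 200L, split = 1)
    scores <- predict(fit, X)
  }
  scores <- pmin(pmax(scores, 1e-3), 1 - 1e-3)
  slope <- NA_real_
  if (length(cal_rows) > 1L && length(unique(t[cal_rows])) == 2L) {
    cal <- suppressWarnings(
      glm(t[cal_rows] ~ qlogis(scores[cal_rows]), family = binomial())
    )
    slope <- unname(coef(cal)[2L])
  }
  list(scores = scores, calibration_slope = slope, fit = fit)
}

#' Propensity-score matching estimate of the ATE
#'
#' Greedy 1:1 nearest-neighbor matching on the propensity score without
#' replacement: treated units are processed in descending score order
#' (random tie order from `seed`) and matched to the closest unmatched
#' control within `caliper`. The estimate is the mean outcome difference
#' over matched pairs.
#'
#' @param y Outcome vector.
#' @param t Binary treatment vector.
#' @param scores Propensity scores in (0, 1).
#' @param caliper Maximum score distance for a match (> 0).
#' @param seed Tie-break seed.
#' @return List with `ate_hat`, `n_pairs`, `n_unmatched`, and the matched
#'   `pairs` (data.frame of treated/control indices and score gap).
#' @export
psm_ate <- function(y, t, scores, caliper = 0.05, seed = 1L) {
  stopifnot(caliper > 0, all(scores > 0 & scores < 1))
  t <- as.integer(t)
  treated <- which(t == 1L)
  control <- which(t == 0L)
  if (!length(treated) || !length(control)) {
    stop("both arms required", call. = FALSE)
  }
  ord <- with_seed(fanout_seed(seed, 59L), {
    treated[order(-scores[treated], sample(length(treated)))]
  })
  free <- rep(TRUE, length(control))
  pairs <- data.frame(treated = integer(), control = integer(),
                      gap = numeric())
  for (i in ord) {
    open <- which(free)
    if (!length(open)) break
    gaps <- abs(scores[control[open]] - scores[i])
    j <- open[which.min(gaps)]
    if (min(gaps) <= caliper) {
      free[j] <- FALSE
      pairs <- rbind(pairs, data.frame(treated = i, control = control[j],
                                       gap = min(gaps)))
    }
  }
  if (!nrow(pairs)) stop("no matches within the caliper", call. = FALSE)
  list(ate_hat = mean(y[pairs$treated] - y[pairs$control]),
       n_pairs = nrow(pairs),
       n_unmatched = (length(treated) + length(control)) - 2L * nrow(pairs),
       pairs = pairs)
}
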