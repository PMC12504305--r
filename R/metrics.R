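# Causal and classification evaluation: PEHE, ATE error, ITE error,
# regression and classification metrics, and bootstrap mean +/- SE
# aggregation.

#' Precision in estimating heterogeneous effects
#'
#' Root-mean-squared (default) or mean-squared error between estimated and
#' true per-unit treatment effects on the probability scale.
#'
#' @param ite_hat,true_ite Equal-length numeric vectors.
#' @param form `"rmse"` (headline) or `"mse"`.
#' @return A nonnegative number.
#' @export
pehe <- function(ite_hat, true_ite, form = c("rmse", "mse")) {
  form <- match.arg(form)
  check_equal_length(ite_hat, true_ite)
  m <- mean((ite_hat - true_ite)^2)
  if (form == "rmse") sqrt(m) else m
}

#' Absolute error of the average treatment effect
#' @inheritParams pehe
#' @return `|mean(ite_hat) - mean(true_ite)|`.
#' @export
ate_error <- function(ite_hat, true_ite) {
  check_equal_length(ite_hat, true_ite)
  abs(mean(ite_hat) - mean(true_ite))
}

#' Mean absolute error of per-unit effects
#' @inheritParams pehe
#' @return `mean(|ite_hat - true_ite|)`.
#' @export
ite_error <- function(ite_hat, true_ite) {
  check_equal_length(ite_hat, true_ite)
  mean(abs(ite_hat - true_ite))
}

check_equal_length <- function(a, b) {
  if (length(a) != length(b) || !length(a)) {
    stop("inputs must be nonempty vectors of equal length", call. = FALSE)
  }
  invisible(TRUE)
}

#' Regression accuracy metrics
#' @param y_hat Predictions.
#' @param y Observations.
#' @return List with `mse` and `r2` (1 for a perfect fit; can be negative
#'   for predictors worse than the mean).
#' @export
regression_metrics <- function(y_hat, y) {
  check_equal_length(y_hat, y)
  mse <- mean((y_hat - y)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum((y - y_hat)^2) / ss_tot else NA_real_
  list(mse = mse, r2 = r2)
}

#' Classification metrics at a threshold
#'
#' Accuracy, precision, and recall from the confusion matrix at
#' `threshold`, plus the threshold-free AUC (see [roc_auc()]).
#'
#' @param scores Predicted positive-class probabilities.
#' @param labels Binary labels.
#' @param threshold Classification threshold (default 0.5).
#' @return List with `accuracy`, `precision`, `recall`, `auc`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  cm <- confusion_matrix(scores, labels, threshold)
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  list(
    accuracy = (cm$tn + cm$tp) / total,
    precision = if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_,
    recall = if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_,
    auc = roc_auc(scores, labels)$auc
  )
}

#' Bootstrap mean and standard error of a metric
#'
#' Nonparametric bootstrap over the rows of a per-row evaluation frame:
#' `metric_fn` is applied to `n_boot` row-resamples and the mean and
#' standard deviation of the replicates are returned. Replicates on which
#' the metric fails are dropped and counted.
#'
#' @param metric_fn Function `data.frame -> scalar`.
#' @param data Data.frame of per-row quantities (e.g. `ite_hat`,
#'   `true_ite`, predictions, labels).
#' @param n_boot Number of replicates (>= 2).
#' @param seed RNG seed.
#' @return List with `mean`, `se`, `n_boot`, and `n_failed`.
#' @export
bootstrap_mean_se <- function(metric_fn, data, n_boot = 100L, seed = 1L) {
  if (n_boot < 2L) stop("`n_boot` must be >= 2", call. = FALSE)
  data <- as.data.frame(data)
  n <- nrow(data)
  reps <- with_seed(fanout_seed(seed, 61L), {
    vapply(seq_len(n_boot), function(b) {
      rows <- sample.int(n, n, replace = TRUE)
      tryCatch(as.numeric(metric_fn(data[rows, , drop = FALSE])),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  failed <- sum(is.na(reps))
  reps <- reps[!is.na(reps)]
  if (!length(reps)) stop("metric failed on every bootstrap replicate",
                          call. = FALSE)
  list(mean = mean(reps), se = sd(reps), n_boot = n_boot, n_failed = failed)
}

#' Evaluate an effect estimate against simulated ground truth
#'
#' Computes the causal metric block (rmse-PEHE, ATE error, mean-absolute
#' ITE error) and — when observed outcomes and treatment are supplied —
#' the factual prediction block (MSE/R2 of the factual probability
#' predictions, classification metrics of the factual scores). Asserts the
#' triangle inequality `pehe >= ate_error`.
#'
#' @param estimate An [effect_estimate()].
#' @param true_ite True per-unit effects.
#' @param y_obs,t Optional observed outcomes and treatment for the factual
#'   block.
#' @return A list of class `metric_report`.
#' @export
metric_report <- function(estimate, true_ite, y_obs = NULL, t = NULL) {
  out <- list(
    pehe = pehe(estimate$ite_hat, true_ite),
    pehe_mse = pehe(estimate$ite_hat, true_ite, form = "mse"),
    ate_error = ate_error(estimate$ite_hat, true_ite),
    ite_error = ite_error(estimate$ite_hat, true_ite)
  )
  stopifnot(out$pehe >= out$ate_error - 1e-12)
  if (!is.null(y_obs) && !is.null(t)) {
    factual <- ifelse(t == 1L, estimate$mu1_hat, estimate$mu0_hat)
    out <- c(out, regression_metrics(factual, y_obs))
    if (length(unique(y_obs)) == 2L) {
      out <- c(out, classification_metrics(factual, y_obs))
    }
  }
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("PEHE (rmse) %.4f | ATE error %.4f | ITE error %.4f\n",
              x$pehe, x$ate_error, x$ite_error))
  if (!is.null(x$auc)) {
    cat(sprintf("factual: mse %.4f r2 %.3f acc %.3f auc %.3f\n",
                x$mse, x$r2, x$accuracy, x$auc))
  }
  invisible(x)
}
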