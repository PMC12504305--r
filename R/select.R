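# Three-stage variable-selection cascade: univariate association screen,
# L1-penalized logistic regression, recursive feature elimination; plus a
# model-agnostic permutation-importance ranking.

feature_matrix <- function(data, outcome, features = NULL) {
  df <- as_cohort_df(data)
  if (!outcome %in% names(df)) {
    stop(sprintf("outcome column `%s` not found", outcome), call. = FALSE)
  }
  features <- features %||% setdiff(names(df), outcome)
  list(X = as.matrix(df[features]), y = as.integer(df[[outcome]]),
       features = features)
}

#' Univariate association screen
#'
#' Keeps features whose marginal association with the binary outcome has
#' p-value at or below `alpha`: the uncorrected Pearson chi-square for
#' discrete features (at most `max_levels` distinct values), a Wilcoxon
#' rank-sum test otherwise.
#'
#' @param data Cohort or data.frame.
#' @param outcome Outcome column name.
#' @param alpha Significance threshold in (0, 1).
#' @param features Candidate feature columns (default: all but the outcome).
#' @param max_levels Maximum distinct values for a feature to be treated as
#'   discrete.
#' @return Character vector of selected features, with attribute
#'   `"p_values"` (named, all candidates).
#' @export
univariate_screen <- function(data, outcome = "outcome", alpha = 0.05,
                              features = NULL, max_levels = 10L) {
  stopifnot(alpha > 0, alpha <= 1)
  fm <- feature_matrix(data, outcome, features)
  pvals <- vapply(fm$features, function(f) {
    x <- fm$X[, f]
    if (length(unique(x)) <= 1L) return(1)
    if (length(unique(x)) <= max_levels) {
      tab <- table(factor(x), factor(fm$y))
      if (ncol(tab) < 2L) return(1)
      pearson_chi_square(contingency_table(unclass(tab)))$p_value
    } else {
      wilcox.test(x ~ factor(fm$y), exact = FALSE)$p.value
    }
  }, numeric(1))
  selected <- fm$features[pvals <= alpha]
  attr(selected, "p_values") <- pvals
  selected
}

#' L1-penalized logistic selection
#'
#' Fits an L1-penalized logistic regression of the outcome on standardized
#' features and returns the features with nonzero coefficients. When
#' `penalty` is `NULL` the penalty is chosen by k-fold cross-validated
#' deviance (deterministic fold assignment from `seed`).
#'
#' @param data Cohort or data.frame.
#' @param outcome Outcome column name.
#' @param penalty Nonnegative lasso penalty (glmnet's `lambda`); `NULL` for
#'   cross-validated choice; `0` gives the unpenalized logistic fit.
#' @param features Candidate feature columns.
#' @param nfolds Cross-validation folds (when `penalty` is `NULL`).
#' @param seed Seed for the fold assignment.
#' @return List with `coefficients` (named, excluding intercept),
#'   `selected`, and `penalty` (the value used).
#' @export
l1_logistic_select <- function(data, outcome = "outcome", penalty = NULL,
                               features = NULL, nfolds = 5L, seed = 1L) {
  fm <- feature_matrix(data, outcome, features)
  if (!is.null(penalty) && penalty < 0) stop("`penalty` must be >= 0", call. = FALSE)
  if (is.null(penalty)) {
    foldid <- with_seed(fanout_seed(seed, 11L),
                        sample(rep_len(seq_len(nfolds), nrow(fm$X))))
    cv <- glmnet::cv.glmnet(fm$X, fm$y, family = "binomial", alpha = 1,
                            foldid = foldid, standardize = TRUE)
    penalty <- cv$lambda.1se
    fit <- cv$glmnet.fit
    cf <- coef(fit, s = penalty)
  } else {
    fit <- glmnet::glmnet(fm$X, fm$y, family = "binomial", alpha = 1,
                          lambda = penalty, standardize = TRUE,
                          thresh = 1e-10, maxit = 1e6)
    cf <- coef(fit)
  }
  cf <- as.numeric(cf)[-1L]
  names(cf) <- fm$features
  list(coefficients = cf,
       # nonzero up to the solver tolerance
       selected = fm$features[abs(cf) > 1e-8],
       penalty = penalty)
}

default_rfe_model <- function() {
  list(
    fit = function(X, y) {
      suppressWarnings(glm.fit(cbind(1, X), y, family = binomial()))
    },
    importance = function(fit, X, y) {
      cf <- fit$coefficients[-1L]
      cf[is.na(cf)] <- 0
      # absolute standardized coefficient
      abs(cf) * apply(X, 2L, sd)
    }
  )
}

#' Recursive feature elimination
#'
#' Repeatedly refits the supplied model and drops the feature with the
#' smallest importance until `k` features remain. Ties are broken by the
#' declared feature order (the earlier feature is dropped).
#'
#' @param data Cohort or data.frame.
#' @param outcome Outcome column name.
#' @param k Target number of surviving features (1 <= k <= p).
#' @param model A list with `fit(X, y)` and `importance(fit, X, y)`
#'   components; the default is a logistic regression scored by absolute
#'   standardized coefficients.
#' @param features Candidate feature columns.
#' @return List with `selected` (in declared order) and `trace`, a
#'   data.frame recording the feature dropped at each round and its
#'   importance at the time.
#' @export
recursive_feature_elimination <- function(data, outcome = "outcome", k,
                                          model = default_rfe_model(),
                                          features = NULL) {
  fm <- feature_matrix(data, outcome, features)
  p <- length(fm$features)
  if (k < 1L || k > p) stop("`k` must be between 1 and the number of features",
                            call. = FALSE)
  current <- fm$features
  trace <- data.frame(round = integer(), dropped = character(),
                      importance = numeric())
  round <- 0L
  while (length(current) > k) {
    round <- round + 1L
    X <- fm$X[, current, drop = FALSE]
    fit <- model$fit(X, fm$y)
    imp <- model$importance(fit, X, fm$y)
    drop_idx <- which.min(imp)   # which.min is first-minimum: declared order
    trace <- rbind(trace, data.frame(round = round,
                                     dropped = current[drop_idx],
                                     importance = unname(imp[drop_idx])))
    current <- current[-drop_idx]
  }
  list(selected = current, trace = trace)
}

#' Permutation importance ranking
#'
#' Model-agnostic importance: the mean drop in a score when one feature
#' column is shuffled, averaged over `n_repeats` shuffles, normalized by the
#' maximum drop so the strongest predictor scores 1.
#'
#' @param data Cohort or data.frame.
#' @param outcome Outcome column name.
#' @param model A fitted model exposed as `list(predict = function(X) ...)`
#'   returning numeric scores for the positive class.
#' @param n_repeats Shuffles per feature.
#' @param seed RNG seed.
#' @param score Function `(scores, labels) -> scalar`, larger is better;
#'   default is the AUC.
#' @param features Feature columns to rank.
#' @return An `importance_ranking`: data.frame with `feature`, `raw_score`,
#'   `normalized_importance`, sorted by descending importance (ties keep the
#'   declared feature order).
#' @export
permutation_importance <- function(data, outcome = "outcome", model,
                                   n_repeats = 10L, seed = 1L,
                                   score = NULL, features = NULL) {
  fm <- feature_matrix(data, outcome, features)
  score <- score %||% function(s, y) roc_auc(s, y)$auc
  base <- score(model$predict(fm$X), fm$y)
  raw <- with_seed(fanout_seed(seed, 13L), {
    vapply(seq_along(fm$features), function(j) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        Xp <- fm$X
        Xp[, j] <- Xp[sample(nrow(Xp)), j]
        base - score(model$predict(Xp), fm$y)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  names(raw) <- fm$features
  normalized <- if (max(raw) > 0) pmax(raw, 0) / max(raw) else rep(0, length(raw))
  ord <- order(-normalized)   # stable: ties keep declared order
  structure(data.frame(feature = fm$features[ord],
                       raw_score = unname(raw[ord]),
                       normalized_importance = unname(normalized[ord]),
                       row.names = NULL),
            class = c("importance_ranking", "data.frame"))
}

#' Run the full selection cascade
#'
#' Univariate screen, then L1-penalized logistic selection restricted to the
#' survivors, then recursive feature elimination down to `k` features. Each
#' stage's output is a subset of its input.
#'
#' @inheritParams univariate_screen
#' @param k Final number of predictors (default 7).
#' @param seed Seed for the cross-validated penalty.
#' @return List with per-stage survivors (`univariate`, `l1`, `selected`)
#'   and the RFE `trace`.
#' @export
feature_selection_cascade <- function(data, outcome = "outcome", alpha = 0.05,
                                      k = 7L, seed = 1L, features = NULL) {
  s1 <- univariate_screen(data, outcome, alpha = alpha, features = features)
  if (!length(s1)) {
    return(list(univariate = character(), l1 = character(),
                selected = character(), trace = NULL))
  }
  s2 <- l1_logistic_select(data, outcome, features = s1, seed = seed)$selected
  if (!length(s2)) {
    return(list(univariate = as.character(s1), l1 = character(),
                selected = character(), trace = NULL))
  }
  k_eff <- min(k, length(s2))
  s3 <- recursive_feature_elimination(data, outcome, k = k_eff, features = s2)
  list(univariate = as.character(s1), l1 = s2, selected = s3$selected,
       trace = s3$trace)
}
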