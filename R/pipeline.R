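# End-to-end orchestration: simulate or load a cohort, run the association
# screen, the feature-selection cascade, the perceptron classifier, and the
# causal estimator zoo on a stratified 80/20 split; write the report bundle.

# stratified train/test indices; strata is any vector of labels
split_indices <- function(strata, fraction, seed) {
  n <- length(strata)
  train <- integer()
  with_seed(seed, {
    for (s in unique(strata)) {
      rows <- which(strata == s)
      k <- round(length(rows) * fraction)
      k <- max(min(k, length(rows)), 0L)
      train <- c(train, if (k > 0L) sample(rows, k) else integer())
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Stratified train/test split of a cohort
#'
#' Disjoint, exhaustive index sets, stratified on the treatment-by-outcome
#' cells so both the near-balanced allocation and the outcome rate are
#' preserved in each part. Falls back to treatment-only stratification
#' (with a warning) when a cell has fewer than 2 rows.
#'
#' @param cohort A `synthetic_cohort` or `cohort`.
#' @param fraction Training fraction in (0, 1) (default 0.8).
#' @param seed RNG seed.
#' @param stratify_on `"treatment_outcome"` or `"treatment"`.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(cohort, fraction = 0.8, seed = 1L,
                         stratify_on = c("treatment_outcome", "treatment")) {
  stratify_on <- match.arg(stratify_on)
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  }
  strata <- if (stratify_on == "treatment_outcome") {
    s <- paste(cohort$t, cohort$y_obs)
    if (min(table(s)) < 2L) {
      warning("a treatment x outcome stratum has fewer than 2 rows; ",
              "stratifying on treatment only")
      s <- as.character(cohort$t)
    }
    s
  } else {
    as.character(cohort$t)
  }
  split_indices(strata, fraction, fanout_seed(seed, 67L))
}

#' Pipeline configuration
#'
#' @param input `"simulate"` or a path to a cohort CSV (see
#'   [read_cohort()]).
#' @param cohort A [cohort_config()] (required when simulating).
#' @param split Training fraction (default 0.8).
#' @param estimators Named list of estimator specifications; each element
#'   is a list with `type` in `"cfr_wass"`, `"cfr_mmd"`, `"tarnet"`,
#'   `"bayesian_ridge"`, `"lasso"`, `"bagging"`, `"psm"` and optional
#'   type-specific arguments (e.g. `epochs`, `alpha`, `n_estimators`,
#'   `caliper`).
#' @param n_boot Bootstrap replicates for the mean +/- SE grid.
#' @param seed Master seed; per-stage seeds are derived by fixed offsets.
#' @param outdir Output directory for the report bundle.
#' @param mlp_epochs Epochs for the perceptron classifier stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "simulate", cohort = NULL, split = 0.8,
                            estimators = default_estimators(),
                            n_boot = 100L, seed = 1L, outdir = tempfile("cfrlbw_run_"),
                            mlp_epochs = 300L) {
  if (split <= 0 || split >= 1) stop("`split` must be in (0, 1)", call. = FALSE)
  if (!length(estimators)) stop("at least one estimator required", call. = FALSE)
  if (identical(input, "simulate") && is.null(cohort)) {
    cohort <- default_mlcc_config(seed = seed)
  }
  structure(list(input = input, cohort = cohort, split = split,
                 estimators = estimators, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), outdir = outdir,
                 mlp_epochs = as.integer(mlp_epochs)),
            class = "pipeline_config")
}

#' Default estimator set for the comparison grid
#' @param epochs Training epochs for the network estimators.
#' @return Named list of estimator specifications.
#' @export
default_estimators <- function(epochs = 150L) {
  list(
    cfr_wass = list(type = "cfr_wass", epochs = epochs, alpha = 1),
    cfr_mmd = list(type = "cfr_mmd", epochs = epochs, alpha = 1),
    tarnet = list(type = "tarnet", epochs = epochs),
    bayesian_ridge = list(type = "bayesian_ridge"),
    lasso = list(type = "lasso"),
    bagging = list(type = "bagging", n_estimators = 10L)
  )
}

fit_estimator <- function(spec, X, t, y, seed) {
  type <- spec$type
  if (type %in% c("cfr_wass", "cfr_mmd", "tarnet")) {
    cfg <- cfr_config(
      rep_layers = spec$rep_layers %||% c(32L, 32L),
      head_layers = spec$head_layers %||% 16L,
      alpha = if (type == "tarnet") 0 else (spec$alpha %||% 1),
      ipm = switch(type, cfr_wass = "wass", cfr_mmd = "mmd", tarnet = "none"),
      epochs = spec$epochs %||% 150L,
      batch_size = spec$batch_size %||% 128L,
      lr = spec$lr %||% 0.01,
      seed = seed
    )
    fit_cfr(X, t, y, cfg)
  } else if (type == "bayesian_ridge") {
    fit_bayesian_ridge_ite(X, t, y, mode = spec$mode %||% "per_arm")
  } else if (type == "lasso") {
    fit_lasso_outcome(X, t, y, penalty = spec$penalty, seed = seed)
  } else if (type == "bagging") {
    fit_bagging(X, t, y, n_estimators = spec$n_estimators %||% 10L,
                seed = seed)
  } else {
    stop(sprintf("unknown estimator type `%s`", type), call. = FALSE)
  }
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, then writes a report bundle to
#' `config$outdir`: the chi-square association screen
#' (`association.csv`), the permutation-importance ranking
#' (`importance.json`), the perceptron's train/test confusion matrices and
#' ROC points (`mlp_confusion.csv`, `roc.csv`), the estimator metric grid
#' (`metrics.csv`), the bootstrap mean +/- SE grid (`metrics_boot.csv`),
#' and a `manifest.json` recording the seed, package version, and input
#' hash. The run is reproducible from the configuration alone. A stage
#' failure aborts with the stage name after persisting the manifest.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-stage objects and `outdir`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  # stage: cohort
  cohort <- stage("cohort", {
    if (identical(config$input, "simulate")) {
      cfg <- config$cohort
      cfg$seed <- fanout_seed(config$seed, 71L)
      generate_cohort(cfg)
    } else {
      read_cohort(config$input)
    }
  })
  cohort_path <- file.path(config$outdir, "cohort.csv")
  if (inherits(cohort, "synthetic_cohort")) {
    write_cohort(cohort, cohort_path,
                 truth_path = file.path(config$outdir, "cohort_truth.csv"))
  } else {
    write_cohort(structure(list(X = cohort$X, t = cohort$t,
                                y_obs = cohort$y_obs),
                           class = "synthetic_cohort"), cohort_path)
  }
  manifest <- list(
    package = "cfrlbw",
    version = as.character(utils::packageVersion("cfrlbw")),
    seed = config$seed,
    input = if (identical(config$input, "simulate")) "simulate" else config$input,
    input_md5 = unname(tools::md5sum(cohort_path)),
    n = nrow(cohort$X),
    estimators = names(config$estimators)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  # stage: association screen
  screen <- stage("association", association_screen(cohort))
  write_association_report(screen, file.path(config$outdir, "association.csv"))

  # stage: split (no later stage sees test outcomes during fitting)
  idx <- stage("split", split_cohort(cohort, config$split,
                                     seed = config$seed))
  X <- cohort$X
  t <- cohort$t
  y <- cohort$y_obs
  tr <- idx$train
  te <- idx$test

  # stage: perceptron classifier + ranking
  mlp <- stage("mlp", {
    fit <- train_mlp(X[tr, , drop = FALSE], y[tr], hidden = 5L,
                     seed = fanout_seed(config$seed, 73L),
                     epochs = config$mlp_epochs, split = 1)
    scores_te <- predict(fit, X[te, , drop = FALSE])
    roc <- roc_auc(scores_te, y[te])
    cm_rows <- do.call(rbind, lapply(
      list(training = fit$train_confusion,
           testing = confusion_matrix(scores_te, y[te])),
      function(cm) as.data.frame(cm[c("tn", "fp", "fn", "tp")])
    ))
    cm_rows$sample <- rownames(cm_rows)
    cm_rows$overall_pct <- vapply(
      list(fit$train_confusion, confusion_matrix(scores_te, y[te])),
      function(cm) confusion_summary(cm)$overall_pct, numeric(1))
    write.csv(cm_rows, file.path(config$outdir, "mlp_confusion.csv"),
              row.names = FALSE)
    write.csv(roc$curve, file.path(config$outdir, "roc.csv"),
              row.names = FALSE)
    list(fit = fit, auc = roc$auc)
  })
  ranking <- stage("importance", {
    model <- list(predict = function(M) predict(mlp$fit, M))
    rk <- permutation_importance(
      as.data.frame(cbind(X, outcome = y))[te, ], "outcome", model,
      n_repeats = 5L, seed = fanout_seed(config$seed, 79L),
      features = colnames(X))
    jsonlite::write_json(rk, file.path(config$outdir, "importance.json"),
                         digits = NA, pretty = TRUE)
    rk
  })

  # stage: estimator zoo
  truth <- inherits(cohort, "synthetic_cohort")
  grids <- stage("estimate", {
    rows <- list()
    boot_rows <- list()
    for (nm in names(config$estimators)) {
      spec <- config$estimators[[nm]]
      est_seed <- fanout_seed(config$seed, 83L + match(nm, names(config$estimators)))
      if (identical(spec$type, "psm")) {
        ps <- fit_propensity(X[tr, , drop = FALSE], t[tr], model = "logistic")
        # PSM is a within-sample design estimator: report its ATE only
        psm <- psm_ate(y[tr], t[tr], ps$scores,
                       caliper = spec$caliper %||% 0.05, seed = est_seed)
        rows[[nm]] <- data.frame(estimator = nm, pehe = NA, ate_error = if (truth)
          abs(psm$ate_hat - mean(cohort$true_ite[tr])) else NA,
          ite_error = NA, mse = NA, r2 = NA, accuracy = NA, precision = NA,
          recall = NA, auc = NA, ate_hat = psm$ate_hat)
        next
      }
      fit <- fit_estimator(spec, X[tr, , drop = FALSE], t[tr], y[tr], est_seed)
      est <- estimate_effects(fit, X[te, , drop = FALSE])
      if (truth) {
        rep <- metric_report(est, cohort$true_ite[te], y[te], t[te])
        rows[[nm]] <- data.frame(estimator = nm, pehe = rep$pehe,
                                 ate_error = rep$ate_error,
                                 ite_error = rep$ite_error,
                                 mse = rep$mse %||% NA, r2 = rep$r2 %||% NA,
                                 accuracy = rep$accuracy %||% NA,
                                 precision = rep$precision %||% NA,
                                 recall = rep$recall %||% NA,
                                 auc = rep$auc %||% NA,
                                 ate_hat = est$ate_hat)
        df <- data.frame(ite_hat = est$ite_hat, true_ite = cohort$true_ite[te])
        bs <- function(fn) bootstrap_mean_se(fn, df, n_boot = config$n_boot,
                                             seed = est_seed)
        b_pehe <- bs(function(d) pehe(d$ite_hat, d$true_ite))
        b_ite <- bs(function(d) ite_error(d$ite_hat, d$true_ite))
        b_ate <- bs(function(d) ate_error(d$ite_hat, d$true_ite))
        b_atehat <- bs(function(d) mean(d$ite_hat))
        boot_rows[[nm]] <- data.frame(
          estimator = nm,
          pehe_mean = b_pehe$mean, pehe_se = b_pehe$se,
          ite_error_mean = b_ite$mean, ite_error_se = b_ite$se,
          ate_error_mean = b_ate$mean, ate_error_se = b_ate$se,
          ate_hat_mean = b_atehat$mean, ate_hat_se = b_atehat$se)
      } else {
        factual <- ifelse(t[te] == 1L, est$mu1_hat, est$mu0_hat)
        cmx <- classification_metrics(factual, y[te])
        rows[[nm]] <- data.frame(estimator = nm, pehe = NA, ate_error = NA,
                                 ite_error = NA,
                                 mse = regression_metrics(factual, y[te])$mse,
                                 r2 = regression_metrics(factual, y[te])$r2,
                                 accuracy = cmx$accuracy,
                                 precision = cmx$precision,
                                 recall = cmx$recall, auc = cmx$auc,
                                 ate_hat = est$ate_hat)
      }
    }
    list(metrics = do.call(rbind, rows),
         boot = if (length(boot_rows)) do.call(rbind, boot_rows))
  })
  write.csv(grids$metrics, file.path(config$outdir, "metrics.csv"),
            row.names = FALSE)
  if (!is.null(grids$boot)) {
    write.csv(grids$boot, file.path(config$outdir, "metrics_boot.csv"),
              row.names = FALSE)
  }
  invisible(list(cohort = cohort, screen = screen, split = idx, mlp = mlp,
                 ranking = ranking, metrics = grids$metrics,
                 boot = grids$boot, outdir = config$outdir))
}
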