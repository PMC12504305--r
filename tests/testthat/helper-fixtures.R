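# Shared fixtures built in code.

# small bespoke generating process with fully enumerable covariate support:
# three independent binary covariates
tiny_config <- function(n, seed = 1L, effect_intercept = 0.5,
                        treatment_slope = 0.8) {
  covs <- list(
    covariate_spec("a", "binary", 0.3),
    covariate_spec("b", "binary", 0.5),
    covariate_spec("c", "binary", 0.1)
  )
  cohort_config(
    n, covs,
    treatment_coefs = list(intercept = -0.2,
                           coef = c(a = treatment_slope, b = -0.4, c = 0.2)),
    outcome_base_coefs = list(intercept = -0.4,
                              coef = c(a = -1.0, b = 0.6, c = -0.8)),
    effect_coefs = list(intercept = effect_intercept,
                        coef = c(a = 0.7, b = 0, c = -0.3)),
    seed = seed
  )
}

# exact E[mu1 - mu0] for tiny_config by enumerating the 8 covariate cells
tiny_true_ate_exact <- function(cfg) {
  grid <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  pr <- with(grid, (0.3^a * 0.7^(1 - a)) * (0.5) * (0.1^c * 0.9^(1 - c)))
  bc <- cfg$outcome_base_coefs
  ec <- cfg$effect_coefs
  lp0 <- bc$intercept + as.matrix(grid) %*% bc$coef
  lp1 <- lp0 + ec$intercept + as.matrix(grid) %*% ec$coef
  sum(pr * (plogis(lp1) - plogis(lp0)))
}

# the printed contingency tables of the screening analysis (rows = variable
# levels, columns = >=2500 g, <2500 g)
screening_tables <- function() {
  list(
    meconium_aspiration = matrix(c(492, 16, 610, 48), 2),
    apgar_low = matrix(c(393, 115, 477, 181), 2),
    vacuum_assisted = matrix(c(466, 42, 585, 73), 2),
    folic_acid_iron = matrix(c(483, 25, 639, 19), 2),
    pih = matrix(c(484, 24, 609, 49), 2),
    residence = matrix(c(397, 111, 533, 125), 2),
    breastfeeding = matrix(c(121, 387, 173, 485), 2),
    maternal_age = matrix(c(86, 339, 83, 106, 437, 115), 3),
    allocation = matrix(c(250, 258, 334, 324), 2),
    nutrition_counseling = matrix(c(482, 26, 633, 25), 2),
    postnatal_care = matrix(c(213, 163, 119, 13, 295, 200, 148, 15), 4)
  )
}

printed_chi_square <- c(
  meconium_aspiration = 9.496, apgar_low = 3.589, vacuum_assisted = 2.576,
  folic_acid_iron = 3.265, pih = 3.62, residence = 1.446,
  breastfeeding = 0.930, maternal_age = 0.340, allocation = 0.275,
  nutrition_counseling = 1.192, postnatal_care = 1.020
)

# cellwise brute-force Pearson statistic (independent oracle)
chi_square_oracle <- function(counts) {
  n <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      e <- sum(counts[i, ]) * sum(counts[, j]) / n
      stat <- stat + (counts[i, j] - e)^2 / e
    }
  }
  stat
}

# worked-example contribution terms of the feed-forward arithmetic
worked_example_terms <- function() {
  list(
    z1 = c(-0.738, 0.568, -0.245, -0.8149, -0.897, -0.581, 0.1489, 0.99, 0.156),
    z2 = c(0.1229, -0.1538, -0.1694, 0.3538, 0.3494, 0.34939, -0.3857, 0.556, 0.9875)
  )
}

# exhaustive assignment-enumeration Wasserstein oracle for equal-size
# uniform supports
wasserstein_enum_oracle <- function(A, B) {
  k <- nrow(A)
  C <- as.matrix(stats::dist(rbind(A, B)))[seq_len(k), k + seq_len(k), drop = FALSE]
  permn <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in permn(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  min(vapply(permn(seq_len(k)),
             function(p) mean(C[cbind(seq_len(k), p)]), numeric(1)))
}

# tie-corrected Mann-Whitney AUC oracle by explicit pair counting
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
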