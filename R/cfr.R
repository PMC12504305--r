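# Representation-balancing counterfactual regression: a shared
# representation network Phi feeding two arm-specific outcome heads,
# trained on the factual loss plus alpha times an integral probability
# metric (Wasserstein or MMD) between the treated and control
# representation distributions. alpha = 0 recovers TARNet.

#' Configuration for counterfactual regression networks
#'
#' @param rep_layers Widths of the shared representation layers.
#' @param head_layers Widths of the hidden layers of each outcome head.
#' @param alpha Nonnegative weight of the IPM balancing penalty; must be 0
#'   when `ipm = "none"`.
#' @param ipm `"wass"` (entropic Wasserstein), `"mmd"` (biased
#'   Gaussian-kernel MMD^2), or `"none"` (TARNet).
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (stratified by arm).
#' @param seed RNG seed (initialization and batching).
#' @param epsilon Entropic regularization for the Wasserstein penalty;
#'   `NULL` for the per-batch median-cost heuristic.
#' @param sinkhorn_iter Sinkhorn iterations per batch during training.
#' @return An object of class `cfr_config`.
#' @export
cfr_config <- function(rep_layers = c(32L, 32L), head_layers = 16L,
                       alpha = 1, ipm = c("wass", "mmd", "none"),
                       lr = 0.01, epochs = 300L, batch_size = 128L,
                       seed = 1L, epsilon = NULL, sinkhorn_iter = 50L) {
  ipm <- match.arg(ipm)
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (ipm == "none" && alpha != 0) {
    stop("`alpha` must be 0 when ipm = \"none\"", call. = FALSE)
  }
  structure(list(rep_layers = as.integer(rep_layers),
                 head_layers = as.integer(head_layers),
                 alpha = alpha, ipm = ipm, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), epsilon = epsilon,
                 sinkhorn_iter = as.integer(sinkhorn_iter)),
            class = "cfr_config")
}

# -- small dense-stack machinery (ReLU hidden units, He init) --------------

stack_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                    fan_in, sizes[l + 1L]),
         b = numeric(sizes[l + 1L]))
  })
}

# forward through a stack; ReLU on every layer except optionally the last
stack_forward <- function(layers, X, last_linear = TRUE) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  for (l in seq_along(layers)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    acts[[l + 1L]] <- if (l == length(layers) && last_linear) Z else pmax(Z, 0)
  }
  acts
}

# backward pass: dOut is gradient w.r.t. the stack output (post-activation
# of the last layer as produced by stack_forward). Returns per-layer grads
# and the gradient w.r.t. the input.
stack_backward <- function(layers, acts, dOut, last_linear = TRUE) {
  grads <- vector("list", length(layers))
  delta <- dOut
  for (l in rev(seq_along(layers))) {
    if (!(l == length(layers) && last_linear)) {
      delta <- delta * (acts[[l + 1L]] > 0)
    }
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    delta <- delta %*% t(layers[[l]]$W)
  }
  list(grads = grads, dX = delta)
}

adam_state <- function(layers) {
  lapply(layers, function(ly) list(mW = ly$W * 0, vW = ly$W * 0,
                                   mb = ly$b * 0, vb = ly$b * 0))
}

adam_step <- function(layers, grads, state, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    st <- state[[l]]
    st$mW <- beta1 * st$mW + (1 - beta1) * grads[[l]]$W
    st$vW <- beta2 * st$vW + (1 - beta2) * grads[[l]]$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * grads[[l]]$b
    st$vb <- beta2 * st$vb + (1 - beta2) * grads[[l]]$b^2
    layers[[l]]$W <- layers[[l]]$W -
      lr * (st$mW / (1 - beta1^step)) / (sqrt(st$vW / (1 - beta2^step)) + eps)
    layers[[l]]$b <- layers[[l]]$b -
      lr * (st$mb / (1 - beta1^step)) / (sqrt(st$vb / (1 - beta2^step)) + eps)
    state[[l]] <- st
  }
  list(layers = layers, state = state)
}

# -- IPM penalties on a batch of representations ---------------------------

# value and gradient of biased Gaussian MMD^2 between rows of A and B
mmd_value_grad <- function(A, B, bw) {
  m <- nrow(A)
  n <- nrow(B)
  Kaa <- exp(-sq_distances(A, A) / (2 * bw^2))
  Kbb <- exp(-sq_distances(B, B) / (2 * bw^2))
  Kab <- exp(-sq_distances(A, B) / (2 * bw^2))
  value <- sum(Kaa) / m^2 + sum(Kbb) / n^2 - 2 * sum(Kab) / (m * n)
  # d/dA of the three kernel sums (bandwidth treated as a constant)
  gA <- (-2 / (bw^2)) * (
    (A * rowSums(Kaa) - Kaa %*% A) / m^2 -
      (A * rowSums(Kab) - Kab %*% B) / (m * n)
  )
  gB <- (-2 / (bw^2)) * (
    (B * rowSums(Kbb) - Kbb %*% B) / n^2 -
      (B * rowSums(t(Kab)) - t(Kab) %*% A) / (m * n)
  )
  list(value = value, gA = gA, gB = gB)
}

# value and (envelope-theorem) gradient of the entropic Wasserstein-1
# distance between uniform samples A and B
wass_value_grad <- function(A, B, epsilon, iters) {
  m <- nrow(A)
  n <- nrow(B)
  C <- sqrt(sq_distances(A, B))
  if (is.null(epsilon)) {
    pos <- C[C > 0]
    epsilon <- if (length(pos)) 0.1 * median(pos) else 0.1
  }
  res <- suppressWarnings(
    sinkhorn(C, rep(1 / m, m), rep(1 / n, n), epsilon,
             max_iter = iters, tol = 1e-6)
  )
  Tm <- res$plan
  Cg <- C
  Cg[Cg < 1e-12] <- 1e-12
  R <- Tm / Cg
  gA <- A * rowSums(R) - R %*% B          # sum_j T_ij (a_i - b_j) / C_ij
  gB <- B * colSums(R) - t(R) %*% A
  list(value = res$cost, gA = gA, gB = gB)
}

#' Fit a counterfactual regression network
#'
#' Minimizes the arm-reweighted factual cross-entropy plus
#' `alpha * IPM(Phi(X) | t = 1, Phi(X) | t = 0)` by minibatch Adam with
#' arm-stratified batches. With `ipm = "none"` (and `alpha = 0`) this is
#' TARNet; with `"wass"`/`"mmd"` it is CFR-WASS/CFR-MMD. During training
#' the Wasserstein penalty uses entropic Sinkhorn iterations for
#' differentiability; the exact transportation-simplex distance remains
#' available through [wasserstein()] for evaluation.
#'
#' @param X n x p numeric covariate matrix.
#' @param t Binary treatment vector (both arms required).
#' @param y Binary outcome vector (1 = normal birth weight).
#' @param config A [cfr_config()].
#' @return An object of class `cfr_fit` with the network parameters, the
#'   per-epoch training `log` (factual loss and mean batch IPM), and the
#'   configuration. Use [estimate_effects()] or `predict()` for potential
#'   outcome predictions.
#' @export
fit_cfr <- function(X, t, y, config = cfr_config()) {
  X <- as.matrix(X)
  t <- as.integer(t)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(unique(t)) < 2L) {
    stop("both treatment arms must be present", call. = FALSE)
  }
  u <- mean(t)
  # inverse arm-frequency weights stabilize the factual loss
  w <- ifelse(t == 1L, 1 / (2 * u), 1 / (2 * (1 - u)))
  p <- ncol(X)
  with_seed(fanout_seed(config$seed, 31L), {
    rep_net <- stack_init(c(p, config$rep_layers))
    d_rep <- config$rep_layers[length(config$rep_layers)]
    head0 <- stack_init(c(d_rep, config$head_layers, 1L))
    head1 <- stack_init(c(d_rep, config$head_layers, 1L))
    st_rep <- adam_state(rep_net)
    st_h0 <- adam_state(head0)
    st_h1 <- adam_state(head1)
    idx1 <- which(t == 1L)
    idx0 <- which(t == 0L)
    nb <- max(1L, floor(n / config$batch_size))
    log_df <- data.frame(epoch = seq_len(config$epochs),
                         factual_loss = NA_real_, ipm = NA_real_)
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
      s1 <- sample(idx1)
      s0 <- sample(idx0)
      b1 <- split(s1, cut(seq_along(s1), nb, labels = FALSE))
      b0 <- split(s0, cut(seq_along(s0), nb, labels = FALSE))
      ep_loss <- 0
      ep_ipm <- 0
      for (bi in seq_len(nb)) {
        if (bi > length(b1) || bi > length(b0)) next
        batch <- c(b1[[bi]], b0[[bi]])
        if (length(b1[[bi]]) < 1L || length(b0[[bi]]) < 1L) next
        step <- step + 1L
        Xb <- X[batch, , drop = FALSE]
        tb <- t[batch]
        yb <- y[batch]
        wb <- w[batch]
        acts_rep <- stack_forward(rep_net, Xb, last_linear = FALSE)
        Phi <- acts_rep[[length(acts_rep)]]
        i1 <- which(tb == 1L)
        i0 <- which(tb == 0L)
        a0 <- stack_forward(head0, Phi[i0, , drop = FALSE])
        a1 <- stack_forward(head1, Phi[i1, , drop = FALSE])
        z0 <- a0[[length(a0)]]
        z1 <- a1[[length(a1)]]
        p0 <- plogis(z0)
        p1 <- plogis(z1)
        nb_rows <- length(batch)
        loss <- (sum(wb[i0] * bce(p0, yb[i0])) +
                   sum(wb[i1] * bce(p1, yb[i1]))) / nb_rows
        if (!is.finite(loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
               call. = FALSE)
        }
        # factual gradient through the sigmoid heads
        d0 <- matrix(wb[i0] * (p0 - yb[i0]) / nb_rows, ncol = 1L)
        d1 <- matrix(wb[i1] * (p1 - yb[i1]) / nb_rows, ncol = 1L)
        bk0 <- stack_backward(head0, a0, d0)
        bk1 <- stack_backward(head1, a1, d1)
        dPhi <- matrix(0, nb_rows, d_rep)
        dPhi[i0, ] <- bk0$dX
        dPhi[i1, ] <- bk1$dX
        ipm_val <- 0
        if (config$ipm != "none" && length(i1) > 1L && length(i0) > 1L) {
          A <- Phi[i1, , drop = FALSE]
          B <- Phi[i0, , drop = FALSE]
          pen <- if (config$ipm == "mmd") {
            bw <- median_bandwidth(A, B)
            mmd_value_grad(A, B, bw)
          } else {
            wass_value_grad(A, B, config$epsilon, config$sinkhorn_iter)
          }
          ipm_val <- pen$value
          dPhi[i1, ] <- dPhi[i1, ] + config$alpha * pen$gA
          dPhi[i0, ] <- dPhi[i0, ] + config$alpha * pen$gB
        }
        bkr <- stack_backward(rep_net, acts_rep, dPhi, last_linear = FALSE)
        up <- adam_step(head0, bk0$grads, st_h0, config$lr, step)
        head0 <- up$layers; st_h0 <- up$state
        up <- adam_step(head1, bk1$grads, st_h1, config$lr, step)
        head1 <- up$layers; st_h1 <- up$state
        up <- adam_step(rep_net, bkr$grads, st_rep, config$lr, step)
        rep_net <- up$layers; st_rep <- up$state
        ep_loss <- ep_loss + loss
        ep_ipm <- ep_ipm + ipm_val
      }
      log_df$factual_loss[epoch] <- ep_loss / nb
      log_df$ipm[epoch] <- ep_ipm / nb
    }
    structure(list(rep_net = rep_net, head0 = head0, head1 = head1,
                   config = config, log = log_df, p = p),
              class = "cfr_fit")
  })
}

bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Representation of covariates under a fitted CFR network
#' @param fit A `cfr_fit`.
#' @param X Covariate matrix.
#' @return n x d matrix of representation-layer activations.
#' @export
cfr_representation <- function(fit, X) {
  acts <- stack_forward(fit$rep_net, as.matrix(X), last_linear = FALSE)
  acts[[length(acts)]]
}

#' IPM between treated and control representations of a fitted network
#'
#' Evaluates the fitted representation on `X` and measures the discrepancy
#' between arms with the biased Gaussian MMD^2 (`"mmd"`) or the exact (when
#' both arms have at most 64 rows) or entropic Wasserstein distance.
#'
#' @param fit A `cfr_fit`.
#' @param X Covariate matrix.
#' @param t Treatment vector.
#' @param ipm Which metric; defaults to the fit's training metric (a fit
#'   trained with `ipm = "none"` is measured with `"wass"`).
#' @param max_points Per-arm subsample cap for tractability (seeded).
#' @param seed Subsampling seed.
#' @return A single number.
#' @export
representation_ipm <- function(fit, X, t, ipm = NULL, max_points = 256L,
                               seed = 1L) {
  ipm <- ipm %||% if (fit$config$ipm == "none") "wass" else fit$config$ipm
  Phi <- cfr_representation(fit, X)
  i1 <- which(t == 1L)
  i0 <- which(t == 0L)
  with_seed(fanout_seed(seed, 37L), {
    if (length(i1) > max_points) i1 <- sample(i1, max_points)
    if (length(i0) > max_points) i0 <- sample(i0, max_points)
  })
  A <- sample_set(Phi[i1, , drop = FALSE])
  B <- sample_set(Phi[i0, , drop = FALSE])
  if (ipm == "mmd") {
    mmd_squared(A, B, estimator = "biased")
  } else if (nrow(A$points) <= 64L && nrow(B$points) <= 64L) {
    wasserstein(A, B, mode = "exact")
  } else {
    as.numeric(wasserstein(A, B, mode = "entropic", max_iter = 200L))
  }
}

#' @export
predict.cfr_fit <- function(object, newdata, ...) {
  Phi <- cfr_representation(object, newdata)
  z0 <- stack_forward(object$head0, Phi)
  z1 <- stack_forward(object$head1, Phi)
  list(mu0_hat = drop(plogis(z0[[length(z0)]])),
       mu1_hat = drop(plogis(z1[[length(z1)]])))
}
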