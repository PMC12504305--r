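# Integral probability metrics between treated and control representation
# samples: Gaussian-kernel squared maximum mean discrepancy, and order-1
# Wasserstein distance with Euclidean ground cost (exact discrete optimal
# transport via the transportation simplex, or entropically regularized
# Sinkhorn iterations).

#' Weighted sample set
#'
#' A finite set of points in d-dimensional representation space with
#' optional nonnegative weights summing to 1 (uniform when omitted).
#'
#' @param points m x d numeric matrix (a vector is treated as m x 1).
#' @param weights Optional length-m nonnegative weights summing to 1.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(points, weights = NULL) {
  if (!is.matrix(points)) points <- matrix(as.numeric(points), ncol = 1L)
  m <- nrow(points)
  if (m < 1L) stop("sample set must contain at least one point", call. = FALSE)
  if (is.null(weights)) {
    weights <- rep(1 / m, m)
    uniform <- TRUE
  } else {
    if (length(weights) != m || any(weights < 0) ||
        abs(sum(weights) - 1) > 1e-9) {
      stop("`weights` must be nonnegative, length m, and sum to 1",
           call. = FALSE)
    }
    weights <- weights / sum(weights)
    uniform <- all(abs(weights - 1 / m) < 1e-12)
  }
  structure(list(points = points, weights = weights, uniform = uniform),
            class = "sample_set")
}

as_sample_set <- function(x) {
  if (inherits(x, "sample_set")) x else sample_set(x)
}

sq_distances <- function(A, B) {
  # pairwise squared Euclidean distances, m x n
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  D2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(D2, 0)
}

#' Median-distance kernel bandwidth
#'
#' The median of the positive pairwise Euclidean distances over the pooled
#' points of both sets — the usual bandwidth heuristic for the Gaussian
#' kernel.
#'
#' @param a,b Sample sets (or matrices).
#' @return A positive bandwidth (falls back to 1 when all points coincide).
#' @export
median_bandwidth <- function(a, b) {
  P <- rbind(as_sample_set(a)$points, as_sample_set(b)$points)
  d <- sqrt(sq_distances(P, P))
  d <- d[upper.tri(d)]
  d <- d[d > 0]
  if (!length(d)) 1 else median(d)
}

#' Squared maximum mean discrepancy
#'
#' Gaussian-kernel MMD^2 between two weighted sample sets, with kernel
#' `k(x, y) = exp(-||x - y||^2 / (2 * bandwidth^2))`. The biased (V-statistic)
#' estimator is always nonnegative; the unbiased (U-statistic) estimator
#' excludes diagonal terms, requires uniform weights and at least two points
#' per set, and may be slightly negative for close distributions.
#'
#' @param a,b `sample_set`s (or point matrices) of equal dimension.
#' @param bandwidth Positive kernel bandwidth; default is the pooled
#'   median-distance heuristic.
#' @param estimator `"biased"` or `"unbiased"`.
#' @return A single number.
#' @export
mmd_squared <- function(a, b, bandwidth = NULL,
                        estimator = c("biased", "unbiased")) {
  estimator <- match.arg(estimator)
  a <- as_sample_set(a)
  b <- as_sample_set(b)
  if (ncol(a$points) != ncol(b$points)) {
    stop("sample sets have different dimensions", call. = FALSE)
  }
  bandwidth <- bandwidth %||% median_bandwidth(a, b)
  if (bandwidth <= 0) stop("`bandwidth` must be > 0", call. = FALSE)
  gk <- function(A, B) exp(-sq_distances(A, B) / (2 * bandwidth^2))
  Kaa <- gk(a$points, a$points)
  Kbb <- gk(b$points, b$points)
  Kab <- gk(a$points, b$points)
  if (estimator == "biased") {
    drop(a$weights %*% Kaa %*% a$weights) +
      drop(b$weights %*% Kbb %*% b$weights) -
      2 * drop(a$weights %*% Kab %*% b$weights)
  } else {
    m <- nrow(a$points)
    n <- nrow(b$points)
    if (!a$uniform || !b$uniform) {
      stop("unbiased estimator requires uniform weights", call. = FALSE)
    }
    if (m < 2L || n < 2L) {
      stop("unbiased estimator needs at least two points per set", call. = FALSE)
    }
    (sum(Kaa) - sum(diag(Kaa))) / (m * (m - 1)) +
      (sum(Kbb) - sum(diag(Kbb))) / (n * (n - 1)) -
      2 * mean(Kab)
  }
}

# ---- exact discrete optimal transport: transportation simplex ------------

# Solve min sum(T * C) s.t. rowSums(T) = a, colSums(T) = b, T >= 0.
# Northwest-corner initial basis + MODI (u-v) improvement with cycle pivots.
ot_exact <- function(C, a, b, max_pivots = 20000L) {
  m <- length(a)
  n <- length(b)
  a <- a / sum(a)
  b <- b / sum(b)
  # tiny mass perturbation keeps the northwest-corner basis a spanning tree
  # (classic anti-degeneracy device); cost error is O(delta * max cost)
  delta <- 1e-11
  a <- a + delta
  b[n] <- b[n] + m * delta
  # northwest corner initialization
  Tm <- matrix(0, m, n)
  basis <- matrix(FALSE, m, n)
  i <- 1L; j <- 1L
  ra <- a; rb <- b
  while (i <= m && j <= n) {
    x <- min(ra[i], rb[j])
    Tm[i, j] <- x
    basis[i, j] <- TRUE
    ra[i] <- ra[i] - x
    rb[j] <- rb[j] - x
    if (i == m && j == n) break
    if (ra[i] <= rb[j] && i < m) i <- i + 1L else j <- j + 1L
  }
  # ensure basis is a spanning tree with m + n - 1 cells
  while (sum(basis) < m + n - 1L) {
    free <- which(!basis)
    basis[free[1L]] <- TRUE
  }
  tol <- 1e-12 * (1 + max(abs(C)))
  for (pivot in seq_len(max_pivots)) {
    # duals from the basis tree (u[1] = 0)
    u <- rep(NA_real_, m)
    v <- rep(NA_real_, n)
    u[1L] <- 0
    repeat {
      progressed <- FALSE
      for (ii in seq_len(m)) {
        if (is.na(u[ii])) next
        js <- which(basis[ii, ] & is.na(v))
        if (length(js)) { v[js] <- C[ii, js] - u[ii]; progressed <- TRUE }
      }
      for (jj in seq_len(n)) {
        if (is.na(v[jj])) next
        is_ <- which(basis[, jj] & is.na(u))
        if (length(is_)) { u[is_] <- C[is_, jj] - v[jj]; progressed <- TRUE }
      }
      if (!anyNA(u) && !anyNA(v)) break
      if (!progressed) {
        # disconnected basis (degenerate): connect with a zero-flow cell
        ii <- which(is.na(u))[1L]
        if (!is.na(ii)) {
          jj <- which(!is.na(v))[1L]
        } else {
          jj <- which(is.na(v))[1L]
          ii <- which(!is.na(u))[1L]
        }
        basis[ii, jj] <- TRUE
      }
    }
    red <- C - outer(u, v, "+")
    red[basis] <- 0
    ent <- which.min(red)
    if (red[ent] >= -tol) break
    ei <- (ent - 1L) %% m + 1L
    ej <- (ent - 1L) %/% m + 1L
    cyc <- find_cycle(basis, ei, ej)
    # alternate signs along the cycle; entering cell is '+'
    minus <- cyc[seq(2L, nrow(cyc), by = 2L), , drop = FALSE]
    theta_idx <- which.min(Tm[minus])
    theta <- Tm[minus][theta_idx]
    sign <- rep(c(1, -1), length.out = nrow(cyc))
    for (k in seq_len(nrow(cyc))) {
      Tm[cyc[k, 1L], cyc[k, 2L]] <- Tm[cyc[k, 1L], cyc[k, 2L]] + sign[k] * theta
    }
    leave <- minus[theta_idx, ]
    basis[leave[1L], leave[2L]] <- FALSE
    basis[ei, ej] <- TRUE
    Tm[leave[1L], leave[2L]] <- 0
  }
  list(cost = sum(Tm * C), plan = Tm)
}

# Unique alternating cycle created by adding (ei, ej) to the basis tree.
# Returns a k x 2 matrix of (row, col) cells starting at the entering cell,
# alternating row-moves and column-moves.
find_cycle <- function(basis, ei, ej) {
  m <- nrow(basis)
  n <- ncol(basis)
  # search for a path from row ei to col ej through basic cells
  # states: ("r", i) or ("c", j); edges are basic cells
  parent <- list()
  seen_r <- rep(FALSE, m)
  seen_c <- rep(FALSE, n)
  queue <- list(list(kind = "r", idx = ei, path = matrix(numeric(0), 0, 2)))
  seen_r[ei] <- TRUE
  found <- NULL
  while (length(queue)) {
    node <- queue[[1L]]
    queue <- queue[-1L]
    if (node$kind == "r") {
      js <- which(basis[node$idx, ])
      for (j in js) {
        path <- rbind(node$path, c(node$idx, j))
        if (j == ej) { found <- path; break }
        if (!seen_c[j]) {
          seen_c[j] <- TRUE
          queue <- c(queue, list(list(kind = "c", idx = j, path = path)))
        }
      }
      if (!is.null(found)) break
    } else {
      is_ <- which(basis[, node$idx])
      for (i in is_) {
        if (!seen_r[i]) {
          seen_r[i] <- TRUE
          path <- rbind(node$path, c(i, node$idx))
          queue <- c(queue, list(list(kind = "r", idx = i, path = path)))
        }
      }
    }
  }
  if (is.null(found)) stop("internal: no pivot cycle found", call. = FALSE)
  rbind(c(ei, ej), found[rev(seq_len(nrow(found))), , drop = FALSE])
}

# ---- entropic regularization: log-domain Sinkhorn ------------------------

sinkhorn <- function(C, a, b, epsilon, max_iter = 1000L, tol = 1e-9) {
  m <- length(a)
  n <- length(b)
  la <- log(a)
  lb <- log(b)
  f <- numeric(m)
  g <- numeric(n)
  lse_rows <- function(M) {
    mx <- apply(M, 1L, max)
    mx + log(rowSums(exp(M - mx)))
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M <- (outer(f, g, "+") - C) / epsilon
    f <- f + epsilon * (la - lse_rows(M))
    M <- (outer(f, g, "+") - C) / epsilon
    g <- g + epsilon * (lb - lse_rows(t(M)))
    M <- (outer(f, g, "+") - C) / epsilon
    Tm <- exp(M)
    err <- max(abs(rowSums(Tm) - a), abs(colSums(Tm) - b))
    if (err < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("Sinkhorn did not reach marginal tolerance %.1e in %d iterations",
                    tol, max_iter))
  }
  list(cost = sum(Tm * C), plan = Tm, converged = converged)
}

#' Wasserstein distance between sample sets
#'
#' Order-1 Wasserstein distance with Euclidean ground cost. `"exact"` mode
#' solves the discrete optimal-transport linear program (transportation
#' simplex; supports of at most 64 points each). `"entropic"` mode runs
#' log-domain Sinkhorn iterations at regularization `epsilon` and returns
#' the transport cost of the regularized plan, which approaches the exact
#' value as `epsilon` shrinks.
#'
#' @param a,b `sample_set`s (or point matrices) of equal dimension.
#' @param mode `"exact"` or `"entropic"`.
#' @param epsilon Entropic regularization (> 0); default
#'   `0.1 * median positive cost`.
#' @param max_iter Maximum Sinkhorn iterations.
#' @return A single number; in entropic mode the attributes `"converged"`
#'   (logical) record Sinkhorn convergence.
#' @export
wasserstein <- function(a, b, mode = c("exact", "entropic"), epsilon = NULL,
                        max_iter = 1000L) {
  mode <- match.arg(mode)
  a <- as_sample_set(a)
  b <- as_sample_set(b)
  if (ncol(a$points) != ncol(b$points)) {
    stop("sample sets have different dimensions", call. = FALSE)
  }
  keep_a <- a$weights > 0
  keep_b <- b$weights > 0
  a <- sample_set(a$points[keep_a, , drop = FALSE], a$weights[keep_a])
  b <- sample_set(b$points[keep_b, , drop = FALSE], b$weights[keep_b])
  C <- sqrt(sq_distances(a$points, b$points))
  if (mode == "exact") {
    if (nrow(a$points) > 64L || nrow(b$points) > 64L) {
      stop("exact mode supports at most 64 points per set", call. = FALSE)
    }
    ot_exact(C, a$weights, b$weights)$cost
  } else {
    if (is.null(epsilon)) {
      pos <- C[C > 0]
      epsilon <- if (length(pos)) 0.1 * median(pos) else 0.1
    }
    if (epsilon <= 0) stop("entropic mode requires epsilon > 0", call. = FALSE)
    res <- sinkhorn(C, a$weights, b$weights, epsilon, max_iter = max_iter)
    structure(res$cost, converged = res$converged)
  }
}
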