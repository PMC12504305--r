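# Single-hidden-layer perceptron for birth weight classification:
# 7 inputs -> 5 logistic hidden units -> 2 independent sigmoid output units
# (one per birth weight class), trained by gradient descent on per-unit
# binary cross-entropy.

#' Logistic (sigmoid) activation
#'
#' `sigma(z) = 1 / (1 + exp(-z))`, strictly in (0, 1), saturating gracefully
#' for large `|z|`.
#'
#' @param z Numeric vector of pre-activations.
#' @return Probabilities in (0, 1).
#' @export
logistic <- function(z) plogis(z)

#' Compensated sum of contribution terms
#'
#' Left-to-right Kahan-compensated accumulation of a vector of signed
#' contribution terms (input-weight products plus biases), as used in the
#' feed-forward arithmetic of the perceptron.
#'
#' @param terms Nonempty numeric vector.
#' @return The sum as a single number.
#' @export
weighted_sum <- function(terms) {
  if (!length(terms)) stop("`terms` must be nonempty", call. = FALSE)
  s <- 0
  comp <- 0
  for (x in as.numeric(terms)) {
    t <- s + x
    if (abs(s) >= abs(x)) comp <- comp + ((s - t) + x)
    else comp <- comp + ((x - t) + s)
    s <- t
  }
  s + comp
}

#' Perceptron weight container
#'
#' Weights and biases of the p-input / h-hidden / 2-output perceptron with
#' logistic activations throughout. Output unit 1 scores normal birth
#' weight, unit 2 low birth weight.
#'
#' @param input_hidden p x h matrix of input-to-hidden weights.
#' @param hidden_bias Length-h hidden bias vector.
#' @param hidden_output h x 2 matrix of hidden-to-output weights.
#' @param output_bias Length-2 output bias vector.
#' @return An object of class `mlp_weights`.
#' @export
mlp_weights <- function(input_hidden, hidden_bias, hidden_output, output_bias) {
  input_hidden <- as.matrix(input_hidden)
  hidden_output <- as.matrix(hidden_output)
  h <- ncol(input_hidden)
  if (length(hidden_bias) != h || nrow(hidden_output) != h ||
      ncol(hidden_output) != 2L || length(output_bias) != 2L) {
    stop("inconsistent weight shapes", call. = FALSE)
  }
  vals <- c(input_hidden, hidden_bias, hidden_output, output_bias)
  if (!all(is.finite(vals))) stop("weights must be finite", call. = FALSE)
  structure(list(input_hidden = input_hidden,
                 hidden_bias = as.numeric(hidden_bias),
                 hidden_output = hidden_output,
                 output_bias = as.numeric(output_bias),
                 activation = "logistic"),
            class = "mlp_weights")
}

#' Deterministic feed-forward pass
#'
#' `hidden = sigma(x' W1 + b1)`, `outputs = sigma(hidden' W2 + b2)`; the two
#' output units are independent sigmoids (their probabilities need not sum
#' to 1).
#'
#' @param weights An [mlp_weights()] object.
#' @param x Input vector of length `nrow(weights$input_hidden)`, or a matrix
#'   with that many columns (one row per unit).
#' @return For a vector input, a list with `p_nbw`, `p_lbw`, and the
#'   `hidden` activations; for a matrix input, a list of matrices
#'   (`outputs` n x 2, `hidden` n x h).
#' @export
mlp_forward <- function(weights, x) {
  p <- nrow(weights$input_hidden)
  if (is.matrix(x)) {
    if (ncol(x) != p) stop(sprintf("input must have %d columns", p), call. = FALSE)
    H <- plogis(sweep(x %*% weights$input_hidden, 2L, weights$hidden_bias, "+"))
    O <- plogis(sweep(H %*% weights$hidden_output, 2L, weights$output_bias, "+"))
    colnames(O) <- c("nbw", "lbw")
    return(list(outputs = O, hidden = H))
  }
  if (length(x) != p) stop(sprintf("input must have length %d", p), call. = FALSE)
  h <- plogis(drop(x %*% weights$input_hidden) + weights$hidden_bias)
  o <- plogis(drop(h %*% weights$hidden_output) + weights$output_bias)
  list(p_nbw = unname(o[1L]), p_lbw = unname(o[2L]), hidden = unname(h))
}

#' Train the perceptron classifier
#'
#' Full-batch gradient training (Adam) of the single-hidden-layer
#' perceptron on a stratified train/test split. Both output units are fit
#' by binary cross-entropy against complementary targets (unit 1: normal
#' birth weight, unit 2: low birth weight). Classification uses the normal
#' birth weight unit at threshold 0.5. Deterministic given `seed`.
#'
#' @param X n x p numeric feature matrix (encoded 0/1 covariates).
#' @param y Binary labels, 1 = normal birth weight, 0 = low birth weight.
#' @param hidden Number of hidden units (default 5).
#' @param seed RNG seed for initialization and the split.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param split Training fraction of the stratified split (default 0.8); use
#'   `1` to train on all rows (no test confusion matrix).
#' @return An object of class `mlp_fit`: `weights` ([mlp_weights()]),
#'   per-epoch `loss`, `train_confusion`/`test_confusion`
#'   ([confusion_matrix()]), and the split indices.
#' @export
train_mlp <- function(X, y, hidden = 5L, seed = 1L, epochs = 500L,
                      lr = 0.05, split = 0.8) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  n <- nrow(X)
  p <- ncol(X)
  if (split < 1) {
    idx <- split_indices(strata = y, fraction = split,
                         seed = fanout_seed(seed, 21L))
    train_idx <- idx$train
    test_idx <- idx$test
  } else {
    train_idx <- seq_len(n)
    test_idx <- integer()
  }
  Xtr <- X[train_idx, , drop = FALSE]
  ytr <- y[train_idx]
  # targets for the two independent sigmoid units
  Ttr <- cbind(nbw = ytr, lbw = 1L - ytr)

  init <- with_seed(fanout_seed(seed, 22L), {
    list(W1 = matrix(rnorm(p * hidden, sd = 1 / sqrt(p)), p, hidden),
         b1 = numeric(hidden),
         W2 = matrix(rnorm(hidden * 2L, sd = 1 / sqrt(hidden)), hidden, 2L),
         b2 = numeric(2L))
  })
  W1 <- init$W1; b1 <- init$b1; W2 <- init$W2; b2 <- init$b2
  m <- lapply(init, function(w) w * 0)
  v <- lapply(init, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  ntr <- nrow(Xtr)
  loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    H <- plogis(sweep(Xtr %*% W1, 2L, b1, "+"))
    O <- plogis(sweep(H %*% W2, 2L, b2, "+"))
    Oc <- pmin(pmax(O, 1e-12), 1 - 1e-12)
    loss[e] <- -mean(Ttr * log(Oc) + (1 - Ttr) * log(1 - Oc)) * 2
    dZ2 <- (O - Ttr) / ntr
    g <- list(W1 = NULL, b1 = NULL, W2 = crossprod(H, dZ2), b2 = colSums(dZ2))
    dH <- dZ2 %*% t(W2) * H * (1 - H)
    g$W1 <- crossprod(Xtr, dH)
    g$b1 <- colSums(dH)
    for (nm in names(g)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- m[[nm]] / (1 - beta1^e)
      vhat <- v[[nm]] / (1 - beta2^e)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      if (nm == "W1") W1 <- W1 - upd
      else if (nm == "b1") b1 <- b1 - upd
      else if (nm == "W2") W2 <- W2 - upd
      else b2 <- b2 - upd
    }
  }
  weights <- mlp_weights(W1, b1, W2, b2)
  score <- function(idx) mlp_forward(weights, X[idx, , drop = FALSE])$outputs[, "nbw"]
  fit <- list(
    weights = weights,
    loss = loss,
    train_idx = train_idx,
    test_idx = test_idx,
    train_confusion = confusion_matrix(score(train_idx), y[train_idx]),
    test_confusion = if (length(test_idx)) {
      confusion_matrix(score(test_idx), y[test_idx])
    }
  )
  class(fit) <- "mlp_fit"
  fit
}

#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  mlp_forward(object$weights, as.matrix(newdata))$outputs[, "nbw"]
}

#' Confusion matrix at a threshold
#'
#' @param scores Predicted positive-class probabilities.
#' @param labels Binary labels (1 = positive class).
#' @param threshold Classification threshold (default 0.5).
#' @return An object of class `confusion_matrix` with `tn`, `fp`, `fn`, `tp`.
#' @export
confusion_matrix <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  structure(list(tn = sum(pred == 0L & labels == 0L),
                 fp = sum(pred == 1L & labels == 0L),
                 fn = sum(pred == 0L & labels == 1L),
                 tp = sum(pred == 1L & labels == 1L)),
            class = "confusion_matrix")
}

#' Percent-correct summary of a confusion matrix
#'
#' @param cm A [confusion_matrix()] or a list with `tn`, `fp`, `fn`, `tp`.
#' @return List with `overall_pct` and `per_class_pct` (named `negative`,
#'   `positive`), on the percent scale rounded to 1 decimal place.
#' @export
confusion_summary <- function(cm) {
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  if (total < 1) stop("empty confusion matrix", call. = FALSE)
  neg <- cm$tn + cm$fp
  pos <- cm$fn + cm$tp
  list(
    overall_pct = round(100 * (cm$tn + cm$tp) / total, 1L),
    per_class_pct = c(
      negative = if (neg > 0) round(100 * cm$tn / neg, 1L) else NA_real_,
      positive = if (pos > 0) round(100 * cm$tp / pos, 1L) else NA_real_
    )
  )
}

#' ROC curve and AUC
#'
#' Full threshold sweep of the receiver operating characteristic, with the
#' area computed by the trapezoidal rule (equal to the tie-corrected
#' Mann-Whitney probability).
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Binary labels; both classes must be present.
#' @return List with `curve` (data.frame of `fpr`, `tpr` ordered along the
#'   sweep) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("AUC undefined: only one class present", call. = FALSE)
  }
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0L, 1L), direction = "<", quiet = TRUE)
  ord <- order(1 - r$specificities, r$sensitivities)
  list(curve = data.frame(fpr = (1 - r$specificities)[ord],
                          tpr = r$sensitivities[ord]),
       auc = as.numeric(r$auc))
}

#' Write perceptron weights as a parameter-estimate table
#'
#' Long-format CSV with one row per parameter: `block`
#' (`input_hidden` or `hidden_output`), `from` (bias or source unit),
#' `to` (hidden or output unit), `weight`.
#'
#' @param weights An [mlp_weights()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mlp_weights <- function(weights, path) {
  p <- nrow(weights$input_hidden)
  h <- ncol(weights$input_hidden)
  in_names <- rownames(weights$input_hidden) %||% paste0("input_", seq_len(p))
  hid <- paste0("H", seq_len(h))
  out <- c("nbw", "lbw")
  rows <- rbind(
    data.frame(block = "input_hidden", from = "bias",
               to = rep(hid, each = 1L), weight = weights$hidden_bias),
    data.frame(block = "input_hidden",
               from = rep(in_names, times = h),
               to = rep(hid, each = p),
               weight = as.vector(weights$input_hidden)),
    data.frame(block = "hidden_output", from = "bias",
               to = out, weight = weights$output_bias),
    data.frame(block = "hidden_output",
               from = rep(hid, times = 2L),
               to = rep(out, each = h),
               weight = as.vector(weights$hidden_output))
  )
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read perceptron weights written by [write_mlp_weights()]
#' @param path CSV path.
#' @return An [mlp_weights()].
#' @export
read_mlp_weights <- function(path) {
  df <- read.csv(path)
  ih <- df[df$block == "input_hidden" & df$from != "bias", ]
  hid <- unique(ih$to)
  ins <- unique(ih$from)
  W1 <- matrix(ih$weight, nrow = length(ins), ncol = length(hid))
  rownames(W1) <- ins
  b1 <- df[df$block == "input_hidden" & df$from == "bias", "weight"]
  ho <- df[df$block == "hidden_output" & df$from != "bias", ]
  W2 <- matrix(ho$weight, nrow = length(hid), ncol = 2L)
  b2 <- df[df$block == "hidden_output" & df$from == "bias", "weight"]
  mlp_weights(W1, b1, W2, b2)
}
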