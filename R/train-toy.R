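#' Two-class data with robust and non-robust features
#'
#' Fixture for demonstrating robust-training objectives on a linear model.
#' Feature 1 is *robust*: class separation `robust_sep` well above the
#' attack budget. The remaining `dims - 1` features are *non-robust*: each
#' separates the classes by only `nuisance_sep` (below the budget) with
#' low noise, so a plain cross-entropy fit exploits them — and an adversary
#' operating with `epsilon > nuisance_sep / 2` can flip them all, while a
#' robustness-regularized fit learns to rely on feature 1.
#'
#' @param n number of samples.
#' @param dims total feature count (>= 2).
#' @param robust_sep class-mean separation of feature 1 (pixel units).
#' @param nuisance_sep class-mean separation of each remaining feature.
#' @param robust_noise,nuisance_noise per-feature noise SDs.
#' @param seed RNG seed.
#' @return list with `x` (n x dims, clamped to \[0.05, 0.95\]), `y` (1/2).
#' @export
gen_nuisance_classification <- function(n, dims = 10L, robust_sep = 0.5,
                                        nuisance_sep = 0.04,
                                        robust_noise = 0.12,
                                        nuisance_noise = 0.02, seed = 1L) {
  stopifnot(dims >= 2L, n >= 2L)
  with_seed(seed, {
    y <- rep(1:2, length.out = n)
    sgn <- ifelse(y == 2L, 1, -1)
    x <- matrix(0.5, n, dims)
    x[, 1] <- 0.5 + sgn * robust_sep / 2 +
      stats::rnorm(n, sd = robust_noise)
    for (j in 2:dims)
      x[, j] <- 0.5 + sgn * nuisance_sep / 2 +
        stats::rnorm(n, sd = nuisance_noise)
    x <- pmin(pmax(x, 0.05), 0.95)
    list(x = x, y = y, seed = seed)
  })
}

#' Train a linear softmax classifier with plain, TRADES or IGR objectives
#'
#' Full-batch gradient descent on a linear softmax model at toy scale. The
#' `"plain"` objective is cross-entropy; `"trades"` adds the worst-case KL
#' regularizer of [trades_loss()] (inner maximization rerun each epoch at
#' the current weights, perturbation treated as fixed in the parameter
#' gradient, as is standard); `"igr"` adds the finite-difference input
#' gradient penalty of [igr_loss()] (finite-difference point treated as
#' fixed likewise).
#'
#' @param x n x d feature matrix in pixel space.
#' @param y integer labels (1-based, consecutive from 1).
#' @param method `"plain"`, `"trades"` or `"igr"`.
#' @param epochs full-batch gradient steps (default 200).
#' @param lr learning rate (default 1).
#' @param weight_decay l2 penalty on the weights (default 1e-4).
#' @param trades a [trades_config()] (used when `method = "trades"`).
#' @param igr an [igr_config()] (used when `method = "igr"`).
#' @param seed seed for the weight initialization.
#' @return a `model_adapter` ([make_linear_model()]) with the learned
#'   weights; attribute `history` holds the per-epoch training loss.
#' @export
train_toy_classifier <- function(x, y, method = c("plain", "trades", "igr"),
                                 epochs = 200L, lr = 1, weight_decay = 1e-4,
                                 trades = trades_config(beta = 2,
                                                        epsilon = 0.1),
                                 igr = igr_config(), seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x); K <- max(y)
  stopifnot(K >= 2L, all(y %in% seq_len(K)))
  onehot <- matrix(0, n, K); onehot[cbind(seq_len(n), y)] <- 1
  init <- with_seed(seed, list(
    W = matrix(stats::rnorm(d * K, sd = 0.01), d, K),
    b = rep(0, K)))
  W <- init$W; b <- init$b
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    logits <- x %*% W + matrix(b, n, K, byrow = TRUE)
    P <- softmax_rows(logits)
    Gz <- (P - onehot) / n
    gW <- t(x) %*% Gz
    gb <- colSums(Gz)
    loss <- cross_entropy(logits, y)
    if (method == "trades" && trades$beta > 0) {
      adapter <- make_linear_model(W, b)
      v <- trades_inner_max(adapter, x, trades)
      pv <- softmax_rows(v %*% W + matrix(b, n, K, byrow = TRUE))
      u <- log(pmax(pv, 1e-300)) - log(pmax(P, 1e-300))
      klv <- rowSums(pv * u)
      gz_v <- pv * (u - klv) / n
      gz_x <- (P - pv) / n
      gW <- gW + trades$beta * (t(v) %*% gz_v + t(x) %*% gz_x)
      gb <- gb + trades$beta * colSums(gz_v + gz_x)
      loss <- loss + trades$beta * mean(klv)
    } else if (method == "igr" && igr$lambda > 0) {
      gx <- (Gz * n) %*% t(W)                     # per-sample input grads
      nrm <- sqrt(rowSums(gx^2))
      active <- nrm >= 1e-12
      z <- x
      z[active, ] <- z[active, , drop = FALSE] +
        igr$h * gx[active, , drop = FALSE] / nrm[active]
      logits_z <- z %*% W + matrix(b, n, K, byrow = TRUE)
      Pz <- softmax_rows(logits_z)
      lz <- ce_per_sample(logits_z, y)
      lx <- ce_per_sample(logits, y)
      cc <- ifelse(active, (igr$lambda / igr$h^2) * (lz - lx), 0)
      Gz_z <- (Pz - onehot) * cc / n
      Gz_x <- (P - onehot) * cc / n
      gW <- gW + t(z) %*% Gz_z - t(x) %*% Gz_x
      gb <- gb + colSums(Gz_z) - colSums(Gz_x)
      loss <- loss + mean(ifelse(active,
                                 (igr$lambda / (2 * igr$h^2)) * (lz - lx)^2, 0))
    }
    gW <- gW + weight_decay * W
    W <- W - lr * gW
    b <- b - lr * gb
    history[ep] <- loss
  }
  out <- make_linear_model(W, b)
  attr(out, "history") <- history
  out
}
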