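#' Cross-validated PCA eigenspectrum
#'
#' Estimates the stimulus-related (signal) eigenspectrum of a noisy
#' trial-structured response set. Per repeat, trials are randomly
#' partitioned into two equal halves (with one trial dropped at random when
#' the trial count is odd); `X1` and `X2` are the within-half means,
#' column-centered with each half's own mean. The SVD of `X1` gives the
#' eigenvector basis `V`; both halves are projected onto `V` and the j-th
#' cross-validated eigenvalue is the cross-product
#' \deqn{\lambda_j = \sum_i \tilde X^{(1)}_{ij} \tilde X^{(2)}_{ij} / (S - 1).}
#' Because trial noise is independent across the two halves, the noise
#' contribution cancels in expectation and the estimates are unbiased for the
#' signal variances; individual entries can therefore be negative. Spectra
#' are averaged over `n_repeats` random partitions (with exactly 2 trials
#' the split is deterministic and a single pass is performed).
#'
#' @param tensor a [trial_tensor()] with at least 2 trials.
#' @param n_repeats number of random half-splits to average over (default 20).
#' @param seed RNG seed for the trial partitions.
#' @return an `eigenspectrum` object: `variances` (length C, ordered by
#'   component index), `n_components`, `method = "cvPCA"`, `n_repeats`.
#' @seealso [pca_spectrum()] for deterministic responses, [fit_power_law()].
#' @export
cvpca <- function(tensor, n_repeats = 20L, seed = 1L) {
  stopifnot(inherits(tensor, "trial_tensor"))
  if (tensor$T < 2L) stop("cvPCA needs at least 2 trials")
  S <- tensor$S; N <- tensor$N; T <- tensor$T
  C <- min(S - 1L, N)
  half <- T %/% 2L
  deterministic <- (T == 2L)
  reps <- if (deterministic) 1L else n_repeats
  lam <- matrix(0, reps, C)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      perm <- if (deterministic) 1:2 else sample.int(T)
      h1 <- perm[seq_len(half)]
      h2 <- perm[half + seq_len(half)]
      X1 <- trial_mean(tensor, h1)
      X2 <- trial_mean(tensor, h2)
      X1 <- scale(X1, center = TRUE, scale = FALSE)
      X2 <- scale(X2, center = TRUE, scale = FALSE)
      V <- svd(X1, nu = 0, nv = C)$v
      P1 <- X1 %*% V
      P2 <- X2 %*% V
      lam[r, ] <- colSums(P1 * P2) / (S - 1)
    }
  })
  new_eigenspectrum(colMeans(lam), method = "cvPCA",
                    n_repeats = if (deterministic) n_repeats else reps)
}

#' PCA eigenspectrum of deterministic activations
#'
#' Eigenvalues of the column-centered covariance of a stimulus x unit
#' activation matrix, in descending order. Used for model-layer responses,
#' which are deterministic, so cross-validation over trials is unnecessary.
#'
#' @param activations numeric matrix, stimuli x units (>= 2 stimuli).
#' @return an `eigenspectrum` object with `method = "PCA"`.
#' @export
pca_spectrum <- function(activations) {
  activations <- as.matrix(activations)
  stopifnot(nrow(activations) >= 2)
  if (anyNA(activations)) stop("activations contain NA")
  xc <- scale(activations, center = TRUE, scale = FALSE)
  if (all(abs(xc) < .Machine$double.eps * 100))
    stop("rank-0 input: activations are constant across stimuli")
  d <- svd(xc, nu = 0, nv = 0)$d
  lam <- d^2 / (nrow(activations) - 1)
  new_eigenspectrum(lam, method = "PCA", n_repeats = 1L)
}

new_eigenspectrum <- function(variances, method, n_repeats) {
  structure(list(variances = as.numeric(variances),
                 n_components = length(variances),
                 method = method, n_repeats = n_repeats),
            class = "eigenspectrum")
}

#' @export
print.eigenspectrum <- function(x, ...) {
  cat(sprintf("<eigenspectrum:%s> %d components; top 3: %s\n", x$method,
              x$n_components,
              paste(signif(utils::head(x$variances, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Fit a power-law exponent to an eigenspectrum
#'
#' Ordinary least squares on (log j, log lambda_j) restricted to component
#' indices in `index_range`; the exponent alpha is the negative slope. The
#' fit uses natural logarithms (the slope is invariant to the base) and only
#' strictly positive eigenvalues (cross-validated spectra can contain
#' negative entries; these are excluded and counted). The upper index is
#' clipped to the number of available components.
#'
#' @param spectrum an `eigenspectrum` (or bare numeric vector of ordered
#'   variances).
#' @param index_range integer pair (i_lo, i_hi); default `c(10, 999)`, the
#'   standard range for model-layer spectra.
#' @return a `power_law_fit` list: `alpha`, `intercept` (log scale),
#'   `index_range` (after clipping), `r_squared`, `n_points`, `n_excluded`
#'   (non-positive eigenvalues inside the range).
#' @examples
#' fit_power_law((1:2000)^-1.23)$alpha  # 1.23
#' @export
fit_power_law <- function(spectrum, index_range = c(10, 999)) {
  lam <- if (inherits(spectrum, "eigenspectrum")) spectrum$variances
         else as.numeric(spectrum)
  C <- length(lam)
  i_lo <- max(1L, as.integer(index_range[1]))
  i_hi <- min(C, as.integer(index_range[2]))
  if (i_hi < i_lo) stop("index range empty after clipping to the spectrum length")
  j <- i_lo:i_hi
  keep <- lam[j] > 0
  n_excluded <- sum(!keep)
  j <- j[keep]
  if (length(j) < 5L)
    stop(sprintf(
      "need >= 5 positive eigenvalues in index range [%d, %d]; found %d",
      i_lo, i_hi, length(j)))
  fit <- stats::lm(y ~ x, data = data.frame(x = log(j), y = log(lam[j])))
  y <- log(lam[j])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(alpha = -unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 index_range = c(i_lo, i_hi),
                 r_squared = r2,
                 n_points = length(j),
                 n_excluded = n_excluded),
            class = "power_law_fit")
}

#' Reliable component range for a cross-validated spectrum
#'
#' Cross-validated eigenvalues are trustworthy only while the signal
#' eigenvalue stands above the eigenvector-estimation noise scale: to first
#' order in perturbation theory, the eigenvectors of a half-split response
#' matrix are corrupted once the signal eigenvalue falls to the coupling
#' magnitude `sigma_half^2 * sqrt(N / S)`, where `sigma_half^2` is the
#' trial-noise variance of a within-half mean (estimated from the
#' within-stimulus variance across trials). Components below that floor mix
#' with their neighbours, which flattens steep spectra. This helper returns
#' the index range `(i_lo, i_hi)` with `i_hi` the last component whose
#' cross-validated eigenvalue exceeds the floor — the recommended fit range
#' for [fit_power_law()] on [cvpca()] output.
#'
#' @param tensor the [trial_tensor()] the spectrum was estimated from.
#' @param spectrum the [cvpca()] `eigenspectrum`.
#' @param i_lo lower fit index (default 10).
#' @return integer pair `c(i_lo, i_hi)`; attribute `noise_floor` carries the
#'   threshold.
#' @export
reliable_component_range <- function(tensor, spectrum, i_lo = 10L) {
  stopifnot(inherits(tensor, "trial_tensor"),
            inherits(spectrum, "eigenspectrum"))
  # Per-(stimulus, neuron) variance across trials -> per-trial noise
  # variance; a half is a mean of floor(T/2) trials.
  trial_var <- apply(tensor$responses, c(1L, 2L), stats::var)
  sigma2_half <- mean(trial_var) / (tensor$T %/% 2L)
  floor_v <- sigma2_half * sqrt(tensor$N / tensor$S)
  above <- which(spectrum$variances > floor_v)
  i_hi <- if (length(above) > 0L) max(above) else spectrum$n_components
  structure(c(as.integer(i_lo), as.integer(i_hi)), noise_floor = floor_v)
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> alpha = %.4f (indices %d-%d, R^2 = %.3f, %d excluded)\n",
              x$alpha, x$index_range[1], x$index_range[2], x$r_squared,
              x$n_excluded))
  invisible(x)
}
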