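#' Generate trial responses with a planted power-law signal eigenspectrum
#'
#' Constructs a signal matrix `G = A diag(sqrt(s_j)) B'` with `A` (S x K) and
#' `B` (N x K) drawn once per seed from the Haar measure and
#' `s_j` proportional to `j^-alpha`, scaled so the total signal variance is 1
#' per neuron on average. Each trial is `G` plus independent white Gaussian
#' noise of SD `noise_sd`, emulating trial-structured recordings whose signal
#' covariance decays as a power law while the trial noise is white — exactly
#' the regime cvPCA is designed to handle.
#'
#' @param n_stimuli,n_neurons S and N (both >= 2).
#' @param alpha planted power-law exponent (> 0).
#' @param n_trials T (>= 2; cvPCA needs two halves).
#' @param noise_sd trial-noise SD, response units.
#' @param seed RNG seed; the generator is bitwise reproducible.
#' @return a [trial_tensor()] with attribute `planted` carrying the signal
#'   spectrum `s`, `alpha` and the signal matrix dimensions.
#' @examples
#' x <- gen_powerlaw_responses(100, 20, alpha = 1, n_trials = 2, seed = 1)
#' x$S
#' @export
gen_powerlaw_responses <- function(n_stimuli, n_neurons, alpha,
                                   n_trials = 2L, noise_sd = 0.5,
                                   seed = 1L) {
  if (alpha <= 0) stop("`alpha` must be positive")
  if (n_trials < 2L) stop("need >= 2 trials (cvPCA needs two halves)")
  if (n_stimuli < 2L || n_neurons < 2L) stop("need S >= 2 and N >= 2")
  S <- as.integer(n_stimuli); N <- as.integer(n_neurons)
  K <- min(S, N)
  with_seed(seed, {
    s <- (seq_len(K))^(-alpha)
    s <- s * N / sum(s)            # total signal variance N => 1 per neuron
    A <- haar_orthonormal(S, K)
    B <- haar_orthonormal(N, K)
    G <- sqrt(S - 1) * (A %*% (sqrt(s) * t(B)))
    resp <- array(0, c(S, N, n_trials))
    for (t in seq_len(n_trials)) {
      resp[, , t] <- G + if (noise_sd > 0)
        matrix(stats::rnorm(S * N, sd = noise_sd), S, N) else 0
    }
    out <- trial_tensor(resp)
    attr(out, "planted") <- list(s = s, alpha = alpha, signal = G,
                                 noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Ground-truth linear readout for synthetic model neurons
#'
#' Samples readout weights for `n_neurons` linear "V1 neurons" of a model
#' layer. Weights are drawn inside the span of the top `rank` principal
#' components of the layer's features on the supplied images, mirroring the
#' assumption that neural signal lives in the dominant feature dimensions,
#' and guaranteeing the mapping is representable by a low-component
#' regression.
#'
#' @param features stimulus x feature matrix of the source layer.
#' @param n_neurons number of synthetic neurons.
#' @param snr signal-to-noise variance ratio per neuron (> 0).
#' @param n_trials trial count for the generated dataset.
#' @param rank number of leading principal components spanning the readout
#'   (default 15).
#' @param source_layer layer name, metadata only.
#' @param seed RNG seed.
#' @return a `linear_neuron_truth` list with `readout_weights`
#'   (feature x neuron), `snr`, `n_trials`, `source_layer`.
#' @export
make_linear_truth <- function(features, n_neurons, snr = 1, n_trials = 2L,
                              rank = 15L, source_layer = "layer",
                              seed = 1L) {
  stopifnot(snr > 0, n_neurons >= 1)
  features <- as.matrix(features)
  rank <- min(rank, ncol(features), nrow(features) - 1L)
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE, rank. = rank)
  W <- with_seed(seed,
    pc$rotation %*% matrix(stats::rnorm(rank * n_neurons), rank, n_neurons))
  structure(list(readout_weights = W, snr = snr, n_trials = as.integer(n_trials),
                 source_layer = source_layer, rank = rank, seed = seed),
            class = "linear_neuron_truth")
}

#' Generate a synthetic neural dataset with linear ground truth
#'
#' Per-trial responses are a fixed linear readout of a model layer's
#' features plus Gaussian noise scaled to the requested signal-to-noise
#' ratio. The ground-truth map is retained so parameter-recovery tests can
#' check that the noise-corrected predictivity of the generating layer is 1.
#'
#' @param model a `model_adapter`.
#' @param images stimulus batch accepted by the adapter (n >= 2 along the
#'   first dimension).
#' @param truth a [make_linear_truth()] object.
#' @param seed RNG seed for the trial noise.
#' @param layer source layer name; defaults to `truth$source_layer`.
#' @return a `neural_dataset` list: `responses` ([trial_tensor()]),
#'   `features` (the layer features actually used), `truth`,
#'   `reliability_computable` flag.
#' @export
gen_linear_v1_dataset <- function(model, images, truth, seed = 1L,
                                  layer = truth$source_layer) {
  stopifnot(inherits(truth, "linear_neuron_truth"))
  n <- dim(images)[1]
  if (is.null(n) || n < 2L) stop("need at least 2 images")
  check_layer(model, layer)
  acts <- adapter_forward(model, images)$layers[[layer]]
  features <- matrix(acts, nrow = dim(acts)[1])
  if (nrow(truth$readout_weights) != ncol(features))
    stop("readout weights do not match the layer feature dimension")
  signal <- features %*% truth$readout_weights
  sig_sd <- apply(signal, 2L, stats::sd)
  noise_sd <- sig_sd / sqrt(truth$snr)
  T <- truth$n_trials
  with_seed(seed, {
    resp <- array(0, c(n, ncol(signal), max(T, 1L)))
    for (t in seq_len(max(T, 1L))) {
      noise <- matrix(stats::rnorm(length(signal)), nrow(signal), ncol(signal))
      resp[, , t] <- signal + sweep(noise, 2L, noise_sd, `*`)
    }
    structure(list(
      responses = trial_tensor(resp),
      features = features,
      truth = truth,
      reliability_computable = T >= 2L
    ), class = "neural_dataset")
  })
}

#' Two-Gaussian toy classification set with closed-form optimal classifier
#'
#' Samples two Gaussian classes placed symmetrically about pixel value 0.5
#' along a seeded random unit axis, at center-to-center distance `margin`.
#' Inputs live in pixel space: coordinates are clamped to \[0.15, 0.85\], so
#' that small-epsilon attacks never hit the \[0, 1\] clipping bound and the
#' closed-form worst-case analysis of the Bayes-optimal linear classifier is
#' exact, while the attack's clipping path still executes.
#'
#' @param n number of samples (>= 2).
#' @param margin distance between the class means (> 0).
#' @param dims input dimensionality.
#' @param noise_sd isotropic class noise SD.
#' @param seed RNG seed.
#' @return a `toy_classification` list: `x` (n x dims in \[0, 1\]), `y`
#'   (labels 1/2), `w`, `b` (Bayes-optimal linear weights/bias for the
#'   class-2-minus-class-1 logit), `axis` (unit direction), `model`
#'   (a [make_linear_model()] adapter with one logit per class).
#' @export
gen_toy_classification <- function(n, margin, dims = 10L, noise_sd = 0.08,
                                   seed = 1L) {
  if (n < 2) stop("need n >= 2")
  if (margin <= 0) stop("`margin` must be positive")
  with_seed(seed, {
    u <- stats::rnorm(dims)
    u <- u / sqrt(sum(u^2))
    y <- rep(1:2, length.out = n)
    sgn <- ifelse(y == 2L, 1, -1)
    x <- matrix(0.5, n, dims) + outer(sgn * margin / 2, u) +
      matrix(stats::rnorm(n * dims, sd = noise_sd), n, dims)
    x <- pmin(pmax(x, 0.15), 0.85)
    # Bayes-optimal direction for equal isotropic covariances: the axis.
    w_diff <- u
    b_diff <- -sum(u * rep(0.5, dims))
    W <- cbind(-w_diff / 2, w_diff / 2)
    b <- c(-b_diff / 2, b_diff / 2)
    list(x = x, y = y, w = w_diff, b = b_diff, axis = u,
         model = make_linear_model(W, b),
         margin = margin, noise_sd = noise_sd, seed = seed)
  })
}
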