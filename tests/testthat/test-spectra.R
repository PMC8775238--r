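test_that("noise-free cvPCA equals PCA of the trial mean", {
  x <- gen_powerlaw_responses(300, 60, alpha = 1, n_trials = 2,
                              noise_sd = 0, seed = 2)
  cv <- cvpca(x, seed = 1)
  pc <- pca_spectrum(trial_mean(x))
  expect_equal(cv$variances, pc$variances[seq_len(cv$n_components)],
               tolerance = 1e-10)
})

test_that("cvPCA recovers a planted exponent under trial noise", {
  x <- gen_powerlaw_responses(1000, 200, alpha = 1, n_trials = 2,
                              noise_sd = 0.5, seed = 4)
  sp <- cvpca(x, seed = 4)
  rng <- reliable_component_range(x, sp)
  fit <- fit_power_law(sp, rng)
  expect_lt(abs(fit$alpha - 1), 0.05)
})

test_that("pure-noise tensors give cross-validated eigenvalues near zero", {
  set.seed(8)
  x <- trial_tensor(array(rnorm(400 * 40 * 6), c(400, 40, 6)))
  sp <- cvpca(x, n_repeats = 20, seed = 8)
  se <- sd(sp$variances) / sqrt(sp$n_components)
  expect_lt(abs(mean(sp$variances)), 3 * max(se, 1e-6))
})

test_that("cvPCA refuses invalid input", {
  expect_error(cvpca(structure(list(T = 1), class = "trial_tensor")),
               "2 trials")
  bad <- array(rnorm(5 * 4 * 2), c(5, 4, 2)); bad[1, 1, 1] <- NA
  expect_error(trial_tensor(bad), "finite")
})

test_that("PCA spectra match constructed covariances", {
  # rank-1: exactly one nonzero eigenvalue
  u <- rnorm(50); v <- rnorm(8)
  sp1 <- pca_spectrum(outer(u, v))
  expect_equal(sum(sp1$variances > 1e-10 * sp1$variances[1]), 1L)
  # orthogonal columns with known variances
  n <- 40
  q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  q <- scale(q, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(q))                      # orthonormal and centered
  x <- q %*% diag(sqrt(c(4, 1, 0.25) * (n - 1)))
  sp2 <- pca_spectrum(x)
  expect_equal(sp2$variances[1:3], c(4, 1, 0.25), tolerance = 1e-8)
  expect_error(pca_spectrum(matrix(1, 10, 3)), "rank-0")
})

test_that("a Gaussian sample with diagonal power-law covariance yields the right slope", {
  set.seed(10)
  d <- 300
  x <- matrix(rnorm(10000 * d), 10000, d) %*% diag((1:d)^(-0.75))
  fit <- fit_power_law(pca_spectrum(x), c(10, 299))
  expect_lt(abs(fit$alpha - 1.5), 0.05)
})

test_that("total PCA variance is conserved", {
  set.seed(11)
  x <- matrix(rnorm(200 * 30), 200, 30)
  sp <- pca_spectrum(x)
  expect_equal(sum(sp$variances), sum(apply(x, 2, var)), tolerance = 1e-10)
})

test_that("power-law fits are exact on exact power laws and scale invariant", {
  expect_lt(abs(fit_power_law((1:2000)^(-1.23))$alpha - 1.23), 1e-9)
  expect_equal(fit_power_law(5 * (1:2000)^(-2))$alpha, 2, tolerance = 1e-9)
  # multiplicative rescaling leaves the exponent untouched (log-base
  # invariance is the same statement)
  lam <- (1:500)^(-1.4) * exp(rnorm(500, sd = 0.05))
  f1 <- fit_power_law(lam, c(10, 499))
  f2 <- fit_power_law(1000 * lam, c(10, 499))
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-12)
})

test_that("non-positive eigenvalues are excluded and match an independent refit", {
  set.seed(12)
  lam <- (1:200)^(-1.1)
  lam[sample(20:180, 25)] <- -abs(rnorm(25, sd = 1e-4))
  fit <- fit_power_law(lam, c(10, 199))
  keep <- which(lam > 0)
  keep <- keep[keep >= 10 & keep <= 199]
  # independent least squares from first principles
  lx <- log(keep); ly <- log(lam[keep])
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  expect_equal(fit$alpha, -slope, tolerance = 1e-12)
  expect_equal(fit$n_excluded, sum(lam[10:199] <= 0))
  expect_error(fit_power_law(c(1, -1, -1, -1, 0.5), c(1, 5)), ">= 5 positive")
})

test_that("cvPCA beats single-trial PCA at recovering the planted spectrum", {
  wins <- 0
  for (s in 1:20) {
    x <- gen_powerlaw_responses(300, 80, alpha = 1, n_trials = 2,
                                noise_sd = 0.5, seed = s)
    planted <- attr(x, "planted")$s
    top <- seq_len(80 %/% 4)
    cv <- cvpca(x, seed = s)$variances[top]
    pc <- pca_spectrum(x$responses[, , 1])$variances[top]
    if (sum(abs(cv - planted[top])) < sum(abs(pc - planted[top])))
      wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("the fit index range does not change model ranking", {
  fix <- small_cnn_fixture(n_images = 120, canvas = 16, seed = 21)
  feats_cnn <- matrix(adapter_forward(fix$model, fix$images)$layers$conv2,
                      nrow = 120)
  bank <- make_gabor_bank_model(seq(2, 30, length.out = 40), canvas = 64,
                                envelope_sd = 10)
  imgs <- gen_pink_noise_images(120, 64, seed = 22)
  feats_bank <- matrix(adapter_forward(bank, imgs)$layers$gabor, nrow = 120)
  a_cnn <- sapply(list(c(1, 1000), c(10, 999)), function(r)
    fit_power_law(pca_spectrum(feats_cnn), r)$alpha)
  a_bank <- sapply(list(c(1, 1000), c(10, 999)), function(r)
    fit_power_law(pca_spectrum(feats_bank), r)$alpha)
  expect_equal(sign(a_cnn[1] - a_bank[1]), sign(a_cnn[2] - a_bank[2]))
})
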