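test_that("stimulus preprocessing crops, resizes and zero-pads centered", {
  m <- make_tiny_cnn(seed = 1, canvas = 60)
  imgs <- gen_pink_noise_images(2, 100, seed = 2)
  out <- preprocess_stimuli(imgs, m, crop = 80, resize = 20)
  expect_equal(dim(out), c(2, 60, 60))
  center <- 20 + 1:20
  expect_true(all(out[, -center, ] == 0))
  expect_true(all(out[, , -center] == 0))
  expect_true(any(out[, center, center] != 0))
  # crop = resize = canvas: identity
  m2 <- make_tiny_cnn(seed = 1, canvas = 16)
  im2 <- gen_pink_noise_images(1, 16, seed = 3)
  expect_equal(preprocess_stimuli(im2, m2, crop = 16, resize = 16), im2)
  expect_error(preprocess_stimuli(im2, m2, crop = 32), "smaller than")
  # padded zeros normalize to -mean/sd inside the adapter
  spec <- m$input_spec
  expect_equal(v1robust:::normalize_input(0, spec), -spec$mean / spec$sd)
})

test_that("feature reduction is a frozen PCA projection", {
  set.seed(4)
  basis <- matrix(rnorm(300 * 40), 300, 40)
  red <- reduce_features(basis, cap = 1000)
  expect_equal(red$n_components, 40L)     # fewer features than the cap
  proj <- red$project(basis)
  cv <- cov(proj)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  red10 <- reduce_features(basis, cap = 10)
  # reconstruction error from top-k equals the tail eigenvalue sum
  proj10 <- red10$project(basis)
  recon <- proj10 %*% t(red10$rotation)
  centered <- scale(basis, center = TRUE, scale = FALSE)
  err <- sum((centered - recon)^2) / (nrow(basis) - 1)
  lam <- pca_spectrum(basis)$variances
  expect_equal(err, sum(lam[11:length(lam)]), tolerance = 1e-8)
  expect_error(reduce_features(basis, cap = 0), ">= 1")
})

test_that("Spearman-Brown correction follows the closed form", {
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(0.5), 2 / 3)
  expect_error(spearman_brown(-1), "undefined")
})

test_that("neuron reliability matches the snr closed form", {
  # duplicated trials: reliability exactly 1
  set.seed(5)
  base <- matrix(rnorm(100 * 6), 100, 6)
  dup <- trial_tensor(array(c(base, base), c(100, 6, 2)))
  rel <- neuron_reliability(dup)
  expect_equal(rel$reliability, rep(1, 6))
  # snr = 1: split-half r ~ 0.5, corrected ~ 2/3
  fix <- small_cnn_fixture(n_images = 300, seed = 6)
  feats <- matrix(adapter_forward(fix$model, fix$images)$layers$conv1,
                  nrow = 300)
  tr <- make_linear_truth(feats, 40, snr = 1, n_trials = 2, seed = 7)
  ds <- gen_linear_v1_dataset(fix$model, fix$images, tr, seed = 8,
                              layer = "conv1")
  rel2 <- neuron_reliability(ds$responses)
  expect_lt(abs(mean(rel2$split_half_r) - 0.5), 0.05)
  expect_lt(abs(mean(rel2$reliability) - 2 / 3), 0.06)
  # anti-correlated halves are flagged unreliable
  anti <- trial_tensor(array(c(base, -base), c(100, 6, 2)))
  rel3 <- neuron_reliability(anti)
  expect_true(all(rel3$unreliable))
  expect_true(all(is.na(rel3$reliability)))
})

test_that("noiseless linear responses are predicted perfectly", {
  set.seed(9)
  f <- matrix(rnorm(200 * 20), 200, 20)
  y <- f %*% matrix(rnorm(20 * 5), 20, 5)
  ds <- structure(list(responses = trial_tensor(array(c(y, y),
                                                      c(200, 5, 2)))),
                  class = "neural_dataset")
  res <- fit_and_score(f, ds, mapping_spec(n_splits = 5, seed = 1))
  expect_lt(abs(res$median - 1), 1e-6)
})

test_that("breaking the stimulus correspondence destroys predictivity", {
  set.seed(10)
  f <- matrix(rnorm(400 * 20), 400, 20)
  y <- f %*% matrix(rnorm(20 * 8), 20, 8)
  yperm <- y[sample.int(400), ]
  ds <- structure(list(responses = trial_tensor(array(c(yperm, yperm),
                                                      c(400, 8, 2)))),
                  class = "neural_dataset")
  res <- fit_and_score(f, ds, mapping_spec(n_splits = 20, seed = 2))
  expect_lt(abs(res$median), 0.05)
})

test_that("predictivity is invariant to positive affine response transforms", {
  fix <- small_cnn_fixture(n_images = 150, seed = 11)
  feats <- matrix(adapter_forward(fix$model, fix$images)$layers$conv1,
                  nrow = 150)
  tr <- make_linear_truth(feats, 10, snr = 2, n_trials = 2, seed = 12)
  ds <- gen_linear_v1_dataset(fix$model, fix$images, tr, seed = 13,
                              layer = "conv1")
  red <- reduce_features(feats, cap = 100)
  fr <- red$project(feats)
  r1 <- fit_and_score(fr, ds, mapping_spec(n_splits = 5, seed = 3))
  ds2 <- ds
  ds2$responses$responses <- 3 * ds$responses$responses + 2
  r2 <- fit_and_score(fr, ds2, mapping_spec(n_splits = 5, seed = 3))
  expect_equal(r1$per_neuron, r2$per_neuron, tolerance = 1e-8)
})

test_that("noise-corrected predictivity recovers 1 across snr levels", {
  fix <- small_cnn_fixture(n_images = 800, seed = 14)
  feats <- matrix(adapter_forward(fix$model, fix$images)$layers$conv2,
                  nrow = 800)
  fr <- reduce_features(feats, cap = 200)$project(feats)
  for (snr in c(0.5, 1, 4)) {
    tr <- make_linear_truth(feats, 30, snr = snr, n_trials = 2,
                            seed = 15 + round(10 * snr))
    ds <- gen_linear_v1_dataset(fix$model, fix$images, tr,
                                seed = 16 + round(10 * snr), layer = "conv2")
    res <- fit_and_score(fr, ds, mapping_spec(n_splits = 10,
                                              seed = 17 + round(10 * snr)))
    expect_lt(abs(res$median - 1), 0.05)
  }
})

test_that("ridge and PLS rank the generating and mismatched layers identically", {
  fix <- small_cnn_fixture(n_images = 250, seed = 18)
  feats <- matrix(adapter_forward(fix$model, fix$images)$layers$conv2,
                  nrow = 250)
  fr <- reduce_features(feats, cap = 100)$project(feats)
  tr <- make_linear_truth(feats, 20, snr = 1, n_trials = 2, seed = 19)
  ds <- gen_linear_v1_dataset(fix$model, fix$images, tr, seed = 20,
                              layer = "conv2")
  set.seed(21)
  rnd <- matrix(rnorm(length(feats)), nrow(feats), ncol(feats))
  fr_rnd <- reduce_features(rnd, cap = 100)$project(rnd)
  rel <- neuron_reliability(ds$responses)
  ranks <- lapply(c("pls", "ridge"), function(me) {
    a <- fit_and_score(fr, ds, mapping_spec(method = me, n_splits = 5,
                                            seed = 22), reliability = rel)
    b <- fit_and_score(fr_rnd, ds, mapping_spec(method = me, n_splits = 5,
                                                seed = 22), reliability = rel)
    a$median > b$median
  })
  expect_equal(ranks[[1]], ranks[[2]])
  expect_true(ranks[[1]])
})

test_that("bootstrap comparison behaves under null and strong-effect regimes", {
  set.seed(23)
  pn <- rnorm(60, mean = 0.6, sd = 0.1)
  mk <- function(v) structure(list(per_neuron = v, neuron_ids = 1:60),
                              class = "predictivity_result")
  same <- bootstrap_compare(mk(pn), mk(pn + rnorm(60, sd = 1e-6)),
                            n = 2000, seed = 1)
  expect_gt(same$p_one_sided, 0.2)
  expect_lt(same$p_one_sided, 0.8)
  strong <- bootstrap_compare(mk(pn + 1), mk(pn), n = 2000, seed = 1)
  expect_lt(strong$p_one_sided, 0.001)
  expect_error(bootstrap_compare(mk(pn), mk(pn), n = 0), "positive")
  b <- mk(pn); b$neuron_ids <- 61:120
  expect_error(bootstrap_compare(mk(pn), b, n = 10), "different neuron sets")
})

test_that("training sets smaller than the component count are refused", {
  f <- matrix(rnorm(20 * 30), 20, 30)
  y <- matrix(rnorm(20 * 3), 20, 3)
  ds <- structure(list(responses = trial_tensor(array(c(y, y), c(20, 3, 2)))),
                  class = "neural_dataset")
  expect_error(fit_and_score(f, ds, mapping_spec(n_components = 25)),
               "smaller than")
})
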