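test_that("representative responses pick the central unit", {
  m <- small_bank()
  b <- build_stimulus_grid(small_grid(), canvas = 64)
  resp <- representative_responses(m, "gabor", b$stimuli[1:5, , ])
  # 1x1 spatial output: the representative neuron IS the channel output
  fw <- adapter_forward(m, b$stimuli[1:5, , ])
  expect_equal(resp, t(fw$layers$gabor[, , 1, 1]))
  # constant-image batch: identical responses across stimuli
  const <- array(0.3, c(4, 64, 64))
  rc <- representative_responses(m, "gabor", const)
  expect_equal(apply(rc, 1, var), rep(0, nrow(rc)))
})

test_that("tuning curves average over orientation and phase per frequency", {
  g <- small_grid()
  b <- build_stimulus_grid(g, canvas = 64)
  # indicator response of one frequency -> delta curve
  ind <- matrix(as.numeric(b$index$frequency == 10), 1)
  cu <- tuning_curve(ind, b$index, g)
  expect_equal(cu$curves[1, ], as.numeric(g$frequencies == 10))
  expect_equal(preferred_sf(cu, "cycles_per_image"), 10)
  # flat responses -> zero peak-to-peak, excluded
  flat <- matrix(1, 1, nrow(b$index))
  cf <- tuning_curve(flat, b$index, g)
  expect_equal(cf$peak_to_peak, 0)
  expect_true(is.na(preferred_sf(cf)))
  # missing grid cells refuse
  expect_error(tuning_curve(ind[, -1, drop = FALSE], b$index[-1, ], g),
               "missing")
})

test_that("tuning curves are invariant to stimulus order permutation", {
  m <- small_bank()
  g <- small_grid()
  b <- build_stimulus_grid(g, canvas = 64)
  resp <- representative_responses(m, "gabor", b$stimuli)
  set.seed(13)
  perm <- sample.int(ncol(resp))
  cu1 <- tuning_curve(resp, b$index, g)
  cu2 <- tuning_curve(resp[, perm], b$index[perm, ], g)
  expect_equal(cu1$curves, cu2$curves)
})

test_that("preferred frequency ties break toward the lowest frequency", {
  g <- small_grid()
  b <- build_stimulus_grid(g, canvas = 64)
  two_peaks <- matrix(as.numeric(b$index$frequency %in% c(5, 28.3)), 1)
  cu <- tuning_curve(two_peaks, b$index, g)
  # exhaustive check of argmax-with-tie: both maxima equal, lowest wins
  expect_equal(max(cu$curves), cu$curves[g$frequencies == 5])
  expect_equal(preferred_sf(cu, "cycles_per_image"), 5)
})

test_that("Gabor-bank preferred frequencies recover the construction values", {
  m <- small_bank()
  g <- small_grid()
  b <- build_stimulus_grid(g, canvas = 64)
  cu <- tuning_curve(representative_responses(m, "gabor", b$stimuli),
                     b$index, g)
  expect_gte(mean(preferred_sf(cu, "cycles_per_image") ==
                  small_bank_frequencies()), 0.95)
  for (i in seq_len(nrow(cu$curves))) expect_unimodal(cu$curves[i, ])
})

test_that("the SF score is an exact CDF-distance similarity", {
  r <- de_valois_reference()
  expect_equal(r$counts, de_valois_counts())
  expect_equal(sf_score(r, r), 1)
  first <- sf_distribution(counts = c(10, rep(0, 9)))
  last <- sf_distribution(counts = c(rep(0, 9), 10))
  expect_equal(sf_score(first, last), 0)
  # independent brute-force CDF computation
  cnt <- de_valois_counts()
  cdf_ref <- cumsum(cnt) / sum(cnt)
  cdf_unif <- cumsum(rep(1, 10)) / 10
  brute <- 1 - max(abs(cdf_ref - cdf_unif))
  unif <- sf_distribution(counts = rep(1, 10))
  expect_equal(sf_score(r, unif), brute, tolerance = 1e-12)
  expect_equal(sf_score(r, unif), sf_score(unif, r))
  expect_error(sf_score(r, sf_distribution(counts = c(1, 1),
                                           bin_edges = c(0, 1, 2))),
               "bin edges")
})

test_that("binning follows half-open De Valois bins and clips with a warning", {
  d <- sf_distribution(c(0.4, 0.5, 2.0, 8.0, 11.1))
  expect_equal(d$counts, c(1, 1, 0, 0, 0, 1, 0, 0, 0, 2))
  expect_equal(d$cdf[10], 1)
  expect_true(all(diff(d$cdf) >= 0))
  expect_warning(sf_distribution(c(0.1, 3)), "clipping")
})

test_that("in-silico experiments resample channels reproducibly", {
  pref <- cycles_to_cpd(rep(small_bank_frequencies(), times = c(1, 1, 2, 3, 5, 4, 2, 2)), 6.4)
  e1 <- run_insilico_experiments(pref, n_neurons = 50, n_experiments = 50,
                                 seed = 3)
  e2 <- run_insilico_experiments(pref, n_neurons = 50, n_experiments = 50,
                                 seed = 3)
  expect_identical(e1$scores, e2$scores)
  expect_true(all(e1$scores >= 0 & e1$scores <= 1))
  # single channel: every experiment yields the same one-bin distribution
  s1 <- run_insilico_experiments(3.1, n_neurons = 20, n_experiments = 10,
                                 seed = 1)
  expect_equal(length(unique(s1$scores)), 1L)
  expect_equal(sd(s1$scores), 0)
  expect_error(run_insilico_experiments(c(NA_real_, NA_real_)),
               "all channels excluded")
})

test_that("optimal stimuli recover the filter's spatial frequency", {
  m <- make_gabor_bank_model(c(4, 8, 12), canvas = 32, envelope_sd = 8)
  # softmax over one channel is constant 1: zero gradient, input unchanged
  m1 <- make_gabor_bank_model(5, canvas = 32, envelope_sd = 8)
  r1 <- optimal_stimulus(m1, "gabor", 1, steps = 5)
  expect_true(all(r1$objective == 1))
  # objective is a softmax entry: bounded in (0, 1] and increasing overall
  r <- optimal_stimulus(m, "gabor", 2, steps = 150, param = "pixel")
  expect_true(all(r$objective > 0 & r$objective <= 1))
  expect_gt(tail(r$objective, 1), r$objective[1])
  img <- r$image - mean(r$image)
  ft <- Mod(stats::fft(img))
  idx <- which(ft == max(ft), arr.ind = TRUE)[1, ]
  k <- function(i) ifelse(i - 1 <= 16, i - 1, i - 1 - 32)
  dom <- sqrt(k(idx[1])^2 + k(idx[2])^2)
  expect_lte(abs(dom - 8), 4)            # within one grid step (4 -> 8 -> 12)
  expect_error(optimal_stimulus(m, "gabor", 99, steps = 1), "out of range")
})
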