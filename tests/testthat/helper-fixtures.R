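# Shared small fixtures, built in code at test time.

# Reduced Gabor bank + grid that fit a 64-px canvas (Nyquist 32).
small_bank_frequencies <- function() c(2.5, 3.5, 5, 7.1, 10, 14.1, 20, 28.3)

small_bank <- function(freqs = small_bank_frequencies(), canvas = 64) {
  make_gabor_bank_model(freqs, canvas = canvas)
}

small_grid <- function(freqs = small_bank_frequencies()) {
  stimulus_grid(frequencies = freqs)
}

# Tiny CNN + matched pink-noise image batch.
small_cnn_fixture <- function(n_images = 60, canvas = 16, seed = 5) {
  list(model = make_tiny_cnn(seed = seed, canvas = canvas),
       images = gen_pink_noise_images(n_images, canvas, seed = seed + 1))
}

# De Valois reference counts, written out independently of the packaged CSV.
de_valois_counts <- function() c(0, 3, 3, 6, 17, 22, 18, 19, 9, 4)

de_valois_edges <- function() {
  c(0.35, 0.5, 0.7, 1.0, 1.4, 2.0, 2.8, 4.0, 5.6, 8.0, 11.2)
}

# Signed margin of the two-class linear toy model: positive = correct side.
toy_margin <- function(toy) {
  sgn <- ifelse(toy$y == 2L, 1, -1)
  as.numeric(sgn * (toy$x %*% toy$w + toy$b))
}

# Unimodal up to a numerical floor: non-decreasing before the peak and
# non-increasing after, with violations below rel_tol * peak ignored.
expect_unimodal <- function(curve, rel_tol = 1e-3) {
  pk <- which.max(curve)
  tol <- rel_tol * max(curve)
  ok_rise <- all(diff(curve[seq_len(pk)]) >= -tol)
  ok_fall <- all(diff(curve[pk:length(curve)]) <= tol)
  expect_true(ok_rise && ok_fall)
}
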