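#' Model adapter contract
#'
#' A *model adapter* wraps a differentiable image classifier and exposes the
#' surface the analysis pipeline needs: named convolutional-layer activations
#' of shape channels x height x width per stimulus, class logits, and
#' gradients of any scalar function of those quantities with respect to the
#' input. Adapters are deterministic: identical inputs give bit-identical
#' activations across calls.
#'
#' Three synthetic adapters are bundled: [make_gabor_bank_model()] (a single
#' Gabor-filter layer with analytically known spatial-frequency tuning),
#' [make_tiny_cnn()] (a small random-weight CNN for smoke tests), and
#' [make_linear_model()] (a linear softmax classifier used by the robustness
#' fixtures).
#'
#' Gradients are exposed as vector-Jacobian products:
#' `adapter_logits_vjp(adapter, x, g)` returns the gradient with respect to
#' `x` of `sum(g * logits(x))`, and `adapter_layer_vjp(adapter, x, layer, g)`
#' the gradient of `sum(g * activations(x))`. Any scalar objective's input
#' gradient follows by supplying its logit- or activation-space gradient as
#' `g`.
#'
#' @param adapter a `model_adapter` object.
#' @param x input batch: samples along the first array dimension, in the
#'   adapter's native pixel range (normalization is applied internally).
#' @name model_adapter
NULL

#' @rdname model_adapter
#' @export
adapter_forward <- function(adapter, x) {
  stopifnot(inherits(adapter, "model_adapter"))
  UseMethod("adapter_forward")
}

#' @rdname model_adapter
#' @param g gradient of the scalar objective with respect to the logits
#'   (samples x classes matrix) or to the layer activations (same shape as
#'   the activation array).
#' @export
adapter_logits_vjp <- function(adapter, x, g) {
  stopifnot(inherits(adapter, "model_adapter"))
  UseMethod("adapter_logits_vjp")
}

#' @rdname model_adapter
#' @param layer layer name, one of `adapter$layer_names`.
#' @export
adapter_layer_vjp <- function(adapter, x, layer, g) {
  stopifnot(inherits(adapter, "model_adapter"))
  UseMethod("adapter_layer_vjp")
}

#' @export
print.model_adapter <- function(x, ...) {
  cat(sprintf("<model_adapter:%s> layers: %s; canvas %s, %d class(es)\n",
              class(x)[1], paste(x$layer_names, collapse = ", "),
              paste(x$input_spec$canvas, collapse = "x"), x$n_classes))
  invisible(x)
}

check_layer <- function(adapter, layer) {
  if (!layer %in% adapter$layer_names)
    stop(sprintf("unknown layer '%s'; available: %s", layer,
                 paste(adapter$layer_names, collapse = ", ")))
}

# Coerce an image batch to (n, H, W); a single matrix becomes a batch of 1.
as_image_batch <- function(x, canvas) {
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  stopifnot(length(dim(x)) == 3L)
  if (!identical(as.integer(dim(x)[2:3]), as.integer(c(canvas, canvas))))
    stop(sprintf("expected %dx%d images, got %dx%d",
                 canvas, canvas, dim(x)[2], dim(x)[3]))
  x
}

normalize_input <- function(x, spec) (x - spec$mean) / spec$sd


# ---------------------------------------------------------------------------
# Linear softmax adapter (flat feature-vector inputs)

#' Linear softmax classifier adapter
#'
#' Wraps fixed weights `W` (features x classes) and bias `b` as a
#' `model_adapter` over flat inputs (samples x features). The single layer
#' `"features"` exposes the (normalized) input itself, so the adapter can
#' stand in for a one-layer model in pipeline tests. Used as the target model
#' for the closed-form adversarial-attack oracles and the toy training loops.
#'
#' @param W numeric matrix, features x classes.
#' @param b numeric bias vector, length = number of classes.
#' @param input_range valid pixel interval, default `c(0, 1)`.
#' @param mean,sd input normalization constants.
#' @return a `model_adapter`.
#' @export
make_linear_model <- function(W, b = rep(0, ncol(W)), input_range = c(0, 1),
                              mean = 0, sd = 1) {
  stopifnot(is.matrix(W), length(b) == ncol(W), all(is.finite(W)))
  structure(
    list(
      layer_names = "features",
      input_spec = list(canvas = nrow(W), channels = 1L,
                        range = input_range, mean = mean, sd = sd),
      n_classes = ncol(W), W = W, b = b
    ),
    class = c("linear_adapter", "model_adapter")
  )
}

as_flat_batch <- function(x, d) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  stopifnot(is.matrix(x), ncol(x) == d)
  x
}

#' @export
adapter_forward.linear_adapter <- function(adapter, x) {
  x <- as_flat_batch(x, nrow(adapter$W))
  xn <- normalize_input(x, adapter$input_spec)
  logits <- xn %*% adapter$W + matrix(adapter$b, nrow(xn), length(adapter$b),
                                      byrow = TRUE)
  feats <- array(xn, c(nrow(xn), ncol(xn), 1L, 1L))
  list(layers = list(features = feats), logits = logits)
}

#' @export
adapter_logits_vjp.linear_adapter <- function(adapter, x, g) {
  x <- as_flat_batch(x, nrow(adapter$W))
  stopifnot(is.matrix(g), nrow(g) == nrow(x), ncol(g) == adapter$n_classes)
  (g %*% t(adapter$W)) / adapter$input_spec$sd
}

#' @export
adapter_layer_vjp.linear_adapter <- function(adapter, x, layer, g) {
  check_layer(adapter, layer)
  x <- as_flat_batch(x, nrow(adapter$W))
  g <- array(g, c(nrow(x), ncol(x)))
  g / adapter$input_spec$sd
}


# ---------------------------------------------------------------------------
# Gabor-bank adapter

#' Gabor filter bank adapter with known preferred spatial frequencies
#'
#' Builds a one-layer model whose channels are centered Gabor filters at the
#' requested spatial frequencies (cycles/image), orientation 0. In the
#' default quadrature-energy variant a channel responds with the amplitude
#' `sqrt(e^2 + o^2)` of an even/odd (cosine/sine phase) filter pair, making
#' the response invariant to stimulus phase, so each channel's preferred
#' spatial frequency is its construction frequency by design. With
#' `phase_invariance = FALSE` channels are half-rectified linear responses of
#' the even filter. Filters are mean-subtracted (zero DC response) and
#' l2-normalized. A fixed random linear head provides logits so that
#' gradient-based attacks are runnable against the adapter.
#'
#' @param channel_frequencies preferred frequencies in cycles/image, one per
#'   channel; must be positive and below the canvas Nyquist (canvas/2).
#' @param canvas square canvas size in pixels (even).
#' @param envelope_sd Gaussian envelope SD of the filters, pixels.
#' @param phase_invariance logical; quadrature-energy (default) vs
#'   half-rectified linear channels.
#' @param field_of_view assumed field of view in degrees (metadata used when
#'   converting to cycles/degree; default 6.4).
#' @param head_seed seed for the fixed random classification head.
#' @return a `model_adapter` with one layer `"gabor"` whose activations are
#'   channels x 1 x 1 per stimulus.
#' @examples
#' m <- make_gabor_bank_model(c(5, 10, 20), canvas = 64, envelope_sd = 10)
#' out <- adapter_forward(m, array(0.5, c(1, 64, 64)))
#' dim(out$layers$gabor)
#' @export
make_gabor_bank_model <- function(channel_frequencies, canvas = 128,
                                  envelope_sd = 35 * canvas / 224,
                                  phase_invariance = TRUE,
                                  field_of_view = 6.4, head_seed = 99L) {
  stopifnot(length(channel_frequencies) >= 1L, all(channel_frequencies > 0))
  if (canvas %% 2L != 0L) stop("`canvas` must be even")
  if (any(channel_frequencies >= canvas / 2))
    stop("channel frequencies must be below the canvas Nyquist (canvas/2 cycles/image)")
  C <- length(channel_frequencies)
  even <- matrix(0, C, canvas * canvas)
  odd <- matrix(0, C, canvas * canvas)
  for (ci in seq_len(C)) {
    lam <- canvas / channel_frequencies[ci]
    ge <- gabor_image(gabor_params(canvas = canvas, wavelength = lam,
                                   sigma = envelope_sd, phase = 0))
    go <- gabor_image(gabor_params(canvas = canvas, wavelength = lam,
                                   sigma = envelope_sd, phase = -pi / 2))
    ge <- ge - mean(ge); go <- go - mean(go)
    even[ci, ] <- ge / sqrt(sum(ge^2))
    odd[ci, ] <- go / sqrt(sum(go^2))
  }
  head <- with_seed(head_seed, {
    list(W = matrix(stats::rnorm(C * 2, sd = 1 / sqrt(C)), C, 2),
         b = c(0, 0))
  })
  structure(
    list(
      layer_names = "gabor",
      input_spec = list(canvas = canvas, channels = 1L, range = c(0, 1),
                        mean = 0.5, sd = 0.5),
      n_classes = 2L,
      channel_frequencies = channel_frequencies,
      field_of_view = field_of_view,
      phase_invariance = phase_invariance,
      even = even, odd = odd, head = head
    ),
    class = c("gabor_bank_adapter", "model_adapter")
  )
}

gabor_bank_channels <- function(adapter, x) {
  x <- as_image_batch(x, adapter$input_spec$canvas)
  n <- dim(x)[1]
  xn <- normalize_input(x, adapter$input_spec)
  xf <- matrix(xn, nrow = n)                      # n x (H*W), column-major
  ve <- xf %*% t(adapter$even)                    # n x C
  if (adapter$phase_invariance) {
    vo <- xf %*% t(adapter$odd)
    list(act = sqrt(ve^2 + vo^2), ve = ve, vo = vo)
  } else {
    list(act = pmax(ve, 0), ve = ve, vo = NULL)
  }
}

#' @export
adapter_forward.gabor_bank_adapter <- function(adapter, x) {
  ch <- gabor_bank_channels(adapter, x)
  n <- nrow(ch$act); C <- ncol(ch$act)
  logits <- ch$act %*% adapter$head$W +
    matrix(adapter$head$b, n, 2, byrow = TRUE)
  list(layers = list(gabor = array(ch$act, c(n, C, 1L, 1L))),
       logits = logits)
}

# Gradient of sum(g * channel activations) w.r.t. the raw input batch.
gabor_bank_channel_vjp <- function(adapter, x, g_act) {
  ch <- gabor_bank_channels(adapter, x)
  if (adapter$phase_invariance) {
    amp <- pmax(ch$act, 1e-12)
    ge <- g_act * ch$ve / amp
    go <- g_act * ch$vo / amp
    gx <- ge %*% adapter$even + go %*% adapter$odd
  } else {
    ge <- g_act * (ch$ve > 0)
    gx <- ge %*% adapter$even
  }
  canvas <- adapter$input_spec$canvas
  array(gx, c(nrow(gx), canvas, canvas)) / adapter$input_spec$sd
}

#' @export
adapter_logits_vjp.gabor_bank_adapter <- function(adapter, x, g) {
  stopifnot(is.matrix(g), ncol(g) == 2L)
  gabor_bank_channel_vjp(adapter, x, g %*% t(adapter$head$W))
}

#' @export
adapter_layer_vjp.gabor_bank_adapter <- function(adapter, x, layer, g) {
  check_layer(adapter, layer)
  x <- as_image_batch(x, adapter$input_spec$canvas)
  C <- nrow(adapter$even)
  g <- array(g, c(dim(x)[1], C))
  gabor_bank_channel_vjp(adapter, x, g)
}


# ---------------------------------------------------------------------------
# Tiny CNN adapter: conv(3x3) -> relu -> conv(3x3) -> relu -> mean pool -> fc

# Valid 2-d convolution of a batch (n, Cin, H, W) with weights
# (Cout, Cin, k, k); returns (n, Cout, H-k+1, W-k+1).
conv2d_forward <- function(x, w) {
  dn <- dim(x); dw <- dim(w)
  n <- dn[1]; cin <- dn[2]; H <- dn[3]; W <- dn[4]
  cout <- dw[1]; k <- dw[3]
  Ho <- H - k + 1L; Wo <- W - k + 1L
  out <- array(0, c(n, cout, Ho, Wo))
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    xs <- x[, , di:(di + Ho - 1L), dj:(dj + Wo - 1L), drop = FALSE]
    xm <- matrix(aperm(xs, c(1, 3, 4, 2)), ncol = cin)  # (n*Ho*Wo) x Cin
    wm <- matrix(w[, , di, dj], nrow = cout)             # Cout x Cin
    om <- xm %*% t(wm)                                   # (n*Ho*Wo) x Cout
    out <- out + aperm(array(om, c(n, Ho, Wo, cout)), c(1, 4, 2, 3))
  }
  out
}

# Gradient of conv2d_forward w.r.t. its input, given upstream grad
# g of shape (n, Cout, Ho, Wo).
conv2d_input_grad <- function(g, w, H, W) {
  dg <- dim(g); dw <- dim(w)
  n <- dg[1]; cout <- dg[2]; Ho <- dg[3]; Wo <- dg[4]
  cin <- dw[2]; k <- dw[3]
  gx <- array(0, c(n, cin, H, W))
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    gm <- matrix(aperm(g, c(1, 3, 4, 2)), ncol = cout)   # (n*Ho*Wo) x Cout
    wm <- matrix(w[, , di, dj], nrow = cout)             # Cout x Cin
    cm <- gm %*% wm                                      # (n*Ho*Wo) x Cin
    add <- aperm(array(cm, c(n, Ho, Wo, cin)), c(1, 4, 2, 3))
    gx[, , di:(di + Ho - 1L), dj:(dj + Wo - 1L)] <-
      gx[, , di:(di + Ho - 1L), dj:(dj + Wo - 1L), drop = FALSE] + add
  }
  gx
}

#' Small fixed-weight convolutional adapter
#'
#' Two valid 3x3 convolutional layers (`"conv1"`, `"conv2"`) with ReLU,
#' global average pooling and a linear classification head, all weights
#' drawn once from a seeded Gaussian and then frozen. Serves as a cheap,
#' fully differentiable stand-in model for pipeline and attack smoke tests.
#'
#' @param seed integer RNG seed fixing the weights.
#' @param canvas input size in pixels (square).
#' @param channels1,channels2 channel counts of the two conv layers.
#' @param n_classes number of output classes.
#' @return a `model_adapter` with layers `"conv1"` and `"conv2"`.
#' @export
make_tiny_cnn <- function(seed = 1L, canvas = 20L, channels1 = 6L,
                          channels2 = 8L, n_classes = 4L) {
  k <- 3L
  par <- with_seed(seed, list(
    w1 = array(stats::rnorm(channels1 * 1 * k * k, sd = 0.5),
               c(channels1, 1L, k, k)),
    b1 = stats::rnorm(channels1, sd = 0.1),
    w2 = array(stats::rnorm(channels2 * channels1 * k * k,
                            sd = 0.5 / sqrt(channels1)),
               c(channels2, channels1, k, k)),
    b2 = stats::rnorm(channels2, sd = 0.1),
    Wh = matrix(stats::rnorm(channels2 * n_classes, sd = 1 / sqrt(channels2)),
                channels2, n_classes),
    bh = stats::rnorm(n_classes, sd = 0.1)
  ))
  structure(
    list(
      layer_names = c("conv1", "conv2"),
      input_spec = list(canvas = canvas, channels = 1L, range = c(0, 1),
                        mean = 0.5, sd = 0.5),
      n_classes = n_classes, par = par, k = k
    ),
    class = c("tiny_cnn_adapter", "model_adapter")
  )
}

tiny_cnn_pass <- function(adapter, x) {
  x <- as_image_batch(x, adapter$input_spec$canvas)
  n <- dim(x)[1]
  xn <- array(normalize_input(x, adapter$input_spec),
              c(n, 1L, dim(x)[2], dim(x)[3]))
  p <- adapter$par
  z1 <- conv2d_forward(xn, p$w1)
  z1 <- sweep(z1, 2L, p$b1, `+`)
  a1 <- pmax(z1, 0)
  z2 <- conv2d_forward(a1, p$w2)
  z2 <- sweep(z2, 2L, p$b2, `+`)
  a2 <- pmax(z2, 0)
  pooled <- apply(a2, c(1L, 2L), mean)
  pooled <- matrix(pooled, nrow = n)
  logits <- pooled %*% p$Wh + matrix(p$bh, n, adapter$n_classes, byrow = TRUE)
  list(xn = xn, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
       pooled = pooled, logits = logits)
}

#' @export
adapter_forward.tiny_cnn_adapter <- function(adapter, x) {
  f <- tiny_cnn_pass(adapter, x)
  list(layers = list(conv1 = f$a1, conv2 = f$a2), logits = f$logits)
}

# Backprop from an upstream gradient on conv2 activations (post-ReLU).
tiny_cnn_backprop_from_a2 <- function(adapter, f, g_a2) {
  p <- adapter$par
  g_z2 <- g_a2 * (f$z2 > 0)
  d1 <- dim(f$a1)
  g_a1 <- conv2d_input_grad(g_z2, p$w2, d1[3], d1[4])
  g_z1 <- g_a1 * (f$z1 > 0)
  dx <- dim(f$xn)
  g_xn <- conv2d_input_grad(g_z1, p$w1, dx[3], dx[4])
  array(g_xn, dim(f$xn)[c(1, 3, 4)]) / adapter$input_spec$sd
}

#' @export
adapter_logits_vjp.tiny_cnn_adapter <- function(adapter, x, g) {
  f <- tiny_cnn_pass(adapter, x)
  stopifnot(is.matrix(g), ncol(g) == adapter$n_classes)
  p <- adapter$par
  g_pooled <- g %*% t(p$Wh)                       # n x C2
  d2 <- dim(f$a2)
  g_a2 <- array(rep(g_pooled, times = d2[3] * d2[4]) / (d2[3] * d2[4]), d2)
  tiny_cnn_backprop_from_a2(adapter, f, g_a2)
}

#' @export
adapter_layer_vjp.tiny_cnn_adapter <- function(adapter, x, layer, g) {
  check_layer(adapter, layer)
  f <- tiny_cnn_pass(adapter, x)
  p <- adapter$par
  if (layer == "conv2") {
    g <- array(g, dim(f$a2))
    return(tiny_cnn_backprop_from_a2(adapter, f, g))
  }
  g <- array(g, dim(f$a1))
  g_z1 <- g * (f$z1 > 0)
  dx <- dim(f$xn)
  g_xn <- conv2d_input_grad(g_z1, p$w1, dx[3], dx[4])
  array(g_xn, dim(f$xn)[c(1, 3, 4)]) / adapter$input_spec$sd
}
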