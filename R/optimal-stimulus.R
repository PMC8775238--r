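#' Synthesize the optimal stimulus for a channel
#'
#' Gradient ascent on the softmax, across channels, of the spatially
#' averaged activations of a convolutional layer:
#' \deqn{g(X, i) = \frac{\exp(\bar X_i)}{\sum_c \exp(\bar X_c)}, \qquad
#'   \bar X_c = \frac{1}{HW} \sum_{h,w} X[c, h, w],}
#' maximized for the target channel `i` with Adam (learning rate 0.05).
#' By default the image is parameterized by its discrete Fourier transform
#' (the update is performed on the complex spectrum and the image is its
#' real inverse transform), which preconditions the ascent toward the
#' frequency content the filter prefers; a direct pixel parameterization is
#' available for tests.
#'
#' @param model a `model_adapter`.
#' @param layer convolutional layer name.
#' @param channel 1-based channel index to maximize.
#' @param steps number of ascent steps.
#' @param lr Adam learning rate (default 0.05).
#' @param param `"fourier"` (default) or `"pixel"` input parameterization.
#' @param init optional initial image (canvas x canvas matrix); defaults to
#'   mid-gray plus a small seeded perturbation.
#' @param seed seed for the default initialization.
#' @return list with `image` (canvas x canvas matrix, clipped to the model's
#'   pixel range), `objective` (per-step values of `g`).
#' @export
optimal_stimulus <- function(model, layer, channel, steps = 100L, lr = 0.05,
                             param = c("fourier", "pixel"), init = NULL,
                             seed = 1L) {
  check_layer(model, layer)
  param <- match.arg(param)
  canvas <- model$input_spec$canvas
  probe <- adapter_forward(model, array(0.5, c(1L, canvas, canvas)))
  C <- dim(probe$layers[[layer]])[2]
  if (channel < 1L || channel > C)
    stop(sprintf("channel index %d out of range (layer has %d channels)",
                 channel, C))
  x0 <- init %||% with_seed(seed,
    matrix(0.5 + stats::rnorm(canvas^2, sd = 0.01), canvas, canvas))
  rng <- model$input_spec$range

  # d g / d activations for the softmax-of-spatial-mean objective.
  objective_grad <- function(acts) {
    d <- dim(acts)                       # 1 x C x H x W
    means <- apply(array(acts, d[2:4]), 1L, mean)
    p <- exp(means - max(means)); p <- p / sum(p)
    gbar_mean <- -p[channel] * p
    gbar_mean[channel] <- gbar_mean[channel] + p[channel]
    g <- array(0, d)
    for (c in seq_len(d[2])) g[1, c, , ] <- gbar_mean[c] / (d[3] * d[4])
    list(g = g, value = p[channel])
  }

  adam <- function(grad_fn, theta0, transform) {
    m <- v <- theta0 * 0
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    theta <- theta0
    obj <- numeric(steps)
    for (t in seq_len(steps)) {
      xt <- transform(theta)
      batch <- array(xt, c(1L, canvas, canvas))
      acts <- adapter_forward(model, batch)$layers[[layer]]
      og <- objective_grad(acts)
      obj[t] <- og$value
      gx <- adapter_layer_vjp(model, batch, layer, og$g)
      gx <- matrix(gx[1, , ], canvas, canvas)
      gt <- if (is.complex(theta)) stats::fft(gx) / length(gx) else gx
      m <- beta1 * m + (1 - beta1) * gt
      v <- beta2 * v + (1 - beta2) * abs(gt)^2
      mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
      theta <- theta + lr * mh / (sqrt(vh) + eps)   # ascent
    }
    list(theta = theta, obj = obj)
  }

  if (param == "pixel") {
    res <- adam(NULL, x0, function(th) pmin(pmax(th, rng[1]), rng[2]))
    img <- pmin(pmax(res$theta, rng[1]), rng[2])
  } else {
    z0 <- stats::fft(x0)
    to_img <- function(z) {
      xi <- Re(stats::fft(z, inverse = TRUE)) / length(z)
      pmin(pmax(xi, rng[1]), rng[2])
    }
    res <- adam(NULL, z0, to_img)
    img <- to_img(res$theta)
  }
  list(image = img, objective = res$obj)
}
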