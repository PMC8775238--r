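#' Gabor patch parameters
#'
#' Parameter set for a single Gabor patch: a sinusoidal grating windowed by a
#' Gaussian envelope,
#' \deqn{f(x, y) = \exp\!\big(-(x'^2 + \gamma^2 y'^2) / (2\sigma^2)\big)
#'       \cos(2\pi x'/\lambda + \psi),}
#' where \eqn{(x', y')} are the orientation-rotated, canvas-centered pixel
#' coordinates. The standard \eqn{\gamma^2} aspect-ratio form is used (for
#' the default \eqn{\gamma = 1} the exponent is unaffected).
#'
#' @param canvas square canvas size in pixels.
#' @param wavelength pixels per cycle of the sinusoid (>= 2, Nyquist).
#' @param sigma Gaussian envelope SD in pixels (default 35, matched to a
#'   224-px canvas).
#' @param gamma aspect ratio (dimensionless), default 1.
#' @param phase sinusoid phase psi in radians.
#' @param orientation orientation theta in radians.
#' @return a `gabor_params` list.
#' @export
gabor_params <- function(canvas = 224L, wavelength, sigma = 35,
                         gamma = 1, phase = 0, orientation = 0) {
  stopifnot(sigma > 0, canvas >= 4)
  if (wavelength < 2)
    stop("`wavelength` below 2 px aliases (Nyquist); refusing")
  structure(list(canvas = as.integer(canvas), wavelength = wavelength,
                 sigma = sigma, gamma = gamma, phase = phase,
                 orientation = orientation),
            class = "gabor_params")
}

#' Render a Gabor patch
#'
#' Evaluates the Gabor function on the pixel grid. The canvas center pixel
#' (index `floor(canvas/2) + 1` along each axis) sits at coordinate (0, 0),
#' so with `orientation = 0, phase = 0` the center value is exactly 1.
#' Values lie in \[-1, 1\]; [build_stimulus_grid()] maps them to the \[0, 1\]
#' pixel range via `(v + 1) / 2` for presentation to a model.
#'
#' @param params a [gabor_params()] object.
#' @return a canvas x canvas numeric matrix in \[-1, 1\].
#' @examples
#' g <- gabor_image(gabor_params(canvas = 64, wavelength = 8, sigma = 10))
#' g[33, 33]  # center pixel = 1
#' @export
gabor_image <- function(params) {
  stopifnot(inherits(params, "gabor_params"))
  n <- params$canvas
  ctr <- floor(n / 2) + 1L
  coords <- seq_len(n) - ctr
  x <- matrix(coords, n, n, byrow = TRUE)   # column index -> horizontal
  y <- matrix(coords, n, n)                 # row index -> vertical
  th <- params$orientation
  xp <- cos(th) * x + sin(th) * y
  yp <- -sin(th) * x + cos(th) * y
  env <- exp(-(xp^2 + params$gamma^2 * yp^2) / (2 * params$sigma^2))
  env * cos(2 * pi * xp / params$wavelength + params$phase)
}

#' Gabor stimulus grid specification
#'
#' The in-silico electrophysiology stimulus set: 10 orientations evenly
#' spaced over \[0 deg, 172.5 deg\], 10 phases evenly spaced over
#' \[0 deg, 360 deg), and the 10 spatial frequencies 2.5, 3.5, 5, 7.1, 10,
#' 14.1, 20, 28.3, 40, 56 cycles/image, i.e. 1000 stimuli in total. The
#' assumed field of view (default 6.4 degrees) converts cycles/image to
#' cycles/degree.
#'
#' @param orientations orientations in degrees.
#' @param phases phases in degrees.
#' @param frequencies spatial frequencies in cycles/image, strictly
#'   increasing.
#' @param field_of_view field of view in degrees.
#' @return a `stimulus_grid` list.
#' @export
stimulus_grid <- function(orientations = seq(0, 172.5, length.out = 10),
                          phases = seq(0, 360, length.out = 11)[1:10],
                          frequencies = c(2.5, 3.5, 5, 7.1, 10, 14.1,
                                          20, 28.3, 40, 56),
                          field_of_view = 6.4) {
  stopifnot(length(frequencies) >= 1, all(diff(frequencies) > 0),
            field_of_view > 0)
  structure(list(orientations = orientations, phases = phases,
                 frequencies = frequencies, field_of_view = field_of_view),
            class = "stimulus_grid")
}

#' Build the Gabor stimulus batch for a grid
#'
#' Renders one Gabor patch per (orientation, phase, frequency) triple at a
#' fixed canvas, mapping values to the \[0, 1\] pixel range. The wavelength
#' of each patch is `canvas / cycles_per_image`.
#'
#' @param grid a [stimulus_grid()].
#' @param canvas canvas size in pixels.
#' @param sigma envelope SD in pixels; defaults to 35 scaled by
#'   `canvas / 224`.
#' @return list with `stimuli` (array n x canvas x canvas in \[0, 1\]) and
#'   `index` (data.frame with columns `orientation`, `phase`, `frequency`
#'   aligned to the batch).
#' @examples
#' b <- build_stimulus_grid(stimulus_grid(), canvas = 64)
#' nrow(b$index)  # 1000
#' @export
build_stimulus_grid <- function(grid = stimulus_grid(), canvas = 224L,
                                sigma = 35 * canvas / 224) {
  stopifnot(inherits(grid, "stimulus_grid"))
  if (any(canvas / grid$frequencies < 2))
    stop("highest grid frequency exceeds the canvas Nyquist; refusing")
  idx <- expand.grid(phase = grid$phases, orientation = grid$orientations,
                     frequency = grid$frequencies,
                     KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, c("orientation", "phase", "frequency")]
  n <- nrow(idx)
  stim <- array(0, c(n, canvas, canvas))
  for (i in seq_len(n)) {
    p <- gabor_params(canvas = canvas,
                      wavelength = canvas / idx$frequency[i],
                      sigma = sigma,
                      phase = idx$phase[i] * pi / 180,
                      orientation = idx$orientation[i] * pi / 180)
    stim[i, , ] <- (gabor_image(p) + 1) / 2
  }
  list(stimuli = stim, index = idx, grid = grid, canvas = canvas)
}

#' Convert cycles/image to cycles/degree
#'
#' @param f spatial frequency in cycles per image.
#' @param fov field of view in degrees (> 0).
#' @return frequency in cycles per degree: `f / fov`.
#' @examples
#' cycles_to_cpd(56, 6.4)  # 8.75
#' @export
cycles_to_cpd <- function(f, fov = 6.4) {
  stopifnot(fov > 0)
  f / fov
}
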