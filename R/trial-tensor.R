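#' Trial-structured response tensor
#'
#' Container for stimulus x neuron x trial responses, the input to
#' [cvpca()] and [neuron_reliability()]. Responses are stored as a dense
#' 3-d array; trial-to-trial variability is what cvPCA strips out when
#' estimating the stimulus-related (signal) eigenspectrum.
#'
#' @param responses numeric array of dimension S x N x T (stimulus, neuron,
#'   trial). All values must be finite.
#' @param stimulus_ids,neuron_ids optional identifier vectors; defaults to
#'   integer indices.
#' @return an object of class `trial_tensor` with elements `responses`,
#'   `stimulus_ids`, `neuron_ids` and dimensions `S`, `N`, `T`.
#' @examples
#' x <- trial_tensor(array(rnorm(20 * 5 * 2), c(20, 5, 2)))
#' dim(x$responses)
#' @export
trial_tensor <- function(responses, stimulus_ids = NULL, neuron_ids = NULL) {
  if (!is.array(responses) || length(dim(responses)) != 3L)
    stop("`responses` must be a 3-d array (stimulus x neuron x trial)")
  if (anyNA(responses) || !all(is.finite(responses)))
    stop("`responses` must be finite and free of NA")
  d <- dim(responses)
  if (d[1] < 2L || d[2] < 2L)
    stop("need at least 2 stimuli and 2 neurons")
  structure(
    list(
      responses = responses,
      stimulus_ids = stimulus_ids %||% seq_len(d[1]),
      neuron_ids = neuron_ids %||% seq_len(d[2]),
      S = d[1], N = d[2], T = d[3]
    ),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  cat(sprintf("<trial_tensor> %d stimuli x %d neurons x %d trials\n",
              x$S, x$N, x$T))
  invisible(x)
}

#' Trial-averaged responses
#'
#' Mean over the trial axis (optionally over a subset of trials), giving the
#' stimulus x neuron response matrix.
#'
#' @param tensor a [trial_tensor()].
#' @param trials optional integer vector of trial indices.
#' @return S x N numeric matrix.
#' @export
trial_mean <- function(tensor, trials = NULL) {
  stopifnot(inherits(tensor, "trial_tensor"))
  trials <- trials %||% seq_len(tensor$T)
  if (length(trials) == 1L) return(tensor$responses[, , trials])
  apply(tensor$responses[, , trials, drop = FALSE], c(1L, 2L), mean)
}
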