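#' Responses of representative neurons to a stimulus batch
#'
#' For a convolutional layer every unit in a channel shares its filter, so a
#' single "representative neuron" per channel — the unit at the spatial
#' center `(floor(H/2), floor(W/2))` (zero-based) of the activation map —
#' suffices to characterise the channel's tuning. Returns that unit's
#' activation per channel and stimulus.
#'
#' @param model a `model_adapter`.
#' @param layer layer name with spatial C x H x W output.
#' @param stimuli stimulus batch in the model's pixel range (the adapter
#'   applies its own channel normalization).
#' @return channels x stimuli response matrix.
#' @export
representative_responses <- function(model, layer, stimuli) {
  check_layer(model, layer)
  acts <- adapter_forward(model, stimuli)$layers[[layer]]
  if (length(dim(acts)) != 4L)
    stop("layer output is not spatial (expected C x H x W per stimulus)")
  H <- dim(acts)[3]; W <- dim(acts)[4]
  ci <- floor(H / 2) + 1L   # zero-based floor(H/2) -> 1-based index
  cj <- floor(W / 2) + 1L
  t(acts[, , ci, cj, drop = TRUE])
}

#' Spatial-frequency tuning curves
#'
#' The tuning-curve value of a channel at a spatial frequency is its mean
#' response over all orientation x phase combinations at that frequency.
#'
#' @param responses channels x stimuli matrix from
#'   [representative_responses()].
#' @param index stimulus index data.frame (columns `orientation`, `phase`,
#'   `frequency`) aligned with the batch, as returned by
#'   [build_stimulus_grid()].
#' @param grid the [stimulus_grid()] used (supplies the frequency axis and
#'   field of view).
#' @return a `tuning_curves` object: `curves` (channels x frequencies
#'   matrix), `frequencies` (cycles/image), `frequencies_cpd`,
#'   `peak_to_peak` per channel.
#' @export
tuning_curve <- function(responses, index, grid) {
  stopifnot(inherits(grid, "stimulus_grid"))
  responses <- as.matrix(responses)
  if (ncol(responses) != nrow(index))
    stop("responses are not aligned with the stimulus index")
  freqs <- grid$frequencies
  per_freq <- length(grid$orientations) * length(grid$phases)
  curves <- matrix(0, nrow(responses), length(freqs))
  for (k in seq_along(freqs)) {
    sel <- which(index$frequency == freqs[k])
    if (length(sel) != per_freq)
      stop(sprintf("grid cell missing: frequency %g has %d of %d stimuli",
                   freqs[k], length(sel), per_freq))
    curves[, k] <- rowMeans(responses[, sel, drop = FALSE])
  }
  structure(list(curves = curves, frequencies = freqs,
                 frequencies_cpd = cycles_to_cpd(freqs, grid$field_of_view),
                 peak_to_peak = apply(curves, 1L, function(v) max(v) - min(v)),
                 field_of_view = grid$field_of_view),
            class = "tuning_curves")
}

#' Preferred spatial frequency per channel
#'
#' The preferred frequency is the argmax of the tuning curve; ties are
#' broken toward the lowest frequency (deterministic, and conservative with
#' respect to claims about high-frequency preference). Channels whose
#' peak-to-peak tuning value is 0 (flat curves) carry no frequency
#' preference and are excluded (`NA`).
#'
#' @param curves a [tuning_curve()] object.
#' @param units `"cycles_per_image"` or `"cpd"`.
#' @return numeric vector, one preferred frequency per channel; `NA` for
#'   excluded channels.
#' @export
preferred_sf <- function(curves, units = c("cpd", "cycles_per_image")) {
  stopifnot(inherits(curves, "tuning_curves"))
  units <- match.arg(units)
  axis <- if (units == "cpd") curves$frequencies_cpd else curves$frequencies
  pref <- axis[apply(curves$curves, 1L, which.max)]  # which.max: first max
  pref[curves$peak_to_peak <= 0] <- NA_real_
  pref
}

#' De Valois macaque V1 preferred-SF reference distribution
#'
#' The preferred spatial frequency histogram of cells in the foveal area of
#' macaque V1 (De Valois, Albrecht & Thorell 1982, foveal sample): bin edges
#' 0.35, 0.5, 0.7, 1.0, 1.4, 2.0, 2.8, 4.0, 5.6, 8.0 cycles/degree with
#' 11.2 as the rightmost edge, and cell counts 0, 3, 3, 6, 17, 22, 18, 19,
#' 9, 4. Shipped as a packaged CSV.
#'
#' @return an `sf_distribution` for the reference histogram.
#' @export
de_valois_reference <- function() {
  path <- system.file("extdata", "de_valois_sf_counts.csv",
                      package = "v1robust", mustWork = TRUE)
  ref <- utils::read.csv(path)
  sf_distribution(counts = ref$count,
                  bin_edges = c(ref$bin_edge_low_cpd,
                                ref$bin_edge_high_cpd[nrow(ref)]))
}

#' Binned preferred-SF distribution
#'
#' Bins preferred spatial frequencies (cpd) into half-open bins
#' `[edge_i, edge_{i+1})` (the last bin closed). Values outside the edges
#' are clipped into the terminal bins with a warning; this cannot occur with
#' the default stimulus grid at a 6.4-degree field of view, whose ten
#' frequencies fall one into each De Valois bin.
#'
#' @param pref_cpd preferred frequencies in cycles/degree (`NA` dropped), or
#'   `NULL` when `counts` is given directly.
#' @param bin_edges increasing edge vector (length = bins + 1); defaults to
#'   the De Valois edges.
#' @param counts optional pre-binned counts (length = bins), bypassing
#'   `pref_cpd`.
#' @return an `sf_distribution`: `bin_edges`, `counts`, `proportions`,
#'   `cdf` (non-decreasing, ends at 1).
#' @export
sf_distribution <- function(pref_cpd = NULL,
                            bin_edges = c(0.35, 0.5, 0.7, 1.0, 1.4, 2.0,
                                          2.8, 4.0, 5.6, 8.0, 11.2),
                            counts = NULL) {
  stopifnot(all(diff(bin_edges) > 0))
  nb <- length(bin_edges) - 1L
  if (is.null(counts)) {
    pref_cpd <- pref_cpd[!is.na(pref_cpd)]
    if (length(pref_cpd) == 0L) stop("no preferred frequencies to bin")
    if (any(pref_cpd < bin_edges[1] | pref_cpd >= bin_edges[nb + 1L])) {
      warning("preferred frequencies outside the bin range; clipping into terminal bins")
      pref_cpd <- pmin(pmax(pref_cpd, bin_edges[1]),
                       bin_edges[nb + 1L] - 1e-9)
    }
    idx <- findInterval(pref_cpd, bin_edges, rightmost.closed = TRUE)
    counts <- tabulate(idx, nbins = nb)
  } else {
    stopifnot(length(counts) == nb, all(counts >= 0))
  }
  total <- sum(counts)
  if (total <= 0) stop("empty distribution")
  props <- counts / total
  structure(list(bin_edges = bin_edges, counts = counts,
                 proportions = props, cdf = cumsum(props)),
            class = "sf_distribution")
}

#' @export
print.sf_distribution <- function(x, ...) {
  cat(sprintf("<sf_distribution> %d bins [%g, %g] cpd, n = %g\n",
              length(x$counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], sum(x$counts)))
  invisible(x)
}

#' V1 spatial-frequency similarity score
#'
#' One minus the maximum absolute difference between two binned empirical
#' cumulative distributions (a Kolmogorov-Smirnov-style statistic mapped to
#' a similarity in \[0, 1\]): 1 when the CDFs coincide on every bin, 0 when
#' all mass sits in the first bin of one distribution and the last bin of
#' the other. Distributions are compared as proportions, so differing
#' sample sizes are immaterial.
#'
#' @param x,y `sf_distribution` objects on identical bin edges.
#' @return similarity score in \[0, 1\].
#' @examples
#' r <- de_valois_reference()
#' sf_score(r, r)  # 1
#' @export
sf_score <- function(x, y) {
  stopifnot(inherits(x, "sf_distribution"), inherits(y, "sf_distribution"))
  if (!isTRUE(all.equal(x$bin_edges, y$bin_edges)))
    stop("distributions have different bin edges")
  1 - max(abs(x$cdf - y$cdf))
}

#' In-silico electrophysiology experiments
#'
#' Emulates repeated electrophysiology sessions: per experiment,
#' `n_neurons` representative neurons are sampled uniformly with
#' replacement from the non-excluded channels, their preferred spatial
#' frequencies (cpd) are binned into the reference bins, and the resulting
#' distribution is scored against the reference with [sf_score()].
#'
#' @param pref_cpd per-channel preferred frequencies in cpd (`NA` =
#'   excluded channel), e.g. from [preferred_sf()].
#' @param n_neurons neurons sampled per experiment (default 150).
#' @param n_experiments number of experiments (default 1000).
#' @param reference reference `sf_distribution` (default
#'   [de_valois_reference()]).
#' @param seed RNG seed; fixed seed gives identical experiments.
#' @return list with `scores` (length `n_experiments`), `mean_score`,
#'   `sd_score`, and `distributions` (list of `sf_distribution`).
#' @export
run_insilico_experiments <- function(pref_cpd, n_neurons = 150L,
                                     n_experiments = 1000L,
                                     reference = de_valois_reference(),
                                     seed = 1L) {
  pool <- pref_cpd[!is.na(pref_cpd)]
  if (length(pool) == 0L) stop("all channels excluded (flat tuning curves)")
  with_seed(seed, {
    dists <- vector("list", n_experiments)
    scores <- numeric(n_experiments)
    for (e in seq_len(n_experiments)) {
      draw <- pool[sample.int(length(pool), n_neurons, replace = TRUE)]
      d <- sf_distribution(draw, bin_edges = reference$bin_edges)
      dists[[e]] <- d
      scores[e] <- sf_score(d, reference)
    }
    list(scores = scores, mean_score = mean(scores),
         sd_score = stats::sd(scores), distributions = dists)
  })
}
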