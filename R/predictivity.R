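#' Preprocess stimuli for feature extraction
#'
#' The standard stimulus path for the V1 predictivity analysis: center-crop
#' to `crop` pixels, resize (bilinear) to `resize` pixels, zero-pad up to
#' the model's canvas with the content centered, then apply the model's
#' channel normalization offset implicitly at forward time. The padded
#' region holds pixel value 0, which after normalization becomes
#' `-mean / sd`.
#'
#' @param images array n x H x W (grayscale) with H, W >= `crop`.
#' @param model a `model_adapter`; supplies the canvas size.
#' @param crop central crop size in pixels (default 80).
#' @param resize post-crop size in pixels (default 40).
#' @return array n x canvas x canvas in the model's pixel range.
#' @export
preprocess_stimuli <- function(images, model, crop = 80L, resize = 40L) {
  if (is.matrix(images)) images <- array(images, c(1L, dim(images)))
  d <- dim(images)
  if (d[2] < crop || d[3] < crop)
    stop(sprintf("images (%dx%d) smaller than the %d-px crop", d[2], d[3], crop))
  canvas <- model$input_spec$canvas
  if (resize > canvas) stop("resized image larger than the model canvas")
  r0 <- floor((d[2] - crop) / 2); c0 <- floor((d[3] - crop) / 2)
  p0 <- floor((canvas - resize) / 2)
  out <- array(0, c(d[1], canvas, canvas))
  for (i in seq_len(d[1])) {
    cropped <- images[i, r0 + seq_len(crop), c0 + seq_len(crop)]
    small <- if (resize == crop) cropped else
      EBImage::imageData(EBImage::resize(EBImage::Image(cropped),
                                         w = resize, h = resize))
    out[i, p0 + seq_len(resize), p0 + seq_len(resize)] <- small
  }
  out
}

#' Fixed PCA reduction of layer features
#'
#' Fits a PCA basis once on an independent basis set and applies the frozen
#' projection to any feature matrix, so the dimensionality reduction is held
#' constant across all train-test splits. When the feature dimension is
#' below the cap, all components are used.
#'
#' @param basis_features stimulus x feature matrix used to fit the basis
#'   (independent of the mapping stimuli).
#' @param cap maximum number of components (default 1000; must be >= 1).
#' @return a `feature_reducer` with `$project(features)` and `$n_components`.
#' @export
reduce_features <- function(basis_features, cap = 1000L) {
  if (cap < 1L) stop("`cap` must be >= 1")
  basis_features <- as.matrix(basis_features)
  k <- min(cap, ncol(basis_features), nrow(basis_features) - 1L)
  pc <- stats::prcomp(basis_features, center = TRUE, scale. = FALSE, rank. = k)
  structure(list(
    n_components = k,
    center = pc$center,
    rotation = pc$rotation,
    project = function(features) {
      features <- as.matrix(features)
      sweep(features, 2L, pc$center) %*% pc$rotation
    }
  ), class = "feature_reducer")
}

#' Spearman-Brown correction of a split-half correlation
#'
#' `2 r / (1 + r)`: the reliability of the mean of the two halves implied by
#' their correlation `r`.
#'
#' @param r split-half correlation in (-1, 1].
#' @return corrected reliability.
#' @examples
#' spearman_brown(0.5)  # 2/3
#' @export
spearman_brown <- function(r) {
  if (any(r <= -1)) stop("Spearman-Brown correction undefined at r = -1")
  2 * r / (1 + r)
}

#' Split-half reliability per neuron
#'
#' Per split, trials are partitioned into two halves, the half-means are
#' correlated across stimuli for each neuron, the correlations are averaged
#' across splits, and the average is Spearman-Brown corrected. With exactly
#' two trials the split is deterministic and a single pass is performed.
#'
#' @param tensor a [trial_tensor()] with >= 2 trials.
#' @param n_half_splits number of random half-splits (default 20).
#' @param seed RNG seed for the splits.
#' @return list with `reliability` (corrected, per neuron), `split_half_r`
#'   (mean uncorrected r), `unreliable` (logical, non-positive split-half
#'   correlation).
#' @export
neuron_reliability <- function(tensor, n_half_splits = 20L, seed = 1L) {
  stopifnot(inherits(tensor, "trial_tensor"))
  if (tensor$T < 2L) stop("reliability needs >= 2 trials")
  T <- tensor$T
  half <- T %/% 2L
  deterministic <- (T == 2L)
  reps <- if (deterministic) 1L else n_half_splits
  rs <- matrix(0, reps, tensor$N)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      perm <- if (deterministic) 1:2 else sample.int(T)
      m1 <- trial_mean(tensor, perm[seq_len(half)])
      m2 <- trial_mean(tensor, perm[half + seq_len(half)])
      rs[r, ] <- vapply(seq_len(tensor$N),
                        function(j) stats::cor(m1[, j], m2[, j]), numeric(1))
    }
  })
  mean_r <- colMeans(rs)
  unreliable <- !is.finite(mean_r) | mean_r <= 0
  rel <- rep(NA_real_, tensor$N)
  ok <- !unreliable & mean_r > -1
  rel[ok] <- spearman_brown(mean_r[ok])
  list(reliability = rel, split_half_r = mean_r, unreliable = unreliable)
}

#' Mapping specification for neural predictivity
#'
#' @param method `"pls"` (partial least squares, default) or `"ridge"`
#'   (closed-form ridge with 5-fold cross-validated coefficient selection).
#' @param n_components PLS component count (default 25).
#' @param ridge_grid regularization coefficient grid for ridge
#'   (default `c(0.01, 0.1, 1, 10)`).
#' @param n_splits number of train-test splits (default 20).
#' @param train_fraction fraction of stimuli in the train set (default 0.75).
#' @param feature_dim_cap PCA cap applied by callers that reduce features
#'   (default 1000).
#' @param seed RNG seed for the splits.
#' @return a `mapping_spec` list.
#' @export
mapping_spec <- function(method = c("pls", "ridge"), n_components = 25L,
                         ridge_grid = c(0.01, 0.1, 1, 10), n_splits = 20L,
                         train_fraction = 0.75, feature_dim_cap = 1000L,
                         seed = 1L) {
  method <- match.arg(method)
  stopifnot(train_fraction > 0, train_fraction < 1, n_splits >= 1)
  structure(list(method = method, n_components = as.integer(n_components),
                 ridge_grid = ridge_grid, n_splits = as.integer(n_splits),
                 train_fraction = train_fraction,
                 feature_dim_cap = as.integer(feature_dim_cap),
                 seed = seed),
            class = "mapping_spec")
}

# Closed-form ridge fit (columns of Y independently), lambda chosen by
# 5-fold CV over the grid; X and Y are centered internally.
ridge_fit <- function(X, Y, grid, n_folds = 5L, seed = 1L) {
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm); Yc <- sweep(Y, 2L, ym)
  solve_ridge <- function(Xtr, Ytr, lambda) {
    d <- ncol(Xtr)
    solve(crossprod(Xtr) + diag(lambda, d), crossprod(Xtr, Ytr))
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), nrow(X))))
  cv_err <- vapply(grid, function(lambda) {
    err <- 0
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      B <- solve_ridge(Xc[tr, , drop = FALSE], Yc[tr, , drop = FALSE], lambda)
      pred <- Xc[!tr, , drop = FALSE] %*% B
      err <- err + sum((pred - Yc[!tr, , drop = FALSE])^2)
    }
    err
  }, numeric(1))
  best <- grid[which.min(cv_err)]
  B <- solve_ridge(Xc, Yc, best)
  list(predict = function(Xnew)
         sweep(sweep(Xnew, 2L, xm) %*% B, 2L, ym, `+`),
       lambda = best)
}

pls_fit <- function(X, Y, n_components) {
  k <- min(n_components, ncol(X), nrow(X) - 1L)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  colnames(Y) <- paste0("n", seq_len(ncol(Y)))
  fit <- mixOmics::pls(X, Y, ncomp = k, mode = "regression", scale = FALSE)
  list(predict = function(Xnew) {
    colnames(Xnew) <- colnames(X)
    pr <- stats::predict(fit, Xnew)$predict
    pr[, , k]
  }, ncomp = k)
}

#' Fit a linear mapping and score noise-corrected predictivity
#'
#' Per train-test split (default 20 splits, 75% train): fit the mapping
#' (PLS with 25 components, or cross-validated ridge) from features to
#' trial-averaged responses on the train stimuli, predict the held-out
#' stimuli, and compute each neuron's Pearson correlation between predicted
#' and observed responses divided by the square root of its Spearman-Brown
#' corrected split-half reliability. Per-neuron scores are averaged across
#' splits before taking the median across neurons; the spread is the SD of
#' the per-split medians. Neurons with non-positive split-half correlation
#' are excluded (the square root of a non-positive reliability is
#' undefined); noise-corrected values may exceed 1 by sampling error and are
#' reported unclipped.
#'
#' @param features stimulus x feature matrix aligned with the dataset
#'   stimuli (typically already PCA-reduced via [reduce_features()]).
#' @param dataset a `neural_dataset` (from [gen_linear_v1_dataset()]) or a
#'   [trial_tensor()].
#' @param spec a [mapping_spec()].
#' @param reliability optional precomputed [neuron_reliability()] result.
#' @return a `predictivity_result`: `per_neuron` (noise-corrected, averaged
#'   over splits), `per_neuron_raw`, `reliability`, `median`, `sd_median`
#'   (SD of per-split medians), `excluded` (neuron indices), `spec`.
#' @export
fit_and_score <- function(features, dataset, spec = mapping_spec(),
                          reliability = NULL) {
  tensor <- if (inherits(dataset, "neural_dataset")) dataset$responses
            else dataset
  stopifnot(inherits(tensor, "trial_tensor"))
  features <- as.matrix(features)
  if (nrow(features) != tensor$S)
    stop("features are not aligned with the dataset stimuli")
  rel <- reliability %||% neuron_reliability(tensor, seed = spec$seed)
  excluded <- which(rel$unreliable)
  if (length(excluded) > 0L)
    warning(sprintf("%d neuron(s) with non-positive reliability excluded",
                    length(excluded)))
  keep <- setdiff(seq_len(tensor$N), excluded)
  if (length(keep) == 0L) stop("no reliable neurons to fit")
  Y <- trial_mean(tensor)[, keep, drop = FALSE]
  S <- tensor$S
  n_train <- round(spec$train_fraction * S)
  if (spec$method == "pls" && n_train <= spec$n_components)
    stop("train set smaller than the PLS component count")
  scores <- matrix(NA_real_, spec$n_splits, length(keep))
  raw <- matrix(NA_real_, spec$n_splits, length(keep))
  with_seed(spec$seed, {
    for (sp in seq_len(spec$n_splits)) {
      tr <- sample.int(S, n_train)
      te <- setdiff(seq_len(S), tr)
      Xtr <- features[tr, , drop = FALSE]
      fit <- if (spec$method == "pls")
        pls_fit(Xtr, Y[tr, , drop = FALSE], spec$n_components)
      else
        ridge_fit(Xtr, Y[tr, , drop = FALSE], spec$ridge_grid, seed = sp)
      pred <- fit$predict(features[te, , drop = FALSE])
      r <- vapply(seq_along(keep), function(j) {
        obs <- Y[te, j]
        if (stats::sd(pred[, j]) == 0 || stats::sd(obs) == 0) return(0)
        stats::cor(pred[, j], obs)
      }, numeric(1))
      raw[sp, ] <- r
      scores[sp, ] <- r / sqrt(rel$reliability[keep])
    }
  })
  per_neuron <- colMeans(scores)
  structure(list(
    per_neuron = per_neuron,
    per_neuron_raw = colMeans(raw),
    reliability = rel$reliability,
    neuron_ids = keep,
    median = stats::median(per_neuron),
    sd_median = stats::sd(apply(scores, 1L, stats::median)),
    excluded = excluded,
    spec = spec
  ), class = "predictivity_result")
}

#' @export
print.predictivity_result <- function(x, ...) {
  cat(sprintf(
    "<predictivity_result:%s> median noise-corrected predictivity %.3f (SD over splits %.3f), %d neurons, %d excluded\n",
    x$spec$method, x$median, x$sd_median, length(x$per_neuron),
    length(x$excluded)))
  invisible(x)
}

#' Bootstrap comparison of two predictivity results
#'
#' Resamples neurons with replacement `n` times and recomputes the
#' difference of median per-neuron predictivity (A minus B) per draw. The
#' one-sided p-value (direction A > B) is the fraction of draws with
#' difference <= 0; the two-sided value is its doubling, capped at 1.
#'
#' @param result_a,result_b `predictivity_result`s over identical neuron
#'   sets.
#' @param n number of bootstrap draws (default 10000, > 0).
#' @param seed RNG seed.
#' @return list with `p_one_sided`, `p_two_sided`, `observed_diff`,
#'   `boot_diffs`.
#' @export
bootstrap_compare <- function(result_a, result_b, n = 10000L, seed = 1L) {
  if (n <= 0) stop("`n` must be positive")
  if (!identical(result_a$neuron_ids, result_b$neuron_ids))
    stop("results cover different neuron sets")
  a <- result_a$per_neuron; b <- result_b$per_neuron
  k <- length(a)
  with_seed(seed, {
    diffs <- vapply(seq_len(n), function(i) {
      idx <- sample.int(k, k, replace = TRUE)
      stats::median(a[idx]) - stats::median(b[idx])
    }, numeric(1))
    p1 <- mean(diffs <= 0)
    list(p_one_sided = p1, p_two_sided = min(1, 2 * min(p1, 1 - p1)),
         observed_diff = stats::median(a) - stats::median(b),
         boot_diffs = diffs)
  })
}
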