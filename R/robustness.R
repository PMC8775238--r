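#' Attack configuration
#'
#' Settings for a norm-bounded projected-gradient attack. The default step
#' size is `epsilon * 2 / n_steps`, i.e. twice the budget spread over the
#' steps, and the default benchmark set ([default_attack_set()]) uses
#' 20 steps with budgets `linf` 1/1020, `l2` 0.15, `l1` 40 in pixel units.
#'
#' @param norm `"linf"`, `"l2"` or `"l1"`.
#' @param epsilon maximum perturbation size in pixel units (>= 0).
#' @param n_steps ascent steps (default 20).
#' @param step_size ascent step size; default `epsilon * 2 / n_steps`.
#' @param clip_range valid pixel interval, default `c(0, 1)`.
#' @return an `attack_config` list.
#' @export
attack_config <- function(norm = c("linf", "l2", "l1"), epsilon,
                          n_steps = 20L, step_size = epsilon * 2 / n_steps,
                          clip_range = c(0, 1)) {
  norm <- match.arg(norm)
  if (epsilon < 0) stop("`epsilon` must be >= 0")
  if (epsilon > 0 && step_size <= 0) stop("`step_size` must be positive")
  structure(list(norm = norm, epsilon = epsilon, n_steps = as.integer(n_steps),
                 step_size = step_size, clip_range = clip_range),
            class = "attack_config")
}

#' The benchmark attack set
#'
#' @param n_steps steps per attack (default 20).
#' @param clip_range valid pixel interval.
#' @return list of three [attack_config()]s: `linf` 1/1020, `l2` 0.15,
#'   `l1` 40.
#' @export
default_attack_set <- function(n_steps = 20L, clip_range = c(0, 1)) {
  list(attack_config("linf", 1 / 1020, n_steps, clip_range = clip_range),
       attack_config("l2", 0.15, n_steps, clip_range = clip_range),
       attack_config("l1", 40, n_steps, clip_range = clip_range))
}

# Euclidean projection of a vector onto the l1 ball of radius eps
# (sort-based simplex projection).
project_l1_ball <- function(v, eps) {
  if (sum(abs(v)) <= eps) return(v)
  u <- sort(abs(v), decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u > (css - eps) / seq_along(u)))
  theta <- (css[rho] - eps) / rho
  sign(v) * pmax(abs(v) - theta, 0)
}

#' Project perturbations onto a norm ball
#'
#' Per sample (first array dimension): `linf` clips elementwise to
#' \[-epsilon, epsilon\]; `l2` rescales radially when the norm exceeds
#' epsilon; `l1` applies the exact Euclidean projection onto the l1 ball.
#' Perturbations already inside the ball are returned unchanged.
#'
#' @param delta perturbation batch (samples along the first dimension).
#' @param norm `"linf"`, `"l2"` or `"l1"`.
#' @param epsilon ball radius (>= 0).
#' @return projected perturbations, same shape as `delta`.
#' @export
project <- function(delta, norm, epsilon) {
  if (!norm %in% c("linf", "l2", "l1")) stop("unknown norm: ", norm)
  stopifnot(all(is.finite(delta)), epsilon >= 0)
  single <- is.null(dim(delta))
  if (single) delta <- matrix(delta, nrow = 1L)
  d <- dim(delta)
  dm <- matrix(delta, nrow = d[1])
  out <- switch(norm,
    linf = pmin(pmax(dm, -epsilon), epsilon),
    l2 = {
      nrm <- sqrt(rowSums(dm^2))
      scl <- ifelse(nrm > epsilon & nrm > 0, epsilon / nrm, 1)
      dm * scl
    },
    l1 = t(apply(dm, 1L, project_l1_ball, eps = epsilon))
  )
  if (single) return(as.numeric(out))
  array(out, d)
}

# Per-sample gradient of mean cross-entropy w.r.t. logits, unscaled by n:
# softmax(z) - onehot(y).
ce_logit_grad <- function(logits, labels) {
  p <- softmax_rows(logits)
  p[cbind(seq_len(nrow(p)), labels)] <- p[cbind(seq_len(nrow(p)), labels)] - 1
  p
}

ascent_direction <- function(g, norm) {
  d <- dim(g)
  gm <- matrix(g, nrow = d[1])
  dir <- switch(norm,
    linf = sign(gm),
    l2 = {
      nrm <- sqrt(rowSums(gm^2))
      gm / ifelse(nrm > 0, nrm, 1)
    },
    l1 = {
      nrm <- rowSums(abs(gm))
      gm / ifelse(nrm > 0, nrm, 1)
    })
  array(dir, d)
}

#' Inner maximization: worst-case perturbation by projected gradient ascent
#'
#' Deterministic projected gradient ascent on the classification loss:
#' starting from `delta = 0` (no random restarts), each step moves along the
#' norm-appropriate direction of the loss gradient (`linf`: elementwise
#' sign; `l2`/`l1`: gradient normalized to unit norm) with the configured
#' step size, projects `delta` back onto the epsilon-ball, and clips
#' `x + delta` to the valid pixel range. Returns the perturbation; the
#' returned `delta` always satisfies its norm bound.
#'
#' @param model a `model_adapter`.
#' @param x input batch (samples along the first dimension), pixel space.
#' @param y integer labels (1-based).
#' @param config an [attack_config()].
#' @return perturbation batch `delta` with `x + delta` in the clip range.
#' @export
adv_inner_max <- function(model, x, y, config) {
  stopifnot(inherits(config, "attack_config"))
  if (config$epsilon == 0) return(x * 0)
  delta <- x * 0
  for (step in seq_len(config$n_steps)) {
    xa <- x + delta
    logits <- adapter_forward(model, xa)$logits
    g <- adapter_logits_vjp(model, xa, ce_logit_grad(logits, y))
    if (all(g == 0)) break
    delta <- delta + config$step_size * ascent_direction(g, config$norm)
    delta <- project(delta, config$norm, config$epsilon)
    xa <- pmin(pmax(x + delta, config$clip_range[1]), config$clip_range[2])
    delta <- xa - x
  }
  delta
}

#' PGD adversarial examples
#'
#' Runs [adv_inner_max()] and returns the perturbed inputs `x + delta`.
#' Deterministic: repeated calls with the same arguments give identical
#' adversarial examples.
#'
#' @inheritParams adv_inner_max
#' @return adversarial batch, same shape as `x`.
#' @export
pgd_attack <- function(model, x, y, config) {
  x + adv_inner_max(model, x, y, config)
}

#' Adversarial accuracy under a set of attacks
#'
#' Top-1 accuracy on inputs perturbed by each attack configuration,
#' averaged across the attack set (an `epsilon = 0` attack reproduces clean
#' accuracy exactly).
#'
#' @param model a `model_adapter`.
#' @param x labeled input batch.
#' @param y integer labels (1-based).
#' @param configs list of [attack_config()]s (default
#'   [default_attack_set()]).
#' @return list with `accuracy` (mean over attacks), `per_attack` (named by
#'   norm), `clean_accuracy`.
#' @export
adversarial_accuracy <- function(model, x, y, configs = default_attack_set()) {
  n <- if (is.null(dim(x))) 1L else dim(x)[1]
  if (n == 0L) stop("empty dataset")
  stopifnot(length(y) == n)
  top1 <- function(batch) {
    logits <- adapter_forward(model, batch)$logits
    mean(max.col(logits, ties.method = "first") == y)
  }
  per <- vapply(configs, function(cfg) top1(pgd_attack(model, x, y, cfg)),
                numeric(1))
  names(per) <- vapply(configs, function(cfg)
    sprintf("%s_%.4g", cfg$norm, cfg$epsilon), character(1))
  list(accuracy = mean(per), per_attack = per, clean_accuracy = top1(x))
}

#' TRADES configuration
#'
#' @param beta robustness regularization coefficient (>= 0; the reference
#'   training value is 2).
#' @param epsilon perturbation radius of the neighbourhood.
#' @param n_inner_steps projected-ascent steps on the KL term (default 3).
#' @param step_size inner step size; default `epsilon * 2 / n_inner_steps`
#'   (the reference schedule: radius 4/255, step 4/255 x 2/3).
#' @param clip_range valid pixel interval.
#' @param init_sd SD of the small seeded Gaussian initialization of the
#'   inner point (the KL and its gradient both vanish exactly at `v = x`,
#'   so the ascent must start off-center; default `epsilon / 10`).
#' @param init_seed seed for that initialization, making the inner
#'   maximization deterministic.
#' @return a `trades_config` list.
#' @export
trades_config <- function(beta = 2, epsilon, n_inner_steps = 3L,
                          step_size = epsilon * 2 / n_inner_steps,
                          clip_range = c(0, 1), init_sd = epsilon / 10,
                          init_seed = 1L) {
  if (beta < 0) stop("`beta` must be >= 0")
  structure(list(beta = beta, epsilon = epsilon,
                 n_inner_steps = as.integer(n_inner_steps),
                 step_size = step_size, clip_range = clip_range,
                 init_sd = init_sd, init_seed = init_seed),
            class = "trades_config")
}

# KL(p || q) per row of two probability matrices.
kl_rows <- function(p, q) {
  rowSums(ifelse(p > 0, p * (log(p) - log(q)), 0))
}

# Inner ascent of TRADES: find v in the linf ball around x maximizing
# KL(f(v) || f(x)). Returns v.
trades_inner_max <- function(model, x, config) {
  if (config$epsilon == 0 || config$n_inner_steps == 0L) return(x)
  q <- softmax_rows(adapter_forward(model, x)$logits)
  delta <- with_seed(config$init_seed,
    array(stats::rnorm(length(x), sd = config$init_sd),
          if (is.null(dim(x))) length(x) else dim(x)))
  delta <- project(delta, "linf", config$epsilon)
  for (step in seq_len(config$n_inner_steps)) {
    v <- x + delta
    p <- softmax_rows(adapter_forward(model, v)$logits)
    u <- log(pmax(p, 1e-300)) - log(pmax(q, 1e-300))
    klv <- rowSums(p * u)
    g_logits <- p * (u - klv)          # d KL / d logits(v)
    g <- adapter_logits_vjp(model, v, g_logits)
    delta <- delta + config$step_size * ascent_direction(g, "linf")
    delta <- project(delta, "linf", config$epsilon)
    v <- pmin(pmax(x + delta, config$clip_range[1]), config$clip_range[2])
    delta <- v - x
  }
  x + delta
}

#' TRADES loss
#'
#' Cross-entropy plus `beta` times the worst-case Kullback-Leibler
#' divergence between the class distributions at a perturbed point and at
#' the clean point, \eqn{\max_{v \in B(x,\varepsilon)} KL(f(v) \| f(x))},
#' with the inner maximization performed by projected gradient ascent under
#' the l-infinity projection. Reduces over the batch by mean. With
#' `beta = 0` the loss equals plain cross-entropy; with zero inner steps the
#' KL term is 0.
#'
#' @param model a `model_adapter` with >= 2 classes.
#' @param x input batch, pixel space.
#' @param y integer labels (1-based).
#' @param config a [trades_config()].
#' @return scalar loss, with attributes `cross_entropy` and `kl` (the two
#'   mean terms).
#' @export
trades_loss <- function(model, x, y, config) {
  stopifnot(inherits(config, "trades_config"))
  if (model$n_classes < 2L) stop("TRADES needs >= 2 classes")
  logits <- adapter_forward(model, x)$logits
  ce <- cross_entropy(logits, y)
  kl <- 0
  if (config$beta > 0 && config$n_inner_steps > 0L && config$epsilon > 0) {
    v <- trades_inner_max(model, x, config)
    p <- softmax_rows(adapter_forward(model, v)$logits)
    q <- softmax_rows(logits)
    kl <- mean(kl_rows(p, q))
  }
  structure(ce + config$beta * kl, cross_entropy = ce, kl = kl)
}

#' Input-gradient-regularization configuration
#'
#' @param lambda regularization coefficient (default 0.3).
#' @param h finite-difference step (default 0.01, > 0).
#' @return an `igr_config` list.
#' @export
igr_config <- function(lambda = 0.3, h = 0.01) {
  if (h <= 0) stop("`h` must be positive")
  if (lambda < 0) stop("`lambda` must be >= 0")
  structure(list(lambda = lambda, h = h), class = "igr_config")
}

# Per-sample cross-entropy values for a logits matrix.
ce_per_sample <- function(logits, labels) {
  lp <- log_softmax_rows(logits)
  -lp[cbind(seq_len(nrow(logits)), labels)]
}

#' Input gradient regularization (IGR) loss
#'
#' Cross-entropy plus a finite-difference penalty on the input gradient of
#' the loss: per sample, `z = x + h * grad / ||grad||_2` and the penalty is
#' `lambda / (2 h^2) * (L(z) - L(x))^2`, whose small-`h` limit is
#' `lambda / 2 * ||grad||_2^2`. Samples whose input-gradient norm is below
#' 1e-12 contribute no penalty. Reduces over the batch by mean; with
#' `lambda = 0` the loss is exactly cross-entropy.
#'
#' @param model a `model_adapter`.
#' @param x input batch, pixel space.
#' @param y integer labels (1-based).
#' @param config an [igr_config()].
#' @return scalar loss with attributes `cross_entropy` and `penalty`.
#' @export
igr_loss <- function(model, x, y, config) {
  stopifnot(inherits(config, "igr_config"))
  logits <- adapter_forward(model, x)$logits
  lx <- ce_per_sample(logits, y)
  if (config$lambda == 0)
    return(structure(mean(lx), cross_entropy = mean(lx), penalty = 0))
  g <- adapter_logits_vjp(model, x, ce_logit_grad(logits, y))
  n <- if (is.null(dim(x))) 1L else dim(x)[1]
  gm <- matrix(g, nrow = n)
  nrm <- sqrt(rowSums(gm^2))
  active <- nrm >= 1e-12
  pen <- numeric(n)
  if (any(active)) {
    zm <- matrix(x, nrow = n)
    zm[active, ] <- zm[active, , drop = FALSE] +
      config$h * gm[active, , drop = FALSE] / nrm[active]
    z <- array(zm, if (is.null(dim(x))) length(x) else dim(x))
    lz <- ce_per_sample(adapter_forward(model, z)$logits, y)
    pen[active] <- (config$lambda / (2 * config$h^2)) *
      (lz[active] - lx[active])^2
  }
  structure(mean(lx + pen), cross_entropy = mean(lx), penalty = mean(pen))
}
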