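#' @importFrom stats rnorm runif cor sd prcomp quantile median coef lm
#' @importFrom utils head read.csv write.csv
NULL

# Numerically stable softmax over the rows of a matrix (samples x classes).
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Stable log-softmax over rows.
log_softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  z - log(rowSums(exp(z)))
}

# Mean cross-entropy of logits (n x C) against integer labels in 1..C.
cross_entropy <- function(logits, labels) {
  lp <- log_softmax_rows(logits)
  -mean(lp[cbind(seq_len(nrow(logits)), labels)])
}

# Draw a matrix with orthonormal columns from the Haar measure (QR of a
# Gaussian matrix with sign-fixed R diagonal).
haar_orthonormal <- function(nrow, ncol) {
  stopifnot(ncol <= nrow)
  qr_dec <- qr(matrix(stats::rnorm(nrow * ncol), nrow, ncol))
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  d[d == 0] <- 1
  sweep(q, 2L, d, `*`)
}

# Evaluate with a local RNG state so library code does not disturb the
# caller's stream; seed must be a single integer.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
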