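#' @keywords internal
"_PACKAGE"

#' Multivariate normal draws via Cholesky factorization
#'
#' @param n number of draws
#' @param mu mean vector
#' @param sigma covariance matrix (symmetric positive semidefinite)
#' @return n x length(mu) matrix
#' @keywords internal
rmvn <- function(n, mu, sigma) {
  p <- length(mu)
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    stop("covariance matrix is not positive semidefinite")
  }
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% rt, 2, mu, "+")
}

#' z-score a numeric vector (NA-aware)
#' @keywords internal
zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("cannot z-score a zero-variance input")
  (x - mean(x, na.rm = TRUE)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check that a value is a probability
#' @keywords internal
assert_prob <- function(x, what) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

#' Deterministic per-replicate seed from a base seed
#' @keywords internal
replicate_seed <- function(base_seed, index) {
  s <- (as.integer(base_seed) + as.integer(index)) %% .Machine$integer.max
  as.integer(s)
}

#' Symmetrize a matrix
#' @keywords internal
symm <- function(m) (m + t(m)) / 2
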