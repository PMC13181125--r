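# Shared numerical helpers: Gaussian smoothing (linear and circular),
# log-sum-exp, seed substreams.

#' Gaussian smoothing of the rows of a matrix
#'
#' Convolution with a truncated Gaussian kernel (radius 4 sigma), with the
#' kernel renormalized over the in-range support so that edges are handled by
#' shrunken windows and constants are preserved exactly.
#'
#' @param m numeric matrix (rows are smoothed independently) or a vector.
#' @param sigma kernel SD in samples; `sigma <= 0` returns the input.
#' @return smoothed matrix (or vector) of the same shape.
#' @keywords internal
smooth_rows_gaussian <- function(m, sigma) {
  vec <- is.null(dim(m))
  if (vec) m <- matrix(m, nrow = 1)
  if (sigma <= 0) return(if (vec) drop(m) else m)
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  n <- ncol(m)
  pad <- matrix(0, nrow = r, ncol = nrow(m))
  xt <- rbind(pad, t(m), pad)                 # time runs down columns
  ones <- rbind(pad * 0, matrix(1, n, nrow(m)), pad * 0)
  num <- stats::filter(xt, k, sides = 2)
  den <- stats::filter(ones, k, sides = 2)
  out <- t((num / den)[(r + 1):(r + n), , drop = FALSE])
  if (vec) drop(out) else out
}

#' Circular Gaussian smoothing matrix
#'
#' Returns an `n x n` row-stochastic matrix `S` such that `S %*% x` smooths a
#' length-`n` circular signal with a wrapped Gaussian of SD `sd_bins`.
#'
#' @param n number of bins.
#' @param sd_bins kernel SD in bins; 0 gives the identity.
#' @keywords internal
circular_smoother <- function(n, sd_bins) {
  if (sd_bins <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    dd <- abs(i - j)
    pmin(dd, n - dd)
  })
  s <- exp(-d^2 / (2 * sd_bins^2))
  s / rowSums(s)
}

# Row-wise log-sum-exp of a matrix.
logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Named analysis stages draw their own seeds from one master seed so that a
#' single integer reproduces a whole session. Kept within the 32-bit integer
#' range.
#'
#' @param seed master seed (integer).
#' @param offset stage offset (integer).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(offset) * 16807) %% 2147483629) + 1L
}

# Guard: stop() with a consistent message prefix for invalid configuration.
stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
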