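#' Gaussian smoothing of a uniformly sampled trace
#'
#' Convolves a trace with a discrete Gaussian kernel. Edges are handled by
#' reflection so the smoothed trace has no shrink-to-zero artifacts at the
#' session boundaries (matters for the percentile baseline of the first and
#' last windows).
#'
#' @param x numeric vector, uniformly sampled.
#' @param sigma kernel standard deviation in seconds.
#' @param rate sampling rate in Hz.
#' @return numeric vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, sigma, rate) {
  stopifnot(is.numeric(x), sigma >= 0, rate > 0)
  if (sigma == 0 || length(x) < 2L) return(x)
  sigma_smp <- sigma * rate
  half <- max(1L, ceiling(4 * sigma_smp))
  k <- stats::dnorm(seq(-half, half), sd = sigma_smp)
  k <- k / sum(k)
  # reflect-pad so every output sample sees a full kernel
  n <- length(x)
  pad_l <- x[pmin(n, seq(half + 1L, 2L))]
  pad_r <- x[pmax(1L, seq(n - 1L, n - half))]
  xp <- c(pad_l, x, pad_r)
  out <- stats::filter(xp, k, method = "convolution", sides = 2L)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Derive a reproducible sub-stream seed
#'
#' One master seed is split into named sub-streams (behavior, amplitudes,
#' noise, ...) so each component of the generator is independently
#' reproducible. Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stream small integer offset identifying the sub-stream.
#' @keywords internal
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7L + stream * 104729) %% 2147483629)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Half-open window mask over a time axis
#'
#' Samples with t0 <= t < t1; the sample at the window start belongs to the
#' window, the one at the end does not. This makes short bins such as
#' 0--200 ms bit-reproducible.
#' @keywords internal
window_mask <- function(time, window) {
  time >= window[1] & time < window[2]
}
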