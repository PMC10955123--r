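#' Zero-lag Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward so the net
#' phase shift is zero, the standard smoothing step for dynamometer torque,
#' angle and velocity channels before any segmentation.
#'
#' The filter coefficients come from [signal::butter()]. The forward-backward
#' application is done with odd-reflection padding and steady-state initial
#' conditions, which keeps constant (DC) signals exact to machine precision
#' and avoids the start-up transient of a zero-initialized IIR filter. The
#' effective magnitude response is the squared Butterworth magnitude, so a
#' 5th-order filter attenuates by ten poles' worth.
#'
#' @param series numeric vector, uniformly sampled.
#' @param sampling_rate sampling frequency in Hz.
#' @param cutoff low-pass cut-off frequency in Hz (default 6).
#' @param order filter order (default 5).
#' @return numeric vector, same length as `series`.
#' @examples
#' t <- seq(0, 2, by = 1 / 200)
#' x <- sin(2 * pi * t) + rnorm(length(t), sd = 0.05)
#' y <- filter_zero_lag(x, 200)
#' @export
filter_zero_lag <- function(series, sampling_rate, cutoff = 6, order = 5L) {
  stop_if_not_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  stop_if_not_scalar_num(cutoff, "cutoff", positive = TRUE)
  if (cutoff >= sampling_rate / 2)
    stop("cutoff must be below the Nyquist frequency (sampling_rate/2)", call. = FALSE)
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "low")
  pad <- 3L * max(length(bf$a), length(bf$b))
  n <- length(series)
  if (n <= pad)
    stop(sprintf("series too short for zero-lag filtering: need more than %d samples, got %d",
                 pad, n), call. = FALSE)
  # odd reflection about both endpoints suppresses edge transients
  pre <- 2 * series[1L] - series[(pad + 1L):2L]
  post <- 2 * series[n] - series[(n - 1L):(n - pad)]
  xe <- c(pre, series, post)
  y <- lfilter_ss(bf$b, bf$a, xe, xe[1L])
  y <- rev(lfilter_ss(bf$b, bf$a, rev(y), y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

# One-directional IIR filtering with the state initialized to the steady-state
# response for a constant input x0 (so a signal "at x0 since forever" has no
# transient).  FIR part via convolution with x0-history, recursive part via
# stats::filter with matching initial outputs.
lfilter_ss <- function(b, a, x, x0) {
  nb <- length(b)
  na <- length(a)
  xf <- c(rep(x0, nb - 1L), x)
  yf <- as.numeric(stats::filter(xf, b, method = "convolution", sides = 1))
  yf <- yf[nb:(nb + length(x) - 1L)]
  y_ss <- x0 * sum(b) / sum(a)
  as.numeric(stats::filter(yf, -a[-1L], method = "recursive", init = rep(y_ss, na - 1L)))
}
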