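# Zero-phase symmetric triangular FIR smoothing and numerical differentiation
# used throughout the trial-analysis pipeline.

#' Symmetric triangular FIR kernel for a given cutoff frequency
#'
#' A zero-phase FIR low-pass with triangular weights `w_j = (m + 1 - |j|)`,
#' `j = -m..m`, normalized to DC gain 1.  Its amplitude response is the Fejer
#' kernel `[sin(pi f (m+1)/fs) / ((m+1) sin(pi f/fs))]^2`.  The integer
#' half-width `m` is chosen numerically so that the gain at `cutoff_hz` is as
#' close as possible to the -3 dB value `1/sqrt(2)`; an error is raised if no
#' integer half-width achieves gain `0.707 +/- 0.02` at the cutoff (achievable
#' -3 dB frequencies of integer-width kernels are discrete, so the gain at the
#' cutoff - not the -3 dB frequency itself - is the design criterion).
#'
#' @param cutoff_hz desired -3 dB frequency (Hz); `0 < cutoff_hz < fs/2`.
#' @param fs sampling rate (Hz), default 1000.
#' @return numeric kernel of odd length `2m + 1` summing to 1, with
#'   attributes `halfwidth` and `gain_at_cutoff`.
#' @export
#' @examples
#' k <- make_triangular_filter(17)
#' sum(k)            # 1 (DC gain)
#' attr(k, "gain_at_cutoff")  # ~0.707
make_triangular_filter <- function(cutoff_hz, fs = 1000) {
  stopifnot(cutoff_hz > 0, cutoff_hz < fs / 2)
  gain <- function(m, f) {
    x <- pi * f * (m + 1) / fs
    (sin(x) / ((m + 1) * sin(pi * f / fs)))^2
  }
  ms <- 1:floor(fs / 2)
  g <- vapply(ms, gain, numeric(1), f = cutoff_hz)
  best <- which.min(abs(g - 1 / sqrt(2)))
  if (abs(g[best] - 1 / sqrt(2)) > 0.02) {
    stop("make_triangular_filter: no integer half-width gives gain 0.707 ",
         "+/- 0.02 at ", cutoff_hz, " Hz (best: ", signif(g[best], 4), ")")
  }
  m <- ms[best]
  w <- (m + 1 - abs(-m:m))
  w <- w / sum(w)
  attr(w, "halfwidth") <- m
  attr(w, "gain_at_cutoff") <- g[best]
  w
}

#' Low-pass filter a trace with a symmetric triangular kernel
#'
#' Zero-phase FIR smoothing with reflection padding at the trace ends (the
#' trace is mirrored about its first and last samples), so the output has the
#' same length as the input and no phase delay.
#'
#' @param x numeric trace.
#' @param cutoff_hz -3 dB frequency (Hz).
#' @param fs sampling rate (Hz).
#' @return filtered trace, same length as `x`.
#' @export
filter_lowpass <- function(x, cutoff_hz, fs = 1000) {
  w <- make_triangular_filter(cutoff_hz, fs)
  m <- attr(w, "halfwidth")
  n <- length(x)
  if (n < 2L) return(x)
  # reflect about the end samples (end samples not repeated)
  li <- pmin(n, 1L + ((2L:(m + 1L)) - 1L))        # 2..m+1, clamped
  ri <- pmax(1L, n - (1L:m))                      # n-1..n-m, clamped
  xp <- c(x[rev(li)], x, x[ri])
  y <- stats::filter(xp, w, method = "convolution", sides = 2)
  as.numeric(y[(m + 1L):(m + n)])
}

#' High-pass filter as identity minus low-pass
#'
#' The symmetric triangular "high-pass" used for sub-movement segmentation:
#' the trace minus its triangular low-pass at the given cutoff.
#'
#' @inheritParams filter_lowpass
#' @return high-passed trace.
#' @export
filter_highpass <- function(x, cutoff_hz, fs = 1000) {
  x - filter_lowpass(x, cutoff_hz, fs)
}

#' Symmetric numerical time derivative
#'
#' Central difference over +/- 1 sample, `(x[t+1] - x[t-1]) / (2 dt)`, with
#' one-sided differences at the trace ends.
#'
#' @param x numeric trace.
#' @param fs sampling rate (Hz).
#' @return derivative, same length as `x`, in units of `x` per second.
#' @export
symmetric_derivative <- function(x, fs = 1000) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  dt <- 1 / fs
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

# Local extrema of a trace in the strict sample sense, with plateaus resolved
# to their earliest sample.  Returns integer indices.
local_extrema <- function(x, what = c("min", "max")) {
  what <- match.arg(what)
  if (what == "max") x <- -x
  n <- length(x)
  if (n < 3L) return(integer(0))
  # run-length encode so plateaus count once, at their first sample
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  inner <- 2:(k - 1)
  ismin <- r$values[inner] < r$values[inner - 1] &
    r$values[inner] < r$values[inner + 1]
  starts[inner][ismin]
}
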