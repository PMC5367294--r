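# Zero-phase low-pass filtering of marker coordinate series.
#
# Coefficients come from signal::butter(); the forward-backward pass is done
# here because the contract requires exact unit DC gain and minimal edge
# transients: the series is extended by symmetric (even) reflection about
# both endpoints -- which neither amplifies measurement noise at the edges
# nor distorts series that start and end near rest, as marker tracks do --
# and each pass starts from the filter's steady-state initial conditions
# scaled to the first padded sample, so a constant input is reproduced to
# machine precision.

# steady-state initial conditions of the direct-form-II-transposed filter
# for a unit-amplitude step (the classic lfilter_zi construction)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  A <- rbind(-a[2:n], cbind(diag(n - 2), 0))
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# direct-form-II-transposed IIR filter with initial state zi
iir_filter <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  y <- numeric(length(x))
  z <- zi
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    for (j in seq_len(n - 2)) {
      z[j] <- b[j + 1] * x[i] + z[j + 1] - a[j + 1] * y[i]
    }
    z[n - 1] <- b[n] * x[i] - a[n] * y[i]
  }
  y
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters a numeric series forward and backward with an order-`order`
#' Butterworth low-pass filter, giving zero phase lag (a forward-backward
#' pass doubles the effective order and squares the magnitude response).
#' Edges are handled by odd reflection padding plus steady-state initial
#' conditions, so the DC gain is exactly 1.
#'
#' @param x numeric series (regularly sampled, no gaps).
#' @param cutoff_hz cutoff frequency in Hz (default 5, the standard choice
#'   for pecking kinematics).
#' @param fs sampling rate in Hz.
#' @param order filter order for each pass (default 4).
#' @return Filtered series, same length as `x`.
#' @export
butter_lowpass <- function(x, cutoff_hz = 5, fs = 300, order = 4) {
  stopifnot(cutoff_hz > 0, fs > 0, cutoff_hz < fs / 2)
  n <- length(x)
  if (n < 3 * order) {
    peckkin_stop("too_short",
                 sprintf("series of length %d is too short for stable order-%d filtering (need >= %d)",
                         n, order, 3 * order))
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  b <- bf$b
  a <- bf$a
  padlen <- min(n - 1, 9 * (order + 1))
  xf <- c(x[(padlen + 1):2], x, x[(n - 1):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, xf, zi * xf[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Smooth a marker track
#'
#' Applies the zero-phase Butterworth low-pass filter of [butter_lowpass()]
#' independently to the x and y coordinates of a gap-free [marker_track].
#' Frame indices are unchanged.
#'
#' @param track a [marker_track] without internal gaps.
#' @param cutoff cutoff frequency in Hz (default 5).
#' @param order filter order per pass (default 4; applied forward and
#'   backward for zero phase).
#' @return The smoothed [marker_track].
#' @export
smooth_track <- function(track, cutoff = 5, order = 4) {
  stopifnot(inherits(track, "marker_track"))
  if (track_has_gaps(track)) {
    peckkin_stop("gap",
                 sprintf("track '%s' has missing frames inside its range; split at the gap or discard the peck",
                         track$marker))
  }
  track$x <- butter_lowpass(track$x, cutoff, track$frame_rate, order)
  track$y <- butter_lowpass(track$y, cutoff, track$frame_rate, order)
  track
}
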