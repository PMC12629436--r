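#' Construct a pupil-diameter trace
#'
#' Binocular pupil-diameter samples at a uniform rate with a per-sample
#' validity flag. Invalid samples (blinks, tracking loss) carry `NA`
#' diameters; the validity flag, not the sentinel, is authoritative.
#'
#' @param t Sample times in seconds, uniformly spaced (tolerance 1e-6 s).
#' @param left_mm,right_mm Pupil diameters in millimetres (`NA` where
#'   invalid).
#' @param valid Logical vector; `FALSE` marks blink/artifact samples.
#' @return A `pupil_trace`: data frame with columns `t`, `left_mm`,
#'   `right_mm`, `valid` and attribute `sample_rate` (Hz).
#' @export
pupil_trace <- function(t, left_mm, right_mm, valid = rep(TRUE, length(t))) {
  n <- length(t)
  if (length(left_mm) != n || length(right_mm) != n || length(valid) != n)
    stop("t, left_mm, right_mm and valid must have equal length")
  if (n < 2L) stop("a pupil trace needs at least 2 samples")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6)
    stop("pupil trace must be uniformly sampled (tolerance 1e-6 s)")
  if (any(c(left_mm[valid], right_mm[valid]) <= 0, na.rm = TRUE))
    stop("valid pupil diameters must be positive")
  out <- data.frame(t = t, left_mm = left_mm, right_mm = right_mm,
                    valid = as.logical(valid))
  attr(out, "sample_rate") <- 1 / mean(dt)
  class(out) <- c("pupil_trace", "data.frame")
  out
}

#' Remove blinks by linear interpolation
#'
#' Replaces invalid spans with straight-line interpolation between the
#' nearest valid neighbours, independently per eye. Invalid spans touching
#' the trace edge are extended with the nearest valid value. Validity flags
#' are updated and the number and total length of interpolated spans recorded
#' in the `blink_spans` attribute.
#'
#' @param trace A [pupil_trace()].
#' @return The trace with all samples valid; idempotent.
#' @export
interpolate_blinks <- function(trace) {
  if (!any(trace$valid)) stop("no valid samples to interpolate from")
  bad <- !trace$valid
  runs <- rle(bad)
  spans <- sum(runs$values)
  for (eye in c("left_mm", "right_mm")) {
    v <- trace[[eye]]
    ok <- trace$valid & !is.na(v)
    if (!any(ok)) stop(sprintf("no valid samples in %s", eye))
    if (any(!ok)) {
      v[!ok] <- stats::approx(trace$t[ok], v[ok], xout = trace$t[!ok],
                              method = "linear", rule = 2)$y
      trace[[eye]] <- v
    }
  }
  trace$valid <- rep(TRUE, nrow(trace))
  attr(trace, "blink_spans") <- list(n = spans, n_samples = sum(bad))
  trace
}

# Steady-state initial conditions for a direct-form-II-transposed IIR filter,
# so filtering a constant signal is exact from the first sample.
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  A <- rbind(-a[-1L], cbind(diag(1, n - 1L), 0))
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n) - t(A), B)
}

# IIR filter (direct form II transposed) with initial state zi.
iir_filter <- function(b, a, x, zi) {
  n <- length(a) - 1L
  z <- zi
  y <- numeric(length(x))
  for (m in seq_along(x)) {
    y[m] <- b[1L] * x[m] + z[1L]
    if (n > 1L)
      z[1:(n - 1L)] <- b[2:n] * x[m] + z[2:n] - a[2:n] * y[m]
    z[n] <- b[n + 1L] * x[m] - a[n + 1L] * y[m]
  }
  y
}

#' Zero-phase Butterworth low-pass filter
#'
#' Smooths a signal with a Butterworth low-pass filter applied forward and
#' backward (zero phase, squared magnitude response). Edge transients are
#' suppressed by odd-reflection padding and steady-state initial conditions,
#' so constant signals pass through unchanged to machine precision.
#'
#' @param x Numeric signal.
#' @param sample_rate Sampling rate in Hz.
#' @param cutoff_hz Cutoff frequency; must be below the Nyquist rate. The
#'   default 4 Hz (with `order` 2) is conventional for 60 Hz pupillometry.
#' @param order Filter order (per pass).
#' @return Filtered signal, same length as `x`.
#' @export
lowpass <- function(x, sample_rate, cutoff_hz = 4, order = 2) {
  if (cutoff_hz >= sample_rate / 2)
    stop("cutoff must be below the Nyquist frequency")
  if (any(!is.finite(x))) stop("signal contains non-finite values")
  bf <- signal::butter(order, cutoff_hz / (sample_rate / 2), type = "low")
  b <- bf$b; a <- bf$a
  npad <- min(length(x) - 1L, 3L * (max(length(a), length(b)) - 1L) * 10L)
  xp <- c(2 * x[1L] - rev(x[2L:(npad + 1L)]),
          x,
          2 * x[length(x)] - rev(x[(length(x) - npad):(length(x) - 1L)]))
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, xp, zi * xp[1L])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(npad + 1L):(npad + length(x))]
}

#' Mean pupil diameter of a preprocessed trace
#'
#' The per-trial pupil feature Dm: the time average of the binocular mean
#' diameter `(left + right) / 2` over the analysis window.
#'
#' @param trace A [pupil_trace()], typically after [interpolate_blinks()] and
#'   [lowpass()].
#' @return Mean diameter in millimetres.
#' @export
mean_pupil <- function(trace) {
  if (nrow(trace) == 0L) stop("empty analysis window")
  mean((trace$left_mm + trace$right_mm) / 2)
}

#' Per-trial pupil feature pipeline
#'
#' Fixed preprocessing order: interpolate blinks, low-pass filter each eye,
#' average the eyes, then take the window mean. z-scoring across trials is a
#' separate dataset-level step ([zscore()]).
#'
#' @inheritParams lowpass
#' @param trace A raw [pupil_trace()].
#' @return Mean pupil diameter Dm in millimetres.
#' @export
pupil_feature <- function(trace, cutoff_hz = 4, order = 2) {
  sr <- attr(trace, "sample_rate")
  trace <- interpolate_blinks(trace)
  trace$left_mm <- lowpass(trace$left_mm, sr, cutoff_hz, order)
  trace$right_mm <- lowpass(trace$right_mm, sr, cutoff_hz, order)
  mean_pupil(trace)
}
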