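# Zero-phase FIR filtering helpers shared by the ECG and EMG front ends.
#
# Filters are windowed-sinc designs (signal::fir1) with an odd number of taps,
# applied once with reflection padding; the group delay of a symmetric FIR is
# exactly (ntaps-1)/2 samples, so delay compensation yields a zero-phase
# response without a second filter pass.

# number of taps for a Hamming-windowed design with a given transition width
.fir_ntaps <- function(fs, transition_hz, n_signal) {
  nt <- ceiling(3.3 * fs / transition_hz)
  if (nt %% 2 == 0) nt <- nt + 1
  # never let the kernel exceed the signal (short inputs in tests)
  max_nt <- n_signal - 1
  if (max_nt %% 2 == 0) max_nt <- max_nt - 1
  min(nt, max(5, max_nt))
}

# apply symmetric FIR h (odd length) with zero phase via reflection padding
.fir_zero_phase <- function(x, h) {
  n <- length(x)
  m <- (length(h) - 1L) / 2L
  if (m < 1L) return(as.numeric(signal::fftfilt(h, x)))
  mm <- min(m, n - 1L)
  pre <- x[1L] + (x[1L] - x[(mm + 1L):2L])
  post <- x[n] + (x[n] - x[(n - 1L):(n - mm)])
  if (mm < m) { # short signal: extend with constants
    pre <- c(rep(pre[1L], m - mm), pre)
    post <- c(post, rep(post[length(post)], m - mm))
  }
  xp <- c(pre, x, post)
  y <- as.numeric(signal::fftfilt(h, xp))
  y[(2L * m + 1L):(2L * m + n)]
}

#' Zero-phase FIR band-pass / high-pass / low-pass filter
#'
#' Windowed-sinc FIR filter applied with exact zero-phase (group-delay
#' compensated symmetric kernel, reflection padding at the edges).
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param low lower pass-band edge in Hz, or `NULL` for a low-pass.
#' @param high upper pass-band edge in Hz, or `NULL` for a high-pass.
#' @param transition transition band width in Hz (controls kernel length;
#'   defaults to half the lowest nonzero edge).
#' @return filtered signal, same length as `x`.
#' @export
fir_filter <- function(x, fs, low = NULL, high = NULL, transition = NULL) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("signal must be finite and free of NA")
  if (is.null(low) && is.null(high)) stop("specify at least one band edge")
  nyq <- fs / 2
  if (!is.null(high) && high >= nyq)
    stop("upper band edge must lie below the Nyquist frequency")
  if (is.null(transition))
    transition <- if (!is.null(low)) low / 2 else high / 10
  nt <- .fir_ntaps(fs, transition, length(x))
  h <- if (!is.null(low) && !is.null(high)) {
    signal::fir1(nt - 1L, c(low, high) / nyq, type = "pass")
  } else if (!is.null(low)) {
    signal::fir1(nt - 1L, low / nyq, type = "high")
  } else {
    signal::fir1(nt - 1L, high / nyq, type = "low")
  }
  .fir_zero_phase(x, as.numeric(h))
}

# centered moving RMS with edge padding (window in samples, forced odd)
.moving_rms <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  m <- (w - 1L) / 2L
  xp <- c(rep(x[1L], m), x, rep(x[length(x)], m))
  cs <- cumsum(c(0, xp^2))
  sqrt((cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]) / w)
}

# pink (1/f amplitude) noise via spectral shaping of white noise
.pink_noise <- function(n, sd = 1) {
  white <- rnorm(n)
  xf <- fft(white)
  f <- c(1, seq_len(n - 1))          # avoid division by zero at DC
  f <- pmin(f, n - f + 1)            # symmetric frequency index
  xf <- xf / sqrt(f)
  out <- Re(fft(xf, inverse = TRUE)) / n
  out * sd / sd(out)
}
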