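# Hamming windowed-sinc FIR filters (linear phase, even order) and their
# single-pass, group-delay-compensated application.

#' Design a Hamming windowed-sinc FIR filter
#'
#' Builds a linear-phase FIR kernel by windowing the ideal sinc response with
#' a Hamming window.  The ideal cutoff is placed at the half-amplitude
#' (-6 dB) frequency, i.e. `passband_edge - transition_bw/2` for a high-pass
#' and `passband_edge + transition_bw/2` for a low-pass, so the realized
#' -6 dB point of the kernel lands on that frequency.  High-pass kernels are
#' obtained by spectral inversion of the complementary low-pass.
#'
#' @param kind `"highpass"` or `"lowpass"`.
#' @param passband_edge_hz Passband edge frequency (Hz).
#' @param transition_bw_hz Transition bandwidth (Hz).
#' @param order Filter order (number of taps minus one); must be even so the
#'   group delay `order/2` is an integer number of samples.
#' @param sfreq_hz Sampling rate (Hz). Default 256.
#' @return A `fir_kernel` object with fields `coefficients`, `order`, `kind`,
#'   `passband_edge_hz`, `transition_bw_hz`, `cutoff_minus6db_hz`, `sfreq_hz`.
#' @export
#' @examples
#' k <- design_windowed_sinc_fir("lowpass", 30, 7.4, 114)
#' fir_minus6db(k)   # ~33.7 Hz
design_windowed_sinc_fir <- function(kind = c("highpass", "lowpass"),
                                     passband_edge_hz, transition_bw_hz,
                                     order, sfreq_hz = 256) {
  kind <- match.arg(kind)
  nyq <- sfreq_hz / 2
  if (order %% 2 != 0 || order < 2) {
    abort("filter order must be even and >= 2 (integer group delay)")
  }
  cutoff <- if (kind == "highpass") {
    passband_edge_hz - transition_bw_hz / 2
  } else {
    passband_edge_hz + transition_bw_hz / 2
  }
  if (cutoff <= 0 || cutoff >= nyq || passband_edge_hz >= nyq) {
    abort(sprintf("cutoff %.3f Hz outside (0, Nyquist = %g Hz)", cutoff, nyq))
  }
  m <- order
  n <- 0:m
  fc <- cutoff / sfreq_hz                 # cycles per sample
  x <- n - m / 2
  sinc <- ifelse(x == 0, 2 * fc, sin(2 * pi * fc * x) / (pi * x))
  w <- 0.54 - 0.46 * cos(2 * pi * n / m)  # Hamming
  h <- sinc * w
  h <- h / sum(h)                          # unit DC gain low-pass
  if (kind == "highpass") {
    delta <- numeric(m + 1)
    delta[m / 2 + 1] <- 1
    h <- delta - h                         # spectral inversion
  }
  structure(
    list(coefficients = h, order = m, kind = kind,
         passband_edge_hz = passband_edge_hz,
         transition_bw_hz = transition_bw_hz,
         cutoff_minus6db_hz = cutoff, sfreq_hz = sfreq_hz),
    class = "fir_kernel"
  )
}

#' @export
print.fir_kernel <- function(x, ...) {
  cat(sprintf("<fir_kernel> %s, order %d, passband edge %g Hz, -6 dB at %g Hz (fs = %g Hz)\n",
              x$kind, x$order, x$passband_edge_hz, x$cutoff_minus6db_hz,
              x$sfreq_hz))
  invisible(x)
}

#' Zero-phase amplitude response of a linear-phase FIR kernel
#'
#' @param kernel A `fir_kernel` (or bare coefficient vector with odd length).
#' @param freqs_hz Frequencies at which to evaluate the response.
#' @param sfreq_hz Sampling rate; taken from the kernel when available.
#' @return Numeric vector of (signed) zero-phase amplitudes; the magnitude
#'   response is its absolute value.
#' @export
fir_frequency_response <- function(kernel, freqs_hz, sfreq_hz = NULL) {
  h <- if (inherits(kernel, "fir_kernel")) kernel$coefficients else kernel
  fs <- sfreq_hz %||% kernel$sfreq_hz
  m2 <- (length(h) - 1) / 2
  k <- seq_along(h) - 1 - m2
  vapply(freqs_hz, function(f) sum(h * cos(2 * pi * f / fs * k)), numeric(1))
}

#' Measured half-amplitude (-6 dB) frequency of an FIR kernel
#'
#' Locates the frequency at which the amplitude response crosses 0.5, by
#' root finding within the filter's transition band.
#'
#' @param kernel A `fir_kernel`.
#' @return Frequency in Hz.
#' @export
fir_minus6db <- function(kernel) {
  stopifnot(inherits(kernel, "fir_kernel"))
  tb2 <- kernel$transition_bw_hz
  lo <- max(1e-6, kernel$cutoff_minus6db_hz - tb2)
  hi <- min(kernel$sfreq_hz / 2 - 1e-6, kernel$cutoff_minus6db_hz + tb2)
  f <- function(fr) abs(fir_frequency_response(kernel, fr)) - 0.5
  uniroot(f, c(lo, hi), tol = 1e-8)$root
}

# linear convolution via FFT
conv_fft <- function(x, h) {
  n <- length(x) + length(h) - 1
  nfft <- stats::nextn(n, 2)
  y <- Re(fft(fft(c(x, numeric(nfft - length(x)))) *
                fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Apply an FIR kernel to a continuous recording
#'
#' Single-pass convolution with group-delay compensation: the output is
#' shifted back by `order/2` samples so features stay time-locked, and the
#' input is edge-padded (first/last sample replicated) so the output length
#' equals the input length.
#'
#' @param rec A `continuous_recording`.
#' @param kernel A `fir_kernel` from [design_windowed_sinc_fir()].
#' @return The filtered `continuous_recording`.
#' @export
apply_fir <- function(rec, kernel) {
  stopifnot(inherits(rec, "continuous_recording"))
  h <- if (inherits(kernel, "fir_kernel")) kernel$coefficients else kernel
  n <- ncol(rec$data)
  if (n <= length(h)) {
    abort(sprintf("recording (%d samples) must be longer than the kernel (%d taps)",
                  n, length(h)))
  }
  m2 <- (length(h) - 1) %/% 2
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    xp <- c(rep(x[1], m2), x, rep(x[n], m2))
    y <- conv_fft(xp, h)
    out$data[i, ] <- y[2 * m2 + seq_len(n)]
  }
  out
}
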