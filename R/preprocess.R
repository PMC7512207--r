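#' Windowed-sinc FIR band-pass kernel (Hamming window)
#'
#' Linear-phase band-pass design. The default order targets a ~1 Hz
#' transition width at 200 Hz sampling (Hamming rule of thumb
#' `order ~ 3.3 * fs / transition`), giving an order-660 kernel.
#'
#' @param fs Sampling rate (Hz).
#' @param low,high Band edges (Hz).
#' @param order Even filter order; `NULL` picks the 1 Hz-transition default.
#' @return Numeric kernel of length `order + 1` (symmetric, unit DC-band gain).
#' @export
fir_bandpass <- function(fs, low = 1, high = 70, order = NULL) {
  if (fs <= 2 * high) stopf("fs must exceed twice the upper band edge")
  if (low <= 0 || low >= high) stopf("need 0 < low < high")
  if (is.null(order)) order <- 2L * ceiling(3.3 * fs / 1 / 2)
  if (order %% 2 != 0) order <- order + 1L
  m <- order / 2
  k <- -m:m
  sinc <- function(fc) {
    out <- 2 * fc / fs * rep(1, length(k))
    nz <- k != 0
    out[nz] <- sin(2 * pi * fc / fs * k[nz]) / (pi * k[nz])
    out
  }
  h <- (sinc(high) - sinc(low)) *
    (0.54 + 0.46 * cos(pi * k / m))          # Hamming
  h
}

#' Zero-phase FIR band-pass filter
#'
#' Applies a symmetric (linear-phase) windowed-sinc kernel by centred
#' convolution with reflective edge padding, so epoch-relative timing is
#' preserved and the output has the input's length.
#'
#' @param x 1-D amplitude series.
#' @param fs Sampling rate (Hz); must exceed 140 Hz for the default band.
#' @param low,high Pass-band edges (Hz), default 1--70.
#' @param order Optional FIR order (even).
#' @return Filtered series, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 1, high = 70, order = NULL) {
  h <- fir_bandpass(fs, low, high, order)
  m <- (length(h) - 1L) / 2L
  if (length(x) < length(h))
    stopf("series length (%d) must be at least filter order + 1 (%d)",
          length(x), length(h))
  xp <- c(2 * x[1] - x[(m + 1):2], x, 2 * x[length(x)] - x[(length(x) - 1):(length(x) - m)])
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(y[(m + 1):(m + length(x))])
}

# Biquad band-stop (RBJ cookbook notch), coefficients for f0/bw in Hz.
notch_coefs <- function(fs, f0, bw) {
  w0 <- 2 * pi * f0 / fs
  q <- f0 / bw
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

iir_pass <- function(x, b, a) {
  v <- stats::filter(c(0, 0, x), b, method = "convolution", sides = 1)
  v <- v[-(1:2)]
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

#' Zero-phase 50 Hz notch filter
#'
#' Second-order band-stop biquad (2 Hz bandwidth by default) applied
#' forward and backward, with reflective padding to suppress edge
#' transients. Attenuation at `f0` far exceeds 20 dB while tones 5 Hz away
#' change by well under 1 dB.
#'
#' @param x 1-D amplitude series.
#' @param fs Sampling rate (Hz).
#' @param f0 Notch frequency (Hz), default 50 (power-line).
#' @param bw Stop-band width (Hz).
#' @return Filtered series, same length as `x`.
#' @export
notch_filter <- function(x, fs, f0 = 50, bw = 2) {
  if (f0 >= fs / 2) stopf("notch frequency must lie below the Nyquist rate")
  co <- notch_coefs(fs, f0, bw)
  np <- min(length(x) - 1L, 3L * ceiling(fs / bw))
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[length(x)] - x[(length(x) - 1):(length(x) - np)])
  y <- iir_pass(xp, co$b, co$a)
  y <- rev(iir_pass(rev(y), co$b, co$a))
  y[(np + 1):(np + length(x))]
}

#' Segment a continuous multichannel recording into fixed-length epochs
#'
#' Cuts non-overlapping consecutive epochs of `epoch_seconds`; a trailing
#' remainder shorter than one epoch is discarded.
#'
#' @param continuous `channels x samples` numeric matrix.
#' @param fs Sampling rate (Hz).
#' @param epoch_seconds Epoch duration (s).
#' @return `trials x channels x samples` array.
#' @export
segment_epochs <- function(continuous, fs, epoch_seconds = 5) {
  if (is.vector(continuous)) continuous <- matrix(continuous, nrow = 1)
  len <- as.integer(round(fs * epoch_seconds))
  n <- ncol(continuous)
  n_epochs <- n %/% len
  if (n_epochs < 1L)
    stopf("recording (%d samples) shorter than one %g-s epoch (%d samples)",
          n, epoch_seconds, len)
  out <- array(0, dim = c(n_epochs, nrow(continuous), len))
  for (e in seq_len(n_epochs))
    out[e, , ] <- continuous[, ((e - 1L) * len + 1L):(e * len), drop = FALSE]
  out
}
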