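#' Construct a normalized power spectral density object
#'
#' @param freqs Strictly increasing, uniformly spaced frequency grid (Hz).
#' @param values Non-negative spectral mass per grid point.
#' @param normalize Renormalize `values` to unit sum (default `TRUE`).
#' @return An object of class `"psdn"` with unit total mass.
#' @export
psdn <- function(freqs, values, normalize = TRUE) {
  if (length(freqs) != length(values)) stopf("freqs/values length mismatch")
  if (any(values < 0)) stopf("PSD values must be non-negative")
  if (length(freqs) > 1) {
    d <- diff(freqs)
    if (any(d <= 0)) stopf("frequency grid must be strictly increasing")
    if (max(d) - min(d) > 1e-9 * max(d)) stopf("frequency grid must be uniform")
  }
  tot <- sum(values)
  if (tot <= 0) stopf("degenerate PSD: total spectral mass is zero")
  if (normalize) values <- values / tot
  structure(list(freqs = freqs, values = values), class = "psdn")
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# Welch segment matrix -> averaged one-sided raw periodogram.
welch_raw <- function(x, fs, window_seconds, overlap) {
  L <- as.integer(round(window_seconds * fs))
  n <- length(x)
  if (L > n) L <- n
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq.int(1L, n - L + 1L, by = step)
  w <- hamming_window(L)
  segs <- vapply(starts, function(s) x[s:(s + L - 1L)] * w, numeric(L))
  p <- abs(mvfft(as.matrix(segs)))^2
  half <- L %/% 2 + 1L
  list(freqs = (0:(half - 1L)) * fs / L,
       power = rowMeans(p[seq_len(half), , drop = FALSE]))
}

#' Normalized power spectral density of one epoch
#'
#' Estimates the PSD (Welch with 1-s Hamming windows and 50% overlap by
#' default, i.e. 1 Hz resolution at 200 Hz; or a raw periodogram), truncates
#' it to the 1--70 Hz analysis band and renormalizes to unit sum.
#'
#' @param epoch 1-D amplitude series (at least 2 s of samples).
#' @param fs Sampling rate (Hz).
#' @param estimator `"welch"` or `"periodogram"`.
#' @param window_seconds,overlap Welch segmentation parameters.
#' @param fmin,fmax Analysis band (Hz).
#' @return A `"psdn"` object.
#' @export
compute_psdn <- function(epoch, fs, estimator = c("welch", "periodogram"),
                         window_seconds = 1, overlap = 0.5,
                         fmin = 1, fmax = 70) {
  estimator <- match.arg(estimator)
  if (length(epoch) < 2 * fs) stopf("epoch must contain at least 2 s of samples")
  if (all(epoch == 0)) stopf("degenerate input: all-zero epoch")
  if (estimator == "welch") {
    est <- welch_raw(epoch, fs, window_seconds, overlap)
  } else {
    n <- length(epoch)
    p <- abs(fft(epoch))^2
    half <- n %/% 2 + 1L
    est <- list(freqs = (0:(half - 1L)) * fs / n, power = p[seq_len(half)])
  }
  keep <- est$freqs >= fmin & est$freqs <= fmax
  psdn(est$freqs[keep], est$power[keep])
}

band_index <- function(psd, f1, f2) {
  fmax <- max(psd$freqs)
  if (f1 < min(psd$freqs) - 1e-9 || f2 > fmax + 1e-9)
    stopf("band [%g, %g] outside PSD grid [%g, %g]", f1, f2, min(psd$freqs), fmax)
  # half-open [f1, f2); the top analysis edge is included so bands tile [1, 70]
  psd$freqs >= f1 - 1e-9 & (psd$freqs < f2 - 1e-9 | f2 >= fmax - 1e-9)
}

#' Relative power in a frequency band
#'
#' Sum of normalized spectral mass over grid points in `[f1, f2)`; the band
#' containing the top analysis edge includes it, so the six conventional
#' bands partition the full range and their relative powers sum to 1.
#'
#' @param psd A `"psdn"` object.
#' @param f1,f2 Band edges (Hz), `f1 < f2`.
#' @return Fraction in `[0, 1]`.
#' @export
relative_power <- function(psd, f1, f2) {
  if (!inherits(psd, "psdn")) stopf("psd must be a psdn object")
  if (f1 >= f2) stopf("need f1 < f2")
  sum(psd$values[band_index(psd, f1, f2)])
}

#' Median frequency of a normalized PSD
#'
#' Smallest grid frequency at which the cumulative normalized spectral mass
#' reaches one half.
#'
#' @param psd A `"psdn"` object.
#' @return Frequency in Hz.
#' @export
median_frequency <- function(psd) {
  if (!inherits(psd, "psdn")) stopf("psd must be a psdn object")
  cs <- cumsum(psd$values) / sum(psd$values)
  psd$freqs[which(cs >= 0.5 - 1e-12)[1]]
}

#' Individual alpha frequency
#'
#' Median-frequency rule restricted to the extended alpha band: the smallest
#' grid frequency in \[4, 15\] Hz at which the cumulative mass inside the
#' band reaches half the band's total mass. Tracks the alpha peak while
#' ignoring delta and gamma activity.
#'
#' @param psd A `"psdn"` object.
#' @param band Extended alpha band edges (Hz), default `c(4, 15)`.
#' @return Frequency in Hz.
#' @export
individual_alpha_frequency <- function(psd, band = c(4, 15)) {
  if (!inherits(psd, "psdn")) stopf("psd must be a psdn object")
  idx <- which(psd$freqs >= band[1] - 1e-9 & psd$freqs <= band[2] + 1e-9)
  mass <- sum(psd$values[idx])
  if (mass <= 0) stopf("degenerate input: no spectral mass in [%g, %g] Hz", band[1], band[2])
  cs <- cumsum(psd$values[idx]) / mass
  psd$freqs[idx][which(cs >= 0.5 - 1e-12)[1]]
}

#' Spectral entropy of a normalized PSD
#'
#' Shannon entropy of the normalized spectral mass, divided by the log of
#' the number of grid points, so a flat spectrum scores 1 and a single-bin
#' point mass scores 0.
#'
#' @param psd A `"psdn"` object.
#' @return Value in `[0, 1]`.
#' @export
spectral_entropy <- function(psd) {
  if (!inherits(psd, "psdn")) stopf("psd must be a psdn object")
  p <- psd$values / sum(psd$values)
  p <- p[p > 0]
  if (length(psd$values) < 2) return(0)
  -sum(p * log(p)) / log(length(psd$values))
}

#' All nine spectral features of one epoch
#'
#' @param epoch 1-D amplitude series.
#' @param fs Sampling rate (Hz).
#' @param ... Passed to [compute_psdn()].
#' @return Named numeric vector: six relative powers, MF, IAF, SE.
#' @export
spectral_features <- function(epoch, fs, ...) {
  psd <- compute_psdn(epoch, fs, ...)
  bands <- eeg_bands()
  rp <- vapply(bands, function(b) relative_power(psd, b[1], b[2]), 0)
  c(stats::setNames(rp, paste0("RP_", names(bands))),
    MF = median_frequency(psd),
    IAF = individual_alpha_frequency(psd),
    SE = spectral_entropy(psd))
}
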