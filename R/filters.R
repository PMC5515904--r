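# Zero-phase frequency-domain filtering.
#
# All filters in the package are applied by multiplying the FFT of each
# channel with a real, non-negative gain curve and inverting the transform.
# This is exactly zero-phase, has unit pass-band gain, and avoids the edge
# transients of very long FIR kernels (a 0.5 Hz high-pass edge at 256 Hz
# needs impulse responses of several seconds). Transition bands are
# raised-cosine ramps.

# gain curve helper: 1 inside [lo, hi], raised-cosine ramps of width trans
.band_gain <- function(freqs, lo, hi, trans_lo, trans_hi) {
  g <- rep(1, length(freqs))
  if (!is.null(lo) && lo > 0) {
    g[freqs < lo - trans_lo] <- 0
    ramp <- freqs >= lo - trans_lo & freqs < lo
    g[ramp] <- 0.5 * (1 - cos(pi * (freqs[ramp] - (lo - trans_lo)) / trans_lo))
  }
  if (!is.null(hi)) {
    g[freqs > hi + trans_hi] <- 0
    ramp <- freqs > hi & freqs <= hi + trans_hi
    g[ramp] <- 0.5 * (1 + cos(pi * (freqs[ramp] - hi) / trans_hi))
  }
  g
}

#' Zero-phase band-pass / band-stop filtering
#'
#' Filters each column of a numeric matrix with a zero-phase
#' frequency-domain filter. Pass-band gain is exactly 1; transition bands
#' are raised-cosine ramps.
#'
#' @param x Numeric vector or samples x channels matrix.
#' @param srate Sampling rate in Hz.
#' @param low High-pass edge in Hz, or `NULL` for no high-pass.
#' @param high Low-pass edge in Hz, or `NULL` for no low-pass.
#' @param notch Numeric vector of notch (band-stop) centre frequencies in
#'   Hz, or `NULL`.
#' @param trans Transition band width in Hz. Defaults to
#'   `max(0.25 * low, 0.25)` for the high-pass edge and `max(0.25 * high, 1)`
#'   for the low-pass edge.
#' @param notch_width Half-width of each notch stop band in Hz.
#' @return Filtered data with the same shape as `x`.
#' @export
filter_fft <- function(x, srate, low = NULL, high = NULL, notch = NULL,
                       trans = NULL, notch_width = 1) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  freqs <- abs(seq(0, srate, length.out = n + 1L)[seq_len(n)])
  freqs <- pmin(freqs, srate - freqs)  # two-sided spectrum
  t_lo <- if (is.null(trans)) max(0.25 * (low %||% 1), 0.25) else trans
  t_hi <- if (is.null(trans)) max(0.25 * (high %||% 4), 1) else trans
  g <- .band_gain(freqs, low, high, t_lo, t_hi)
  if (!is.null(notch)) {
    for (f0 in notch) {
      stopband <- abs(freqs - f0) < notch_width
      ramp <- abs(freqs - f0) >= notch_width & abs(freqs - f0) < 2 * notch_width
      g[stopband] <- 0
      g[ramp] <- g[ramp] *
        0.5 * (1 - cos(pi * (abs(freqs[ramp] - f0) - notch_width) / notch_width))
    }
  }
  cm <- colMeans(x)
  xc <- sweep(x, 2L, cm)
  out <- Re(stats::mvfft(stats::mvfft(xc) * g, inverse = TRUE)) / n
  # restore DC only if it passes the filter
  if (is.null(low) || low <= 0) out <- sweep(out, 2L, cm, `+`)
  if (vec) out <- drop(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Band-limited Gaussian noise
#'
#' White Gaussian noise restricted to a frequency band, scaled to a target
#' standard deviation. Used for the simulated 10-20 Hz coupling sources.
#'
#' @param n Number of samples.
#' @param srate Sampling rate in Hz.
#' @param band Length-2 numeric, pass band in Hz.
#' @param sd Target standard deviation of the output (microvolts).
#' @return Numeric vector of length `n`.
#' @export
band_noise <- function(n, srate, band, sd = 1) {
  x <- filter_fft(stats::rnorm(n), srate, low = band[1L], high = band[2L])
  s <- stats::sd(x)
  if (s == 0) return(x)
  x * (sd / s)
}

#' 1/f ("pink") Gaussian noise
#'
#' Noise with power spectral density proportional to 1/f, generated by
#' shaping the spectrum of white noise, scaled to a target standard
#' deviation. Emulates the broadband background of EEG/iEEG recordings.
#'
#' @param n Number of samples.
#' @param sd Target standard deviation (microvolts).
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, sd = 1) {
  drop(pink_noise_mat(n, 1L, sd))
}

# matrix variant: n samples x nch independent pink-noise channels
pink_noise_mat <- function(n, nch, sd = 1) {
  # amplitude ~ f^(-1/2) => power ~ 1/f
  half <- floor(n / 2)
  k <- c(1, seq_len(half), if (n %% 2 == 0) (half - 1):1 else half:1)
  amp <- 1 / sqrt(pmax(k, 1))
  ph <- matrix(stats::runif(n * nch, 0, 2 * pi), n, nch)
  x <- Re(stats::mvfft(amp * exp(1i * ph), inverse = TRUE))
  x <- sweep(x, 2L, colMeans(x))
  sweep(x, 2L, sd / apply(x, 2L, stats::sd), `*`)
}

#' Anti-aliased integer-factor resampling
#'
#' Resamples a recording to a lower rate that divides the original rate:
#' an anti-alias low-pass at 90% of the new Nyquist frequency followed by
#' decimation. Non-integer ratios are not supported.
#'
#' @param rec An `eeg_recording`.
#' @param target_srate Target sampling rate in Hz.
#' @return The resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target_srate) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_srate == rec$srate) return(rec)
  fac <- rec$srate / target_srate
  if (abs(fac - round(fac)) > 1e-9 || fac < 1)
    stop("target rate must divide the original sampling rate", call. = FALSE)
  fac <- as.integer(round(fac))
  dat <- filter_fft(rec$data, rec$srate, high = 0.9 * target_srate / 2)
  dat <- dat[seq(1L, nrow(dat), by = fac), , drop = FALSE]
  new_recording(dat, target_srate, rec$labels, rec$kind)
}
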