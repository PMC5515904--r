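# Depth-electrode (iEEG) pipeline: filtering, channel QC, common-average
# reference, R-locked epoching, windowed-Fourier time-frequency charts with
# baseline z-normalisation, and band-wise condition contrasts.

#' Preprocess an intracranial recording with channel quality control
#'
#' Screens channels on the raw signal with two automatic criteria, applies
#' a zero-phase 1-200 Hz band-pass plus notch filters at 50 Hz and its
#' harmonics to the survivors, and common-average references them. The
#' criteria (an automatic proxy for visual artifact screening) reject a
#' channel when (1) amplitude: any `|value|` exceeds `qc_threshold` times
#' the channel's amplitude scale, or (2) gradient: any sample-to-sample
#' difference (centred on the gradient's mean) exceeds `qc_threshold`
#' times the gradient scale.
#'
#' By default both scales are the robust peak amplitude (the 99.9th
#' percentile of the rectified signal / gradient): a clean multi-minute
#' recording has a maximum around 1.4-1.7 times this scale while a gross
#' artifact spike exceeds 5 times it, so the conventional multiplier of 5
#' separates artifact from signal. Scales proportional to the SD (`"sd"`)
#' or mean absolute amplitude (`"meanabs"`) are available for criterion 1,
#' but note that on a long Gaussian-like record the 5x threshold then sits
#' inside the natural range of the signal maximum.
#'
#' @param rec An `eeg_recording` (srate at least 512 Hz).
#' @param band Band-pass edges in Hz (default 1-200).
#' @param notch Notch centre frequencies in Hz (default 50, 100, 150).
#' @param qc_threshold Multiplier for both criteria (default 5).
#' @param amp_scale `"quantile"` (robust peak amplitude, the default),
#'   `"sd"` or `"meanabs"` - the amplitude scale of criterion 1.
#' @return The preprocessed `eeg_recording` (rejected channels removed),
#'   with attribute `qc`: a data frame with one row per input channel
#'   (`label`, `retained`, `reason`).
#' @export
ieeg_preprocess <- function(rec, band = c(1, 200), notch = c(50, 100, 150),
                            qc_threshold = 5,
                            amp_scale = c("quantile", "sd", "meanabs")) {
  stopifnot(inherits(rec, "eeg_recording"))
  amp_scale <- match.arg(amp_scale)
  if (rec$srate < 512) stop("sampling rate must be at least 512 Hz",
                            call. = FALSE)
  nch <- ncol(rec$data)
  reason <- rep(NA_character_, nch)
  for (ch in seq_len(nch)) {
    x <- rec$data[, ch]
    scale <- switch(amp_scale,
                    quantile = stats::quantile(abs(x), 0.999),
                    sd = stats::sd(x),
                    meanabs = mean(abs(x)))
    grad <- diff(x)
    grad <- grad - mean(grad)
    if (max(abs(x)) > qc_threshold * scale) {
      reason[ch] <- "amplitude"
    } else if (max(abs(grad)) >
               qc_threshold * stats::quantile(abs(grad), 0.999)) {
      reason[ch] <- "gradient"
    }
  }
  retained <- is.na(reason)
  if (!any(retained))
    stop("insufficient data: all channels rejected by QC", call. = FALSE)
  qc <- data.frame(label = rec$labels, retained = retained,
                   reason = ifelse(retained, "", reason),
                   stringsAsFactors = FALSE)
  notch <- notch[notch < rec$srate / 2]
  dat <- filter_fft(rec$data[, retained, drop = FALSE], rec$srate,
                    low = band[1L], high = band[2L], notch = notch)
  dat <- dat - rowMeans(dat)  # common-average reference
  out <- new_recording(dat, rec$srate, rec$labels[retained], kind = "ieeg")
  attr(out, "qc") <- qc
  out
}

#' Segment an iEEG recording for time-frequency analysis
#'
#' Cuts R-locked epochs with a half-window pad on both sides of the
#' -200..500 ms chart range, so that every 250 ms analysis window whose
#' centre lies inside the chart fits entirely inside the epoch (see
#' [tf_chart()]). Epochs are baseline-corrected by subtracting the mean of
#' the -200..-50 ms window.
#'
#' @param rec A preprocessed `eeg_recording`.
#' @param r An `event_series` of R-peak times.
#' @param pad_s Extra time in seconds beyond -0.2..0.5 on each side
#'   (default 0.15, enough for a 250 ms window).
#' @param baseline_ms Baseline window in ms for the DC correction.
#' @param reject_uv Amplitude rejection bound (default `Inf`: channel-level
#'   QC has already run).
#' @param condition,subject Identifiers stored on the result.
#' @return An `epoch_set` spanning `-0.2 - pad_s` .. `0.5 + pad_s` seconds.
#' @export
ieeg_epochs <- function(rec, r, pad_s = 0.15, baseline_ms = c(-200, -50),
                        reject_uv = Inf, condition = NA_character_,
                        subject = NA_character_) {
  ep <- epoch_recording(rec, r, tmin = -0.2 - pad_s, tmax = 0.5 + pad_s,
                        reject_uv = reject_uv, condition = condition,
                        subject = subject)
  base <- ep$times_ms >= baseline_ms[1L] & ep$times_ms <= baseline_ms[2L]
  mu <- apply(ep$data[, , base, drop = FALSE], c(1L, 2L), mean)
  ep$data <- ep$data - as.numeric(mu)  # recycles over the sample dimension
  ep
}

# Hann-windowed Fourier power for one epoch matrix (channels x samples):
# returns freqs x centers power for a single channel vector
.stft_power <- function(x, srate, centers_idx, half, emat) {
  seg <- vapply(centers_idx, function(c0) x[(c0 - half):(c0 + half - 1L)],
                numeric(2L * half))
  p <- Mod(crossprod(seg, emat))^2  # centers x freqs
  t(p)                              # freqs x centers
}

#' Windowed-Fourier time-frequency chart with baseline z-normalisation
#'
#' Computes per-epoch short-time Fourier power (Hann window of
#' `window_ms`, hop `step_ms`; the 250 ms / 8 ms defaults imply 97%
#' window overlap), averages power over retained epochs, and z-normalises
#' each frequency row by the mean and SD of the baseline time points
#' (window centres within `baseline_ms`). Window centres define the time
#' axis; windows extending past the epoch are dropped, which is why
#' [ieeg_epochs()] pads the segments.
#'
#' @param epochs An `epoch_set` (from [ieeg_epochs()]).
#' @param channel Channel label or index to analyse (default 1).
#' @param window_ms STFT window length in ms (default 250).
#' @param step_ms Hop between window centres in ms (default 8).
#' @param freqs Analysis frequencies in Hz (default 4..108 in steps of
#'   4 Hz, the resolution implied by the 250 ms window).
#' @param chart_ms Time range of the chart in ms (default -200..500).
#' @param baseline_ms Baseline window in ms (default -200..-50).
#' @param keep_epochs Keep the per-epoch z-scored power array (needed by
#'   [band_contrast()]; default `FALSE`).
#' @return List of class `tf_chart`: `times_ms` (window centres), `freqs`,
#'   `z` (freqs x times z-scored power), `power` (freqs x times mean raw
#'   power), `contact`, `condition`, and optionally `z_epochs`
#'   (epochs x freqs x times).
#' @export
tf_chart <- function(epochs, channel = 1L, window_ms = 250, step_ms = 8,
                     freqs = seq(4, 108, by = 4), chart_ms = c(-200, 500),
                     baseline_ms = c(-200, -50), keep_epochs = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  srate <- epochs$srate
  if (srate < 2 * max(freqs))
    stop("sampling rate below twice the maximum analysis frequency",
         call. = FALSE)
  if (is.character(channel)) channel <- match(channel, epochs$labels)
  if (is.na(channel) || channel < 1L || channel > dim(epochs$data)[2L])
    stop("unknown channel", call. = FALSE)
  half <- round(window_ms / 1000 * srate / 2)
  centers_ms <- seq(chart_ms[1L], chart_ms[2L], by = step_ms)
  centers_idx <- vapply(centers_ms, function(tm)
    which.min(abs(epochs$times_ms - tm)), integer(1))
  # drop chart columns whose window would leave the epoch
  ok <- centers_idx - half >= 1L &
    centers_idx + half - 1L <= dim(epochs$data)[3L]
  if (!all(ok)) {
    centers_ms <- centers_ms[ok]
    centers_idx <- centers_idx[ok]
  }
  base_cols <- centers_ms >= baseline_ms[1L] & centers_ms <= baseline_ms[2L]
  if (sum(base_cols) < 2)
    stop("baseline window too short: pad the epochs (see ieeg_epochs)",
         call. = FALSE)
  # Hann-windowed complex exponentials, samples x freqs
  tt <- (seq_len(2L * half) - half - 0.5) / srate
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = 2L * half)))
  emat <- exp(-2i * pi * outer(tt, freqs)) * hann
  keep <- which(!epochs$rejected)
  if (!length(keep)) stop("no retained epochs", call. = FALSE)
  pow <- array(0, c(length(keep), length(freqs), length(centers_ms)))
  for (e_i in seq_along(keep))
    pow[e_i, , ] <- .stft_power(epochs$data[keep[e_i], channel, ], srate,
                                centers_idx, half, emat)
  mean_pow <- apply(pow, c(2L, 3L), mean)
  mu <- rowMeans(mean_pow[, base_cols, drop = FALSE])
  sd0 <- apply(mean_pow[, base_cols, drop = FALSE], 1L, stats::sd)
  z <- (mean_pow - mu) / pmax(sd0, .Machine$double.eps)
  out <- list(times_ms = centers_ms, freqs = freqs, z = z, power = mean_pow,
              contact = epochs$labels[channel], condition = epochs$condition,
              baseline_ms = baseline_ms, window_ms = window_ms,
              step_ms = step_ms)
  if (keep_epochs) {
    # per-epoch z-scores against each epoch's own baseline
    mu_e <- apply(pow[, , base_cols, drop = FALSE], c(1L, 2L), mean)
    sd_e <- apply(pow[, , base_cols, drop = FALSE], c(1L, 2L), stats::sd)
    out$z_epochs <- sweep(sweep(pow, c(1L, 2L), mu_e, `-`),
                          c(1L, 2L), pmax(sd_e, .Machine$double.eps), `/`)
  }
  structure(out, class = "tf_chart")
}

#' @export
print.tf_chart <- function(x, ...) {
  cat(sprintf(
    "<tf_chart> %s (%s): %d freqs (%g-%g Hz) x %d times (%g..%g ms)\n",
    x$contact, x$condition, length(x$freqs), min(x$freqs), max(x$freqs),
    length(x$times_ms), min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Band-wise permutation contrast between two epoch sets
#'
#' Averages per-epoch z-scored power over a frequency band, yielding one
#' time series per epoch, then compares the two conditions with an
#' epoch-level two-sample permutation test (condition labels shuffled
#' `n_perm` times) at every time point from `window_ms[1]` onwards,
#' followed by the consecutive-sample [run_filter()]. The t statistic is
#' signed so positive values mean `a > b`.
#'
#' @param a,b `tf_chart` objects computed with `keep_epochs = TRUE`, same
#'   contact, same time/frequency axes.
#' @param band Length-2 numeric band in Hz: `c(1, 35)` (low) or
#'   `c(35, 110)` (broadband).
#' @param alpha Per-point significance level (default 0.05).
#' @param n_perm Number of label permutations (default 5000).
#' @param window_ms Analysis window (default 100 ms onwards).
#' @param min_run Minimum significant run length (default 5).
#' @param seed Integer seed.
#' @return A `pointwise_test` (see [pointwise_perm_test()]).
#' @export
band_contrast <- function(a, b, band = c(35, 110), alpha = 0.05,
                          n_perm = 5000, window_ms = c(100, 500),
                          min_run = 5, seed = 1L) {
  stopifnot(inherits(a, "tf_chart"), inherits(b, "tf_chart"))
  if (is.null(a$z_epochs) || is.null(b$z_epochs))
    stop("band_contrast needs charts computed with keep_epochs = TRUE",
         call. = FALSE)
  if (!identical(a$freqs, b$freqs) || !identical(a$times_ms, b$times_ms))
    stop("charts have mismatching axes", call. = FALSE)
  rows <- a$freqs >= band[1L] & a$freqs <= band[2L]
  if (!any(rows)) stop("band outside chart frequencies", call. = FALSE)
  xa <- apply(a$z_epochs[, rows, , drop = FALSE], c(1L, 3L), mean)
  xb <- apply(b$z_epochs[, rows, , drop = FALSE], c(1L, 3L), mean)
  na <- nrow(xa); nb <- nrow(xb)
  pooled <- rbind(xa, xb)
  pooled2 <- pooled^2
  tot_s <- colSums(pooled)
  tot_q <- colSums(pooled2)
  t2 <- function(lab) {
    n1 <- sum(lab); n2 <- sum(!lab)
    s1 <- colSums(pooled[lab, , drop = FALSE])
    q1 <- colSums(pooled2[lab, , drop = FALSE])
    s2 <- tot_s - s1
    q2 <- tot_q - q1
    m1 <- s1 / n1; m2 <- s2 / n2
    v1 <- (q1 - n1 * m1^2) / (n1 - 1)
    v2 <- (q2 - n2 * m2^2) / (n2 - 1)
    (m1 - m2) / pmax(sqrt(v1 / n1 + v2 / n2), .Machine$double.eps)
  }
  lab_obs <- rep(c(TRUE, FALSE), c(na, nb))
  t_obs <- t2(lab_obs)
  set.seed(seed)
  exceed <- integer(ncol(pooled))
  for (p_i in seq_len(n_perm)) {
    lab <- sample(lab_obs)
    exceed <- exceed + (abs(t2(lab)) >= abs(t_obs))
  }
  p <- (exceed + 1) / (n_perm + 1)
  in_window <- a$times_ms >= window_ms[1L] & a$times_ms <= window_ms[2L]
  sig <- run_filter(p < alpha & in_window, min_run)
  structure(list(times_ms = a$times_ms, t = t_obs, p = p, sig = sig,
                 windows = .mask_windows(sig, a$times_ms),
                 n_perm = n_perm, alpha = alpha, window_ms = window_ms,
                 band = band),
            class = "pointwise_test")
}
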