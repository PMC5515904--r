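# Scalp preprocessing: reference, resample, band-pass, R-peak detection,
# cardiac-field-artifact removal, R-locked epoching and ROI averaging.

#' Preprocess a raw scalp recording
#'
#' Re-references (to the mean of mastoid channels when present, otherwise
#' the common average, with a message), resamples to `target_srate` with an
#' anti-alias low-pass, and applies a zero-phase band-pass.
#'
#' @param rec An `eeg_recording` (srate at least 256 Hz).
#' @param target_srate Target sampling rate in Hz (default 256).
#' @param band Length-2 numeric band-pass edges in Hz (default 0.5-30).
#' @param reference `"auto"` (mastoids `"M1"`/`"M2"` if present, else
#'   average), `"average"`, `"none"`, or a character vector of reference
#'   channel labels.
#' @return The preprocessed `eeg_recording`.
#' @export
preprocess_scalp <- function(rec, target_srate = 256, band = c(0.5, 30),
                             reference = "auto") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$srate < 256) stop("sampling rate must be at least 256 Hz",
                            call. = FALSE)
  rec <- rereference(rec, reference)
  rec <- resample_recording(rec, target_srate)
  rec$data <- filter_fft(rec$data, rec$srate, low = band[1L], high = band[2L])
  rec
}

#' Re-reference a recording
#' @inheritParams preprocess_scalp
#' @return The re-referenced `eeg_recording`.
#' @export
rereference <- function(rec, reference = "average") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (identical(reference, "none")) return(rec)
  if (identical(reference, "auto")) {
    mast <- intersect(c("M1", "M2"), rec$labels)
    if (length(mast)) {
      reference <- mast
    } else {
      message("no mastoid channels found; falling back to average reference")
      reference <- "average"
    }
  }
  if (identical(reference, "average")) {
    ref <- rowMeans(rec$data)
  } else {
    idx <- match(reference, rec$labels)
    if (anyNA(idx))
      stop("reference channel(s) not present in recording", call. = FALSE)
    ref <- rowMeans(rec$data[, idx, drop = FALSE])
  }
  rec$data <- rec$data - ref
  rec
}

#' Detect R peaks in an ECG channel
#'
#' Local-extremum detector with a robust magnitude threshold: candidate
#' peaks are local maxima exceeding `threshold` times the robust SD
#' (median absolute deviation) of the signal; a refractory period of
#' `min_rr` ms is enforced by keeping the larger of two conflicting peaks.
#' Polarity is auto-detected (the signal is flipped when the largest
#' excursions are negative), so inverted-lead recordings give identical
#' peak times.
#'
#' @param ecg Numeric vector, single-channel `eeg_recording`, or the output
#'   list of [gen_ecg()].
#' @param srate Sampling rate in Hz (ignored when `ecg` is a recording).
#' @param min_rr Refractory period in ms (default 300).
#' @param threshold Magnitude threshold in multiples of the robust SD
#'   (default 4).
#' @param polarity `"auto"`, `"positive"` or `"negative"`.
#' @return An `event_series` of R-peak times in seconds (empty, with a
#'   warning, if no peak exceeds the threshold).
#' @export
detect_r_peaks <- function(ecg, srate = NULL, min_rr = 300, threshold = 4,
                           polarity = c("auto", "positive", "negative")) {
  polarity <- match.arg(polarity)
  if (is.list(ecg) && inherits(ecg$recording, "eeg_recording"))
    ecg <- ecg$recording
  if (inherits(ecg, "eeg_recording")) {
    srate <- ecg$srate
    x <- ecg$data[, 1L]
  } else {
    x <- as.numeric(ecg)
    if (is.null(srate)) stop("`srate` required for a bare vector",
                             call. = FALSE)
  }
  if (length(x) < 2 * srate)
    stop("ECG must be at least 2 s long", call. = FALSE)
  x <- x - stats::median(x)
  if (polarity == "negative" ||
      (polarity == "auto" &&
       abs(stats::quantile(x, 0.0005)) > abs(stats::quantile(x, 0.9995)))) {
    x <- -x
  }
  rsd <- stats::mad(x)
  if (rsd == 0) rsd <- stats::sd(x)
  thr <- threshold * rsd
  n <- length(x)
  is_peak <- c(FALSE, x[2:(n - 1L)] > x[1:(n - 2L)] &
                 x[2:(n - 1L)] >= x[3:n], FALSE) & x > thr
  cand <- which(is_peak)
  if (!length(cand)) {
    warning("no R peaks found above threshold")
    return(event_series(numeric(0), "r-peak"))
  }
  min_gap <- min_rr / 1000 * srate
  keep <- integer(0)
  last <- -Inf
  for (s in cand) {
    if (s - last >= min_gap) {
      keep <- c(keep, s)
      last <- s
    } else if (x[s] > x[keep[length(keep)]]) {
      keep[length(keep)] <- s  # keep the larger peak on conflict
      last <- s
    }
  }
  event_series((keep - 1L) / srate, "r-peak")
}

#' Remove the cardiac-field artifact
#'
#' Two methods are available. `"template-regression"` (deterministic; the
#' default): for each channel, the R-locked median template restricted to
#' +/-`window_ms` around R is scaled by least squares to the channel's
#' R-locked average and subtracted at every R time. `"ica-auto"`:
#' a FastICA decomposition (tanh contrast, symmetric orthogonalisation,
#' deterministic initialisation) is scored per component by (a) the ratio
#' of R-locked peak amplitude within +/-50 ms of R to baseline SD and
#' (b) the absolute anterior-posterior contrast of its topography (the
#' dipolar artifact pattern, in either orientation); components exceeding
#' both thresholds are removed. If the decomposition fails numerically the
#' function falls back to template regression with a warning.
#'
#' @param rec An `eeg_recording`.
#' @param r An `event_series` of R-peak times (non-empty).
#' @param method `"template-regression"` or `"ica-auto"`.
#' @param window_ms Half-width of the artifact window around R in ms
#'   (default 100).
#' @param layout A `channel_layout` (needed for the topography score of
#'   `"ica-auto"`; defaults to the recording's `layout` attribute).
#' @param amp_ratio_min,topo_contrast_min Component-selection thresholds
#'   for `"ica-auto"`: minimum R-locked amplitude ratio (default 3) and
#'   minimum anterior-posterior topography contrast in SD units of the
#'   mixing column (default 0.5).
#' @param n_comp Number of ICA components (default `min(20, n_channels)`).
#' @return The cleaned `eeg_recording`.
#' @export
remove_cfa <- function(rec, r, method = c("template-regression", "ica-auto"),
                       window_ms = 100, layout = NULL,
                       amp_ratio_min = 3, topo_contrast_min = 0.5,
                       n_comp = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(r, "event_series"))
  method <- match.arg(method)
  if (!length(r$times)) stop("`r` must be non-empty", call. = FALSE)
  if (method == "ica-auto") {
    out <- try(.remove_cfa_ica(rec, r, window_ms, layout,
                               amp_ratio_min, topo_contrast_min, n_comp),
               silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
    warning("ICA decomposition failed; falling back to template regression")
  }
  .remove_cfa_template(rec, r, window_ms)
}

.remove_cfa_template <- function(rec, r, window_ms) {
  srate <- rec$srate
  half <- round(window_ms / 1000 * srate)
  rel <- -half:half
  r_samples <- round(r$times * srate) + 1L
  n <- nrow(rec$data)
  inside <- r_samples + min(rel) >= 1L & r_samples + max(rel) <= n
  r_in <- r_samples[inside]
  if (!length(r_in)) return(rec)
  idx <- outer(r_in, rel, `+`)  # epochs x window
  for (ch in seq_len(ncol(rec$data))) {
    seg <- matrix(rec$data[, ch][idx], nrow = length(r_in))
    tmpl <- apply(seg, 2L, stats::median)
    avg <- colMeans(seg)
    denom <- sum(tmpl^2)
    a <- if (denom > 0) sum(tmpl * avg) / denom else 0
    for (k in seq_along(r_in))
      rec$data[idx[k, ], ch] <- rec$data[idx[k, ], ch] - a * tmpl
  }
  rec
}

# compact symmetric FastICA (whitening + tanh contrast); deterministic
# (fixed non-random initialisation, no RNG use)
.fastica <- function(X, n_comp, max_iter = 500, tol = 1e-4) {
  Xc <- sweep(X, 2L, colMeans(X))
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  keep <- seq_len(n_comp)
  K <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(pmax(eg$values[keep], 1e-12)), n_comp)
  Z <- Xc %*% K  # whitened, samples x n_comp
  sym_orth <- function(W) {
    s <- La.svd(W)
    s$u %*% s$vt
  }
  W <- sym_orth(matrix(sin(seq_len(n_comp^2)), n_comp))
  n <- nrow(Z)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    G <- tanh(Z %*% t(W))
    gp <- colMeans(1 - G^2)
    W1 <- sym_orth(crossprod(G, Z) / n - diag(gp, n_comp) %*% W)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  # near-Gaussian components keep rotating among themselves and prevent a
  # tight global convergence; the strongly non-Gaussian (artifact)
  # directions stabilise within a few iterations, so the decomposition is
  # used as-is after max_iter
  if (anyNA(W)) stop("FastICA diverged")
  U <- W %*% t(K)  # unmixing: sources = Xc %*% t(U)
  list(S = Z %*% t(W), mixing = MASS::ginv(U), converged = delta < tol)
}

.remove_cfa_ica <- function(rec, r, window_ms, layout,
                            amp_ratio_min, topo_contrast_min, n_comp) {
  if (is.null(layout)) layout <- attr(rec, "layout")
  nch <- ncol(rec$data)
  if (is.null(n_comp)) n_comp <- min(20L, nch)
  dec <- .fastica(rec$data, n_comp)
  srate <- rec$srate
  r_samples <- round(r$times * srate) + 1L
  half50 <- round(0.05 * srate)
  base_rel <- -round(0.2 * srate):-half50  # baseline: -200..-50 ms
  peak_rel <- -half50:half50
  n <- nrow(rec$data)
  r_in <- r_samples[r_samples + min(base_rel) >= 1L &
                      r_samples + max(peak_rel) <= n]
  remove <- logical(n_comp)
  for (c_i in seq_len(n_comp)) {
    src <- dec$S[, c_i]
    pk <- rowMeans(matrix(abs(src[outer(r_in, peak_rel, `+`)]),
                          nrow = length(r_in)))
    erp <- colMeans(matrix(src[outer(r_in, peak_rel, `+`)],
                           nrow = length(r_in)))
    base <- matrix(src[outer(r_in, base_rel, `+`)], nrow = length(r_in))
    amp_ratio <- max(abs(erp)) / max(stats::sd(colMeans(base)), 1e-12)
    topo <- dec$mixing[, c_i]
    contrast <- Inf
    if (!is.null(layout)) {
      # dipolar anterior-posterior topography, either orientation (the
      # biphasic artifact time course makes source polarity arbitrary)
      ant <- layout$y > 0
      contrast <- abs(mean(topo[!ant]) - mean(topo[ant])) /
        max(stats::sd(topo), 1e-12)
    }
    remove[c_i] <- amp_ratio >= amp_ratio_min &&
      contrast >= topo_contrast_min
  }
  if (any(remove)) {
    contrib <- dec$S[, remove, drop = FALSE] %*%
      t(dec$mixing[, remove, drop = FALSE])
    rec$data <- rec$data - contrib
  }
  rec
}

#' Segment a recording into R-locked epochs
#'
#' Cuts windows of `tmin`..`tmax` seconds around each R peak using
#' nearest-sample rounding of the window edges (at 256 Hz and the default
#' window this yields 180 samples, -199.2..500 ms). Epochs overlapping the
#' record edges are dropped; epochs containing any sample with
#' `|value| > reject_uv` are marked rejected.
#'
#' @param rec A preprocessed `eeg_recording`.
#' @param r An `event_series` of R-peak times.
#' @param tmin,tmax Epoch window in seconds relative to R (defaults -0.2
#'   and 0.5).
#' @param reject_uv Amplitude rejection bound in microvolts (default 300);
#'   `Inf` disables rejection.
#' @param condition,subject Identifiers stored on the result.
#' @return An `epoch_set`. Errors if no epoch survives.
#' @export
epoch_recording <- function(rec, r, tmin = -0.2, tmax = 0.5,
                            reject_uv = 300, condition = NA_character_,
                            subject = NA_character_) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(r, "event_series"))
  srate <- rec$srate
  rel <- round(tmin * srate):round(tmax * srate)
  r_samples <- round(r$times * srate) + 1L
  n <- nrow(rec$data)
  inside <- r_samples + min(rel) >= 1L & r_samples + max(rel) <= n
  r_in <- r_samples[inside]
  if (!length(r_in))
    stop("insufficient data: no epoch fits inside the recording",
         call. = FALSE)
  nep <- length(r_in); nch <- ncol(rec$data); ns <- length(rel)
  dat <- array(0, c(nep, nch, ns))
  idx <- outer(r_in, rel, `+`)
  for (ch in seq_len(nch))
    dat[, ch, ] <- rec$data[, ch][idx]
  rejected <- apply(abs(dat) > reject_uv, 1L, any)
  if (all(rejected))
    stop("insufficient data: all epochs rejected", call. = FALSE)
  epoch_set(dat, rel / srate * 1000, srate, rec$labels, rejected,
            condition, subject)
}

#' Average epochs over a region of interest
#'
#' Means over the ROI channels and then over retained epochs, yielding one
#' waveform per subject and condition.
#'
#' @param epochs An `epoch_set`.
#' @param roi Character vector of channel labels, or one of `"right"`,
#'   `"central"`, `"left"` (the standard frontal ROIs, see [hep_rois()]).
#' @return Numeric vector of length `n_samples` (microvolts), with the
#'   epoch times in ms as the `times_ms` attribute.
#' @export
roi_average <- function(epochs, roi) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(roi) && length(roi) == 1L && roi %in% names(hep_rois()))
    roi <- hep_rois()[[roi]]
  idx <- match(as.character(roi), epochs$labels)
  if (anyNA(idx)) stop("unknown ROI channel label", call. = FALSE)
  keep <- !epochs$rejected
  sub <- epochs$data[keep, idx, , drop = FALSE]
  wave <- apply(sub, 3L, mean)
  attr(wave, "times_ms") <- epochs$times_ms
  wave
}
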