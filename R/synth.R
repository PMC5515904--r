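# Ground-truth synthetic generator.
#
# Emulates the structure of a heartbeat-detection experiment: a lead-II ECG
# with known R-peak times; 128-channel scalp EEG carrying 1/f background,
# posterior alpha, a dipolar cardiac-field artifact, an R-locked negative
# evoked component whose amplitude depends on condition, and band-limited
# 10-20 Hz coupling sources; per-condition keyboard taps; and 4 virtual
# depth contacts with post-R band-power modulations. Every stage returns
# its ground truth so downstream estimators can be tested for recovery.

.conditions <- c("exteroception", "basal", "post-feedback")

#' Simulation configuration
#'
#' Bundles every generator parameter with validated defaults. Defaults
#' encode the recording regime of the emulated experiment: 128 scalp
#' channels at 1024 Hz, 2-minute blocks, and a mean heart rate of 70 bpm.
#' Amplitudes are in microvolts.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param srate Sampling rate in Hz.
#' @param duration Block duration in seconds.
#' @param n_channels Number of scalp channels.
#' @param heart_rate_mean Mean heart rate in bpm.
#' @param rr_jitter_sd SD of the Gaussian R-R interval jitter in ms.
#' @param hep_amplitude Named numeric: evoked-component amplitude (uV,
#'   negative = scalp-negative) per condition. Interoceptive conditions are
#'   more negative than exteroception by default.
#' @param hep_window Length-2 numeric, ms post-R over which the evoked
#'   component extends (must lie within 0..500 ms).
#' @param cfa_amplitude Peak amplitude (uV) of the dipolar cardiac-field
#'   artifact.
#' @param noise_1f_scale SD (uV) of the per-channel 1/f background.
#' @param alpha_amplitude Amplitude (uV) of the posterior 10 Hz rhythm.
#' @param tap_jitter_sd Named numeric, SD (ms) of tap-time jitter per
#'   condition.
#' @param tap_miss_prob Named numeric, per-beat probability of a missed tap.
#' @param tap_extra_prob Named numeric, expected number of spurious taps per
#'   beat (Poisson rate).
#' @param coupling_gain SD (uV) of the injected 10-20 Hz coupling sources.
#' @param coupling_lag_ms Named numeric, lag (ms) between the two members of
#'   each coupled pair, per interoceptive condition.
#' @param coupling_spec `"auto"` (derive condition-specific coupled pairs
#'   from the layout: short right-frontal pairs for basal, long
#'   fronto-posterior pairs for post-feedback) or a list per condition of
#'   `list(a=, b=, lag_ms=, gain=)` entries.
#' @param ieeg_noise_scale SD (uV) of the depth-contact 1/f background.
#' @param ieeg_band_gain List per condition with elements `low` and `bb`:
#'   multiplicative band-power gain applied after each R peak (1 = no
#'   modulation). Defaults modulate 35-110 Hz for basal interoception and
#'   1-35 Hz for exteroception.
#' @param ieeg_windows List with elements `low` and `bb`: length-2 ms
#'   windows post-R (within 100..437 ms) in which the gains apply.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       srate = 1024,
                       duration = 120,
                       n_channels = 128,
                       heart_rate_mean = 70,
                       rr_jitter_sd = 30,
                       hep_amplitude = c("exteroception" = -0.8,
                                         "basal" = -3.0,
                                         "post-feedback" = -3.0),
                       hep_window = c(250, 400),
                       cfa_amplitude = 15,
                       noise_1f_scale = 10,
                       alpha_amplitude = 4,
                       tap_jitter_sd = c("exteroception" = 100,
                                         "basal" = 220,
                                         "post-feedback" = 180),
                       tap_miss_prob = c("exteroception" = 0.05,
                                         "basal" = 0.25,
                                         "post-feedback" = 0.15),
                       tap_extra_prob = c("exteroception" = 0.02,
                                          "basal" = 0.08,
                                          "post-feedback" = 0.06),
                       coupling_gain = 5,
                       coupling_lag_ms = c("basal" = 8, "post-feedback" = 20),
                       coupling_spec = "auto",
                       ieeg_noise_scale = 10,
                       ieeg_band_gain = list(
                         "exteroception" = c(low = 2, bb = 1),
                         "basal" = c(low = 1, bb = 2)),
                       ieeg_windows = list(low = c(150, 437),
                                           bb = c(100, 437))) {
  cfg <- list(seed = as.integer(seed), srate = srate, duration = duration,
              n_channels = as.integer(n_channels),
              heart_rate_mean = heart_rate_mean, rr_jitter_sd = rr_jitter_sd,
              hep_amplitude = hep_amplitude, hep_window = hep_window,
              cfa_amplitude = cfa_amplitude, noise_1f_scale = noise_1f_scale,
              alpha_amplitude = alpha_amplitude,
              tap_jitter_sd = tap_jitter_sd, tap_miss_prob = tap_miss_prob,
              tap_extra_prob = tap_extra_prob, coupling_gain = coupling_gain,
              coupling_lag_ms = coupling_lag_ms, coupling_spec = coupling_spec,
              ieeg_noise_scale = ieeg_noise_scale,
              ieeg_band_gain = ieeg_band_gain, ieeg_windows = ieeg_windows)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$srate > 0, cfg$duration > 0, cfg$n_channels >= 16,
            cfg$heart_rate_mean > 0, cfg$rr_jitter_sd >= 0)
  for (p in c("tap_miss_prob")) {
    if (any(cfg[[p]] < 0 | cfg[[p]] > 1))
      stop(sprintf("`%s` must lie in [0, 1]", p), call. = FALSE)
  }
  if (any(cfg$tap_extra_prob < 0))
    stop("`tap_extra_prob` must be non-negative", call. = FALSE)
  if (cfg$hep_window[1L] < 0 || cfg$hep_window[2L] > 500 ||
      diff(cfg$hep_window) <= 0)
    stop("`hep_window` must be an increasing interval within 0..500 ms",
         call. = FALSE)
  for (w in cfg$ieeg_windows) {
    if (w[1L] < 0 || w[2L] > 500 || diff(w) <= 0)
      stop("iEEG modulation windows must lie within the 0..500 ms epoch",
           call. = FALSE)
  }
  for (nm in .conditions) {
    if (is.na(cfg$hep_amplitude[nm]))
      stop("`hep_amplitude` must name all three conditions", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

.check_condition <- function(condition,
                             allowed = .conditions) {
  if (!condition %in% allowed)
    stop(sprintf("unknown condition '%s' (expected one of: %s)", condition,
                 paste(allowed, collapse = ", ")), call. = FALSE)
  condition
}

# QRS-like biphasic template on a +/-60 ms support: small Q dip, tall R
# peak (Gaussian, sigma 7 ms), S undershoot. Not a physiological ECG model;
# sufficient for peak-detection testing.
.qrs_template <- function(srate) {
  t <- seq(-0.06, 0.06, by = 1 / srate)
  g <- function(mu, sig) exp(-((t - mu)^2) / (2 * sig^2))
  amp <- -150 * g(-0.025, 0.006) + 800 * g(0, 0.007) - 200 * g(0.028, 0.007)
  list(amp = amp, center = which.max(amp))
}

#' Simulate a lead-II ECG with known R-peak times
#'
#' R-R intervals are `60000 / heart_rate_mean` ms plus Gaussian jitter,
#' with a 300 ms refractory floor. Each beat is rendered as a biphasic
#' QRS-like template whose R peak is at least five times the background
#' noise SD (noise SD 20 uV, R amplitude 800 uV).
#'
#' @param cfg A `sim_config`.
#' @return List with `recording` (single-channel `eeg_recording`, kind
#'   `"ecg"`) and `r` (an `event_series` of ground-truth R-peak times in
#'   seconds).
#' @export
gen_ecg <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$duration < 10) stop("duration must be at least 10 s", call. = FALSE)
  set.seed(cfg$seed)
  mean_rr <- 60 / cfg$heart_rate_mean
  t <- 0.5
  times <- numeric(0)
  while (t <= cfg$duration - 0.3) {
    times <- c(times, t)
    rr <- mean_rr + stats::rnorm(1L, 0, cfg$rr_jitter_sd / 1000)
    rr <- max(rr, 0.3)  # refractory floor
    t <- t + rr
  }
  n <- round(cfg$duration * cfg$srate)
  x <- stats::rnorm(n, 0, 20)
  tmpl <- .qrs_template(cfg$srate)
  r_samples <- round(times * cfg$srate) + 1L
  for (s in r_samples) {
    idx <- s - tmpl$center + seq_along(tmpl$amp)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + tmpl$amp[ok]
  }
  r_times <- (r_samples - 1L) / cfg$srate
  list(recording = new_recording(x, cfg$srate, "ECG", kind = "ecg"),
       r = event_series(r_times, "r-peak"))
}

# cosine-tapered (Tukey) envelope of unit amplitude over [w1, w2] ms:
# flat over the central 1 - taper fraction, cosine ramps at both ends, so
# the injected effect genuinely spans the declared ground-truth window
.tukey_window_ms <- function(times_ms, w, taper = 0.3) {
  out <- numeric(length(times_ms))
  inside <- times_ms >= w[1L] & times_ms <= w[2L]
  ph <- (times_ms[inside] - w[1L]) / (w[2L] - w[1L])  # 0..1
  half <- taper / 2
  env <- rep(1, length(ph))
  lo <- ph < half
  hi <- ph > 1 - half
  env[lo] <- 0.5 * (1 - cos(pi * ph[lo] / half))
  env[hi] <- 0.5 * (1 - cos(pi * (1 - ph[hi]) / half))
  out[inside] <- env
  out
}

#' Default condition-specific coupled channel pairs
#'
#' Derives the injected connectivity structure from a layout: for basal
#' interoception, short-range pairs inside/around the right-frontal seed
#' region (nearest non-seed neighbour within 2-7 cm); for post-feedback
#' interoception, long-range pairs from the seed to posterior electrodes at
#' 12-17 cm. Exteroception has no injected coupling.
#'
#' @param layout A `channel_layout`.
#' @param cfg A `sim_config` (for gains and lags).
#' @return Named list per condition of `list(a, b, lag_ms, gain)` entries.
#' @export
default_coupling <- function(layout, cfg) {
  dm <- distance_matrix(layout)
  seed_roi <- intersect(hep_rois()$seed, layout$label)
  pick <- function(from, lo, hi, prefer_posterior = FALSE) {
    used <- character(0)
    out <- list()
    for (a in from) {
      d <- dm[a, ]
      cand <- names(d)[d >= lo & d <= hi & !(names(d) %in% seed_roi) &
                         !(names(d) %in% used)]
      if (prefer_posterior) {
        post <- cand[layout$region[match(cand, layout$label)] == "posterior"]
        if (length(post)) cand <- post
      }
      if (!length(cand)) next
      b <- cand[which.min(d[cand])]
      used <- c(used, b)
      out[[length(out) + 1L]] <- list(a = a, b = b)
    }
    out
  }
  short <- pick(intersect(as.character(c(62, 64, 66, 68, 74)), seed_roi),
                2, 7)
  long <- pick(intersect(as.character(c(63, 65, 67, 75, 77)), seed_roi),
               12, 17, prefer_posterior = TRUE)
  lapply(stats::setNames(.conditions, .conditions), function(cond) {
    pairs <- switch(cond,
                    "basal" = short,
                    "post-feedback" = long,
                    list())
    lag <- unname(cfg$coupling_lag_ms[cond])
    lapply(pairs, function(p)
      list(a = p$a, b = p$b, lag_ms = if (is.na(lag)) 0 else lag,
           gain = cfg$coupling_gain))
  })
}

#' Simulate a scalp EEG block for one condition
#'
#' Each channel is 1/f background noise plus a posterior alpha rhythm; on
#' top of that the generator injects (i) a dipolar cardiac-field artifact
#' locked to each R peak (anterior-negative / posterior-positive,
#' derivative-of-Gaussian time course within +/-100 ms of R), (ii) a
#' frontal negative evoked component over `hep_window` ms post-R with
#' condition-dependent amplitude, and (iii) band-limited 10-20 Hz coupling
#' sources shared (with a lag) by the configured channel pairs. Independent
#' channel noise guarantees no two channels are sample-identical.
#'
#' @param cfg A `sim_config`.
#' @param r An `event_series` of R-peak times.
#' @param condition One of `"exteroception"`, `"basal"`, `"post-feedback"`.
#' @param layout Optional `channel_layout`; defaults to
#'   `make_layout(cfg$n_channels)`.
#' @return An `eeg_recording` with attributes `ground_truth` (list with
#'   `hep_effect_window`, `hep_amplitude`, `coupled_pairs`) and `layout`.
#' @export
gen_scalp <- function(cfg, r, condition, layout = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(r, "event_series"))
  .check_condition(condition)
  if (is.null(layout)) layout <- make_layout(cfg$n_channels)
  set.seed(cfg$seed + 1000L * match(condition, .conditions))
  n <- round(cfg$duration * cfg$srate)
  nch <- nrow(layout)
  radius <- attr(layout, "radius") %||% max(sqrt(rowSums(layout[, c("x", "y", "z")]^2)))

  dat <- pink_noise_mat(n, nch, cfg$noise_1f_scale)
  # posterior alpha
  tt <- (seq_len(n) - 1L) / cfg$srate
  w_alpha <- pmax(0, -layout$y) / radius
  for (ch in which(w_alpha > 0))
    dat[, ch] <- dat[, ch] + cfg$alpha_amplitude * w_alpha[ch] *
      sin(2 * pi * 10 * tt + stats::runif(1L, 0, 2 * pi))

  r_samples <- round(r$times * cfg$srate) + 1L

  # cardiac-field artifact: derivative-of-Gaussian, +/-100 ms around R,
  # dipolar topography (anterior negative, posterior positive)
  if (cfg$cfa_amplitude != 0) {
    ts <- seq(-0.1, 0.1, by = 1 / cfg$srate)
    shape <- -ts * exp(-ts^2 / (2 * 0.02^2))
    shape <- shape / max(abs(shape))
    w_cfa <- -layout$y / radius
    cfa_add <- .add_locked(n, r_samples, shape,
                           center = which.min(abs(ts)))
    dat <- dat + cfa_add %*% t(cfg$cfa_amplitude * w_cfa)
  }

  # evoked component: frontal negativity over hep_window ms post-R
  amp <- unname(cfg$hep_amplitude[condition])
  if (amp != 0) {
    ts_ms <- seq(0, 500, by = 1000 / cfg$srate)
    shape <- .tukey_window_ms(ts_ms, cfg$hep_window)
    w_hep <- pmax(0, layout$y) / radius
    hep_add <- .add_locked(n, r_samples, shape, center = 1L)
    dat <- dat + hep_add %*% t(amp * w_hep)
  }

  # coupling sources, band-limited to 10-20 Hz
  spec <- cfg$coupling_spec
  if (identical(spec, "auto")) spec <- default_coupling(layout, cfg)
  pairs <- spec[[condition]] %||% list()
  for (p in pairs) {
    src <- band_noise(n, cfg$srate, c(10, 20), sd = p$gain)
    lag <- round(p$lag_ms / 1000 * cfg$srate)
    ia <- match(p$a, layout$label); ib <- match(p$b, layout$label)
    if (anyNA(c(ia, ib))) stop("coupling pair references unknown channel",
                               call. = FALSE)
    dat[, ia] <- dat[, ia] + src
    if (lag >= 0) {
      dat[(1L + lag):n, ib] <- dat[(1L + lag):n, ib] + src[1:(n - lag)]
    } else {
      dat[1:(n + lag), ib] <- dat[1:(n + lag), ib] + src[(1L - lag):n]
    }
  }

  rec <- new_recording(dat, cfg$srate, layout$label, kind = "scalp")
  attr(rec, "ground_truth") <- list(
    hep_effect_window = cfg$hep_window,
    hep_amplitude = amp,
    coupled_pairs = lapply(pairs, function(p) c(p$a, p$b)))
  attr(rec, "layout") <- layout
  rec
}

# sparse "add template at each event" helper: returns an n x 1 column of
# the template train (events clipped at record edges)
.add_locked <- function(n, event_samples, shape, center) {
  out <- numeric(n)
  for (s in event_samples) {
    idx <- s - center + seq_along(shape)
    ok <- idx >= 1L & idx <= n
    out[idx[ok]] <- out[idx[ok]] + shape[ok]
  }
  matrix(out, ncol = 1L)
}

#' Simulate keyboard taps for one condition
#'
#' Each heartbeat elicits a tap with probability `1 - tap_miss_prob`,
#' jittered by Gaussian noise with SD `tap_jitter_sd` ms; spurious extra
#' taps are added as a Poisson process with `tap_extra_prob` expected events
#' per beat, uniform over the record span. Output is sorted.
#'
#' @param r An `event_series` of R-peak (or auditory-beat) times.
#' @param cfg A `sim_config`.
#' @param condition Condition label (selects the per-condition parameters).
#' @return An `event_series` of tap times.
#' @export
gen_taps <- function(r, cfg, condition) {
  stopifnot(inherits(r, "event_series"), inherits(cfg, "sim_config"))
  .check_condition(condition)
  if (!length(r$times)) stop("`r` must be non-empty", call. = FALSE)
  set.seed(cfg$seed + 77L + match(condition, .conditions))
  miss <- unname(cfg$tap_miss_prob[condition])
  jit <- unname(cfg$tap_jitter_sd[condition]) / 1000
  extra <- unname(cfg$tap_extra_prob[condition])
  keep <- stats::runif(length(r$times)) >= miss
  taps <- r$times[keep] + stats::rnorm(sum(keep), 0, jit)
  n_extra <- stats::rpois(1L, extra * length(r$times))
  if (n_extra > 0)
    taps <- c(taps, stats::runif(n_extra, min(r$times), max(r$times)))
  event_series(sort(taps), "tap")
}

#' Simulate depth-electrode (iEEG) contacts for one condition
#'
#' Four virtual contacts (posterior insula, amygdala, somatosensory cortex,
#' inferior frontal gyrus), each 1/f noise whose band-limited components are
#' multiplicatively amplified after each R peak: the 35-110 Hz (broadband)
#' component by `ieeg_band_gain[[condition]]["bb"]` inside the `bb` window
#' and the 1-35 Hz component by `...["low"]` inside the `low` window
#' (Hann-shaped gain envelopes).
#'
#' @param cfg A `sim_config`.
#' @param r An `event_series` of R-peak times.
#' @param condition `"exteroception"` or `"basal"`.
#' @return An `eeg_recording` (kind `"ieeg"`) with attribute `ground_truth`
#'   listing the per-band modulation windows and gains.
#' @export
gen_ieeg <- function(cfg, r, condition) {
  stopifnot(inherits(cfg, "sim_config"), inherits(r, "event_series"))
  .check_condition(condition, allowed = c("exteroception", "basal"))
  set.seed(cfg$seed + 500L + match(condition, .conditions))
  n <- round(cfg$duration * cfg$srate)
  contacts <- c("posterior-insula", "amygdala", "somatosensory", "IFG")
  gains <- cfg$ieeg_band_gain[[condition]]
  r_samples <- round(r$times * cfg$srate) + 1L

  env_for <- function(band) {
    w <- cfg$ieeg_windows[[band]]
    g <- gains[[band]]
    if (g == 1) return(rep(1, n))
    ts_ms <- seq(0, 500, by = 1000 / cfg$srate)
    shape <- .tukey_window_ms(ts_ms, w)
    1 + (g - 1) * .add_locked(n, r_samples, shape, center = 1L)[, 1L]
  }
  env_low <- env_for("low")
  env_bb <- env_for("bb")

  dat <- matrix(0, n, length(contacts))
  for (ch in seq_along(contacts)) {
    x <- pink_noise(n, cfg$ieeg_noise_scale)
    x_low <- filter_fft(x, cfg$srate, low = 1, high = 35)
    x_bb <- filter_fft(x, cfg$srate, low = 35, high = 110)
    x_rest <- x - x_low - x_bb
    dat[, ch] <- x_low * env_low + x_bb * env_bb + x_rest
  }
  rec <- new_recording(dat, cfg$srate, contacts, kind = "ieeg")
  attr(rec, "ground_truth") <- list(
    windows = cfg$ieeg_windows, gains = gains, condition = condition)
  rec
}

#' Simulate a behavioural accuracy cohort from summary statistics
#'
#' Draws `n_subjects` accuracy triplets (exteroception, basal,
#' post-feedback) from a trivariate normal with the given per-condition
#' means and SDs and a common pairwise correlation. Values are not
#' truncated to \code{[0, 1]}: the generator prioritises fidelity to the summary
#' statistics it is calibrated to over range constraints.
#'
#' Default `rho` is solved so the expected within-subject ANOVA error mean
#' square equals 0.025: `rho = 1 - 0.025 / mean(sds^2)`.
#'
#' @param n_subjects Number of subjects (at least 2).
#' @param means,sds Length-3 numeric, per-condition means and SDs in task
#'   order (exteroception, basal, post-feedback).
#' @param rho Common pairwise correlation, `|rho| < 1` and the implied
#'   covariance must be positive definite.
#' @param seed Integer seed.
#' @return Data frame with columns `subject` (factor), `condition` (factor
#'   with the three levels) and `accuracy`.
#' @export
gen_cohort <- function(n_subjects = 48,
                       means = c(0.73, 0.47, 0.58),
                       sds = c(0.20, 0.15, 0.19),
                       rho = 1 - 0.025 / mean(c(0.20, 0.15, 0.19)^2),
                       seed = 1L) {
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  stopifnot(length(means) == 3L, length(sds) == 3L, all(sds >= 0))
  Sig <- diag(sds^2)
  for (i in 1:3) for (j in 1:3) if (i != j) Sig[i, j] <- rho * sds[i] * sds[j]
  if (any(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
    stop("implied covariance is not positive definite", call. = FALSE)
  set.seed(seed)
  X <- MASS::mvrnorm(n_subjects, means, Sig)
  data.frame(
    subject = factor(rep(seq_len(n_subjects), times = 3L)),
    condition = factor(rep(.conditions, each = n_subjects),
                       levels = .conditions),
    accuracy = as.numeric(X))
}
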