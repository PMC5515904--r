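# Scalp preprocessing: filters, resampling, R-peak detection, artifact
# removal, epoching and ROI averaging.

test_that("band-pass filter has exact pass band and deep stop band", {
  srate <- 256
  tt <- (0:(srate * 100 - 1)) / srate
  x50 <- sin(2 * pi * 50 * tt)
  expect_lt(stats::sd(filter_fft(x50, srate, 0.5, 30)) / stats::sd(x50), 0.01)
  x10 <- sin(2 * pi * 10 * tt)
  expect_lt(abs(stats::sd(filter_fft(x10, srate, 0.5, 30)) /
                  stats::sd(x10) - 1), 0.05)
  # white noise in -> spectrum confined to the pass band
  set.seed(1)
  y <- filter_fft(rnorm(srate * 60), srate, 0.5, 30)
  spec <- Mod(stats::fft(y))^2
  freqs <- seq(0, srate, length.out = length(y) + 1)[seq_along(y)]
  freqs <- pmin(freqs, srate - freqs)
  out_band <- freqs < 0.2 | freqs > 40
  expect_lt(sum(spec[out_band]) / sum(spec), 0.01)
})

test_that("resampling decimates by integer factors only", {
  rec <- new_recording(matrix(rnorm(10240), ncol = 2), 1024)
  out <- resample_recording(rec, 256)
  expect_equal(out$srate, 256)
  expect_equal(nrow(out$data), 5120 / 4)
  expect_error(resample_recording(rec, 300), "divide")
})

test_that("preprocessing is idempotent on already-clean input", {
  rec <- fx_ecg()
  cfg <- sim_config(seed = 19, srate = 1024, duration = 30, n_channels = 16)
  e <- gen_ecg(cfg)
  lay <- make_layout(16)
  raw <- gen_scalp(cfg, e$r, "basal", lay)
  once <- preprocess_scalp(raw, reference = "average")
  twice <- preprocess_scalp(once, reference = "average")
  rms1 <- sqrt(mean(once$data^2))
  rms2 <- sqrt(mean(twice$data^2))
  expect_lt(abs(rms2 - rms1) / rms1, 0.01)
})

test_that("R-peak detector recovers ground truth, either polarity", {
  e <- fx_ecg()
  det <- detect_r_peaks(e$recording)
  hits <- vapply(e$r$times, function(t) min(abs(t - det$times)), numeric(1))
  expect_gte(mean(hits < 0.02), 0.99)                    # sensitivity
  errs <- vapply(det$times, function(t) min(abs(t - e$r$times)), numeric(1))
  expect_lt(stats::median(errs) * 1000, 5)               # median |error| ms

  flipped <- e$recording
  flipped$data <- -flipped$data
  expect_identical(detect_r_peaks(flipped)$times, det$times)

  flat <- new_recording(rep(0, 3 * 1024), 1024, "ECG", "ecg")
  expect_warning(empty <- detect_r_peaks(flat), "no R peaks")
  expect_length(empty$times, 0)
})

test_that("cardiac-artifact removal attenuates the artifact, spares the signal", {
  lay <- fx_layout()
  # artifact only (no evoked component): >= 80% amplitude reduction
  cfg <- sim_config(seed = 23, srate = 256, duration = 90,
                    hep_amplitude = c("exteroception" = 0, "basal" = 0,
                                      "post-feedback" = 0),
                    coupling_gain = 0)
  e <- gen_ecg(cfg)
  raw <- gen_scalp(cfg, e$r, "basal", lay)
  locked_amp <- function(rec) {
    ep <- epoch_recording(rec, e$r, reject_uv = Inf)
    max(abs(apply(ep$data, c(2, 3), mean)))
  }
  before <- locked_amp(raw)
  after <- locked_amp(remove_cfa(raw, e$r, method = "template-regression"))
  expect_lt(after, 0.2 * before)

  # no artifact: output is essentially the input
  cfg0 <- sim_config(seed = 24, srate = 256, duration = 60,
                     cfa_amplitude = 0, coupling_gain = 0)
  raw0 <- gen_scalp(cfg0, e$r, "basal", lay)
  cln0 <- remove_cfa(raw0, e$r, method = "template-regression")
  cors <- vapply(seq_len(ncol(raw0$data)), function(ch)
    stats::cor(raw0$data[, ch], cln0$data[, ch]), numeric(1))
  expect_gt(min(cors), 0.99)

  # artifact + evoked component: the 200-500 ms effect survives within 20%
  cfgh <- sim_config(seed = 25, srate = 256, duration = 120,
                     noise_1f_scale = 3, coupling_gain = 0)
  eh <- gen_ecg(cfgh)
  roi_wave <- function(rec) {
    ep <- epoch_recording(rec, eh$r, reject_uv = Inf)
    roi_average(ep, "right")
  }
  raw_b <- gen_scalp(cfgh, eh$r, "basal", lay)
  w_before <- roi_wave(raw_b)
  w_after <- roi_wave(remove_cfa(raw_b, eh$r, method = "template-regression"))
  tm <- attr(w_before, "times_ms")
  win <- tm >= 250 & tm <= 400
  expect_lt(abs(mean(w_after[win]) - mean(w_before[win])),
            0.2 * abs(mean(w_before[win])))
})

test_that("ICA-based artifact removal also attenuates the R-locked artifact", {
  cfg <- sim_config(seed = 26, srate = 256, duration = 90, n_channels = 32,
                    hep_amplitude = c("exteroception" = 0, "basal" = 0,
                                      "post-feedback" = 0),
                    coupling_gain = 0)
  e <- gen_ecg(cfg)
  lay <- make_layout(32)
  raw <- gen_scalp(cfg, e$r, "basal", lay)
  locked_amp <- function(rec) {
    ep <- epoch_recording(rec, e$r, reject_uv = Inf)
    max(abs(apply(ep$data, c(2, 3), mean)))
  }
  cln <- remove_cfa(raw, e$r, method = "ica-auto", layout = lay,
                    n_comp = 12)
  expect_lt(locked_amp(cln), 0.5 * locked_amp(raw))
})

test_that("epoching uses nearest-sample window edges and amplitude rejection", {
  cfg <- sim_config(seed = 27, srate = 256, duration = 60, n_channels = 16,
                    coupling_gain = 0)
  e <- gen_ecg(cfg)
  rec <- gen_scalp(cfg, e$r, "basal", make_layout(16))
  ep <- epoch_recording(rec, e$r)
  expect_equal(dim(ep$data)[3], 180)   # round(-51.2)..round(128) at 256 Hz
  expect_equal(ep$times_ms[1], -51 / 256 * 1000)
  expect_equal(ep$times_ms[180], 500)
  # all beats fully inside the record and clean -> all retained
  inside <- e$r$times > 0.21 & e$r$times < 60 - 0.51
  expect_equal(dim(ep$data)[1], sum(inside))
  expect_equal(sum(ep$rejected), 0)

  # a 500 uV artifact sample causes rejection of exactly that epoch
  rec2 <- rec
  s_bad <- round(e$r$times[10] * 256) + 1 + 20
  rec2$data[s_bad, 3] <- 500
  ep2 <- epoch_recording(rec2, e$r)
  expect_equal(sum(ep2$rejected), 1)
  expect_true(ep2$rejected[10 - sum(!inside[1:10])])

  expect_error(epoch_recording(rec, event_series(1000, "r-peak")),
               "insufficient")
})

test_that("ROI averaging is a linear mean over channels then epochs", {
  cfg <- sim_config(seed = 28, srate = 256, duration = 30, n_channels = 16,
                    coupling_gain = 0)
  e <- gen_ecg(cfg)
  rec <- gen_scalp(cfg, e$r, "basal", make_layout(16))
  ep <- epoch_recording(rec, e$r, reject_uv = Inf)
  one <- roi_average(ep, "5")
  expect_equal(as.numeric(one),
               as.numeric(apply(ep$data[, 5, ], 2, mean)))
  expect_equal(roi_average(ep, c("5", "5")), one)
  # linearity: average of summed data = sum of averages
  ep2 <- ep
  ep2$data <- 2 * ep$data
  expect_equal(roi_average(ep2, c("3", "7")),
               2 * roi_average(ep, c("3", "7")))
  expect_error(roi_average(ep, "999"), "unknown ROI")
})
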