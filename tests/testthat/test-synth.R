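# Synthetic generator: layout geometry, ECG/R-peak ground truth, scalp
# effect injection, taps, iEEG modulation, cohort calibration.

test_that("layout places all electrodes on a sphere with pinned ROIs", {
  lay <- fx_layout()
  expect_equal(nrow(lay), 128)
  expect_equal(anyDuplicated(lay$label), 0)
  rad <- sqrt(lay$x^2 + lay$y^2 + lay$z^2)
  expect_true(all(abs(rad - 9) < 1e-9))
  dm <- distance_matrix(lay)
  expect_lte(max(dm), 24)  # sphere diameter bound (18 cm at radius 9)

  rois <- hep_rois()
  expect_true(all(unlist(rois) %in% lay$label))
  # the standard ROIs sit in their named regions
  expect_true(all(lay$region[lay$label %in% rois$seed] == "anterior-right"))
  expect_true(all(lay$region[lay$label %in% rois$central] == "anterior-central"))
  expect_true(all(lay$region[lay$label %in% rois$left] == "anterior-left"))

  seedc <- colMeans(lay[lay$label %in% rois$seed, c("x", "y", "z")])
  d_to_seed <- sqrt((lay$x - seedc[1])^2 + (lay$y - seedc[2])^2 +
                      (lay$z - seedc[3])^2)
  # posterior electrodes are genuinely far from the right-frontal seed
  expect_gte(min(d_to_seed[lay$region == "posterior"]), 10)
  # and the scalp extends well beyond the seed neighbourhood
  expect_gte(max(d_to_seed), 15)

  expect_error(make_layout(8), "at least 16")
})

test_that("two antipodal electrodes on a 9 cm sphere are 18 cm apart", {
  lay <- data.frame(label = c("a", "b"), x = c(0, 0), y = c(9, -9),
                    z = c(0, 0), region = "other")
  class(lay) <- c("channel_layout", "data.frame")
  expect_equal(electrode_distance(lay, "a", "b"), 18)
})

test_that("ECG beat count and refractory floor match the configuration", {
  cfg <- sim_config(seed = 5, duration = 120, heart_rate_mean = 60,
                    rr_jitter_sd = 0)
  e <- gen_ecg(cfg)
  expect_length(e$r$times, 120)  # one beat per second, 120 s
  expect_true(is.unsorted(e$r$times) == FALSE)

  counts <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, duration = 120, heart_rate_mean = 70,
                      rr_jitter_sd = 30)
    length(gen_ecg(cfg)$r$times)
  }, numeric(1))
  expect_lte(abs(mean(counts) - 140), 3)
  # refractory: no RR interval below 300 ms on any seed
  min_rr <- vapply(c(1, 7, 13), function(s) {
    cfg <- sim_config(seed = s, duration = 60, heart_rate_mean = 70,
                      rr_jitter_sd = 200)
    min(diff(gen_ecg(cfg)$r$times))
  }, numeric(1))
  expect_true(all(min_rr > 0.3))
})

test_that("generator is deterministic and conserves event counts", {
  cfg <- sim_config(seed = 11, srate = 256, duration = 30)
  e1 <- gen_ecg(cfg)
  e2 <- gen_ecg(cfg)
  expect_identical(e1$recording$data, e2$recording$data)
  expect_identical(e1$r$times, e2$r$times)
  s1 <- gen_scalp(cfg, e1$r, "basal")
  s2 <- gen_scalp(cfg, e1$r, "basal")
  expect_identical(s1$data, s2$data)
  i1 <- gen_ieeg(cfg, e1$r, "basal")
  i2 <- gen_ieeg(cfg, e1$r, "basal")
  expect_identical(i1$data, i2$data)
})

test_that("scalp generator with all effects off has a flat R-locked average", {
  cfg <- sim_config(seed = 6, srate = 256, duration = 120,
                    cfa_amplitude = 0, alpha_amplitude = 0,
                    hep_amplitude = c("exteroception" = 0, "basal" = 0,
                                      "post-feedback" = 0),
                    coupling_gain = 0)
  e <- gen_ecg(cfg)
  rec <- gen_scalp(cfg, e$r, "basal")
  ep <- epoch_recording(rec, e$r, reject_uv = Inf)
  # channel-mean R-locked average: |mean| < 3 SEM at every time point
  chan_mean <- apply(ep$data, c(1, 3), mean)       # epochs x samples
  mu <- colMeans(chan_mean)
  sem <- apply(chan_mean, 2, stats::sd) / sqrt(nrow(chan_mean))
  expect_true(all(abs(mu) < 3.5 * sem + 1e-12))
})

test_that("injected evoked contrast at the frontal ROI matches configuration", {
  # low-noise configuration so the algebra of the injection is testable
  lay <- fx_layout()
  cfg <- sim_config(seed = 8, srate = 256, duration = 180,
                    noise_1f_scale = 3, coupling_gain = 0)
  e <- gen_ecg(cfg)
  waves <- list()
  for (cond in c("exteroception", "basal")) {
    rec <- gen_scalp(cfg, e$r, cond, lay)
    ep <- epoch_recording(rec, e$r, reject_uv = Inf)
    waves[[cond]] <- roi_average(ep, "right")
  }
  tm <- attr(waves$basal, "times_ms")
  plateau <- tm >= 280 & tm <= 370  # flat part of the tapered envelope
  observed <- mean(waves$basal[plateau] - waves$exteroception[plateau])
  rois <- hep_rois()
  w <- mean(pmax(0, lay$y[lay$label %in% rois$right]) / 9)
  injected <- (cfg$hep_amplitude["basal"] -
                 cfg$hep_amplitude["exteroception"]) * w
  expect_lt(abs(observed - injected), 0.25 * abs(injected))
})

test_that("coupled channel pairs share band-limited structure", {
  lay <- fx_layout()
  cfg <- sim_config(seed = 14, srate = 256, duration = 60)
  e <- gen_ecg(cfg)
  rec <- gen_scalp(cfg, e$r, "basal", lay)
  gt <- attr(rec, "ground_truth")$coupled_pairs
  expect_gt(length(gt), 0)
  band_cor <- function(a, b) {
    fa <- filter_fft(rec$data[, match(a, rec$labels)], 256, 10, 20)
    fb <- filter_fft(rec$data[, match(b, rec$labels)], 256, 10, 20)
    abs(stats::cor(fa, fb))
  }
  coupled <- band_cor(gt[[1]][1], gt[[1]][2])
  uncoupled <- band_cor("20", "110")
  expect_gt(coupled, uncoupled + 0.1)
  # no two channels are sample-identical or sign-opposed
  frac_same <- mean(rec$data[, match(gt[[1]][1], rec$labels)] ==
                      rec$data[, match(gt[[1]][2], rec$labels)])
  expect_lt(frac_same, 0.01)
})

test_that("tap generator honours jitter, miss and extra-tap settings", {
  e <- fx_ecg()
  cfg0 <- sim_config(seed = 2, duration = 60,
                     tap_jitter_sd = c("exteroception" = 0, "basal" = 0,
                                       "post-feedback" = 0),
                     tap_miss_prob = c("exteroception" = 0, "basal" = 0,
                                       "post-feedback" = 0),
                     tap_extra_prob = c("exteroception" = 0, "basal" = 0,
                                        "post-feedback" = 0))
  taps <- gen_taps(e$r, cfg0, "basal")
  expect_equal(taps$times, e$r$times)

  cfg1 <- sim_config(seed = 2, duration = 60,
                     tap_miss_prob = c("exteroception" = 1, "basal" = 1,
                                       "post-feedback" = 1),
                     tap_extra_prob = c("exteroception" = 0, "basal" = 0,
                                        "post-feedback" = 0))
  expect_length(gen_taps(e$r, cfg1, "basal")$times, 0)

  # accuracy decreases monotonically in tap jitter (averaged over seeds)
  grid <- c(0, 100, 200, 300)
  accs <- vapply(grid, function(j) {
    mean(vapply(1:5, function(s) {
      cfg <- sim_config(seed = s, duration = 120,
                        tap_jitter_sd = c("exteroception" = j, "basal" = j,
                                          "post-feedback" = j),
                        tap_miss_prob = c("exteroception" = 0, "basal" = 0,
                                          "post-feedback" = 0),
                        tap_extra_prob = c("exteroception" = 0, "basal" = 0,
                                           "post-feedback" = 0))
      ec <- gen_ecg(cfg)
      accuracy_index(ec$r, gen_taps(ec$r, cfg, "basal"))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(accs) < 0))
  expect_true(all(accs > 0 & accs <= 1))
})

test_that("iEEG generator validates windows and condition labels", {
  cfg <- fx_ecg()$cfg
  expect_error(sim_config(ieeg_windows = list(low = c(150, 600),
                                              bb = c(100, 437))),
               "0..500")
  expect_error(gen_ieeg(cfg, fx_ecg()$r, "post-feedback"), "unknown condition")
  expect_error(gen_scalp(cfg, fx_ecg()$r, "resting"), "unknown condition")
})

test_that("cohort generator reproduces requested moments", {
  # degenerate draw: zero variance returns the means exactly
  tab <- gen_cohort(5, sds = c(0, 0, 0), rho = 0, seed = 1)
  expect_equal(as.numeric(tapply(tab$accuracy, tab$condition, mean)),
               c(0.73, 0.47, 0.58))
  expect_equal(as.numeric(tapply(tab$accuracy, tab$condition, stats::sd)),
               c(0, 0, 0))

  # large-n convergence of the sample covariance to the request
  big <- gen_cohort(1e5, seed = 3)
  X <- cohort_wide(big)
  sds <- c(0.20, 0.15, 0.19)
  rho <- 1 - 0.025 / mean(sds^2)
  target <- diag(sds^2)
  for (i in 1:3) for (j in 1:3) if (i != j) target[i, j] <- rho * sds[i] * sds[j]
  expect_lt(max(abs(stats::cov(X) - target)), 0.002)

  expect_error(gen_cohort(1), "at least 2")
  expect_error(gen_cohort(10, rho = 1.2), "rho")
  expect_error(gen_cohort(10, rho = -0.9), "positive definite")
})
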