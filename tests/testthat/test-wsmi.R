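# Symbolic connectivity: CSD transform, ordinal symbolization, weighted
# symbolic mutual information, seed maps, contrasts and distance profiles.

test_that("CSD transform subtracts nearest-neighbour means", {
  lay <- data.frame(label = as.character(1:5),
                    x = c(0, 1, -1, 0, 0), y = c(0, 0, 0, 1, -1),
                    z = 0, region = "other")
  class(lay) <- c("channel_layout", "data.frame")
  dat <- matrix(0, 50, 5)
  dat[, 1] <- sin(seq_len(50))
  rec <- new_recording(dat, 256, as.character(1:5))
  out <- csd_transform(rec, lay, n_neighbors = 4)
  expect_equal(out$data[, 1], dat[, 1])          # active channel unchanged
  for (ch in 2:5)
    expect_equal(out$data[, ch], -dat[, 1] / 4)  # neighbours get -1/4

  # identical signal everywhere -> all-zero output
  same <- new_recording(matrix(rep(sin(seq_len(50)), 5), 50, 5), 256,
                        as.character(1:5))
  expect_true(all(abs(csd_transform(same, lay)$data) < 1e-12))

  # linearity
  r1 <- new_recording(matrix(rnorm(250), 50, 5), 256, as.character(1:5))
  r2 <- new_recording(matrix(rnorm(250), 50, 5), 256, as.character(1:5))
  r12 <- new_recording(r1$data + r2$data, 256, as.character(1:5))
  expect_equal(csd_transform(r12, lay)$data,
               csd_transform(r1, lay)$data + csd_transform(r2, lay)$data)

  expect_error(csd_transform(new_recording(dat[, 1:3], 256,
                                           as.character(1:3)), lay, 4),
               "more channels")
})

test_that("symbolization maps rank patterns as documented", {
  s <- symbolize(seq_len(50), srate = 250, tau_ms = 4)  # tau = 1 sample
  expect_true(all(s == 0))                              # ascending pattern
  expect_equal(attr(s, "tau_samples"), 1L)
  expect_equal(attr(symbolize(rnorm(100), 256, tau_ms = 16),
                    "tau_samples"), 4L)                 # 16 ms at 256 Hz

  set.seed(2)
  x <- rnorm(500)
  expect_identical(as.integer(symbolize(-x, 256)),
                   opposed_symbol(symbolize(x, 256)))
  expect_setequal(unique(symbolize(rnorm(5000), 256)), 0:5)

  # invariance under strictly increasing transforms
  y <- runif(400)
  expect_identical(as.integer(symbolize(y, 256)),
                   as.integer(symbolize(exp(3 * y) - 1, 256)))

  expect_error(symbolize(rnorm(5), 256, tau_ms = 16), "too short")
  expect_error(symbolize(rnorm(100), 256, k = 4), "k = 3")
})

test_that("wSMI is zero for identical and opposed streams, symmetric otherwise", {
  set.seed(3)
  x <- rnorm(4000)
  sx <- symbolize(x, 256)
  sn <- symbolize(-x, 256)
  expect_identical(wsmi_pair(sx, sx), 0)
  expect_identical(wsmi_pair(sx, sn), 0)
  y <- symbolize(rnorm(4000), 256)
  expect_equal(wsmi_pair(sx, y), wsmi_pair(y, sx))
  expect_error(wsmi_pair(sx, y[1:100]), "equal length")
})

test_that("wSMI matches the exhaustive-count oracle on short streams", {
  set.seed(4)
  for (rep_i in 1:25) {
    n <- sample(5:20, 1)
    a <- sample(0:5, n, replace = TRUE)
    b <- sample(0:5, n, replace = TRUE)
    expect_equal(wsmi_pair(a, b, clamp = FALSE),
                 wsmi_oracle(a, b, clamp = FALSE), tolerance = 1e-12)
    expect_equal(wsmi_pair(a, b), wsmi_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("wSMI of independent streams is near zero, coupled streams stand out", {
  set.seed(5)
  null_vals <- vapply(1:100, function(i) {
    a <- symbolize(rnorm(10008), 256)
    b <- symbolize(rnorm(10008), 256)
    wsmi_pair(a, b, clamp = FALSE)
  }, numeric(1))
  expect_lt(max(abs(null_vals)), 0.01)

  # lagged noisy copy (lag 2 tau, SNR 10): far above the independent null
  x <- pink_noise(20000, 1)
  lag <- 8  # 2 * tau at 256 Hz
  y <- c(rep(0, lag), x[1:(20000 - lag)]) + 0.1 * rnorm(20000)
  v <- wsmi_pair(symbolize(x, 256), symbolize(y, 256))
  expect_gt(v, stats::quantile(abs(null_vals), 0.99))

  # weighted value does not exceed the unweighted plug-in MI for
  # positively coupled streams
  sa <- symbolize(x, 256); sb <- symbolize(y, 256)
  joint <- matrix(tabulate(as.integer(sa) * 6L + as.integer(sb) + 1L,
                           36), 6, 6, byrow = TRUE) / length(sa)
  pa <- rowSums(joint); pb <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz])) / log(6)
  expect_lte(v, mi)
  expect_lt(mi, 1)  # normalised scale
})

test_that("seed map enumerates ROI-by-target pairs and is label-stable", {
  cfg <- sim_config(seed = 31, srate = 256, duration = 30)
  e <- gen_ecg(cfg)
  lay <- fx_layout()
  rec <- gen_scalp(cfg, e$r, "basal", lay)
  m <- wsmi_seed_map(rec, lay)
  expect_equal(nrow(m), 13 * 115)
  expect_true(all(m$value >= 0))
  expect_true(all(m$distance_cm > 0))

  # permuting channel order leaves per-pair values unchanged
  perm <- sample(ncol(rec$data))
  rec2 <- new_recording(rec$data[, perm], rec$srate, rec$labels[perm])
  m2 <- wsmi_seed_map(rec2, lay)
  key <- function(d) paste(d$seed, d$target)
  m2 <- m2[match(key(m), key(m2)), ]
  expect_equal(m$value, m2$value)
})

test_that("condition contrast is calibrated under the null and flags a == b", {
  pairs <- data.frame(seed = "67", target = as.character(1:50),
                      distance_cm = runif(50, 1, 18))
  mk <- function(vals) {
    d <- cbind(pairs, value = vals)
    class(d) <- c("wsmi_matrix", "data.frame")
    d
  }
  subj <- lapply(1:10, function(i) mk(runif(50)))
  same <- wsmi_compare(subj, subj)
  expect_false(any(same$sig_0.05))

  set.seed(6)
  rej <- mean(replicate(200, {
    a <- lapply(1:10, function(i) mk(rnorm(50)))
    b <- lapply(1:10, function(i) mk(rnorm(50)))
    mean(wsmi_compare(a, b)$sig_0.05)
  }))
  expect_lt(abs(rej - 0.05), 0.01)
  expect_error(wsmi_compare(subj[1:2], subj[1:2]), "at least 3")
})

test_that("electrode distance follows the Euclidean formula", {
  lay <- data.frame(label = c("a", "b", "c"),
                    x = c(0, 3, 1), y = c(0, 4, 1), z = c(0, 0, 1),
                    region = "other")
  class(lay) <- c("channel_layout", "data.frame")
  expect_equal(electrode_distance(lay, "a", "b"), 5)  # 3-4-5 triangle
  expect_equal(electrode_distance(lay, "a", "a"), 0)
  expect_equal(electrode_distance(lay, "a", "c"),
               electrode_distance(lay, "c", "a"))
  expect_error(electrode_distance(lay, "a", "zz"), "unknown")
})

test_that("distance profile bins by distance and flags nothing under the null", {
  pairs <- data.frame(seed = "67", target = as.character(1:60),
                      distance_cm = runif(60, 1, 18))
  mk <- function(vals) {
    d <- cbind(pairs, value = vals)
    class(d) <- c("wsmi_matrix", "data.frame")
    d
  }
  subj <- lapply(1:8, function(i) mk(runif(60)))
  prof <- wsmi_distance_profile(subj, subj, n_perm = 500, seed = 1)
  expect_false(any(prof$sig))
  expect_true(all(diff(prof$distance_cm) > 0))
  expect_equal(sum(prof$n_pairs), 60)
})
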