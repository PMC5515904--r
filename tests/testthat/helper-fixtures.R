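# Shared fixtures, built once per test run and cached. Expensive cohort
# fixtures are used both by module tests and by the acceptance suite.
#
# Fixture scales are deliberately smaller than a full study (fewer subjects,
# and 256/512 Hz generation where the analysis itself runs at 256 Hz) so the
# whole suite stays fast; the methods vignette documents the sizes.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# one small ECG + ground truth, 1024 Hz
fx_ecg <- function() fixture("ecg", function() {
  cfg <- sim_config(seed = 42, srate = 1024, duration = 60)
  c(gen_ecg(cfg), list(cfg = cfg))
})

# the standard 128-channel layout
fx_layout <- function() fixture("layout", function() make_layout(128))

# per-subject ROI waveforms for exteroception vs basal, full preprocessing
# chain (10 subjects, 512 Hz acquisition, 2-minute blocks)
fx_hep_waves <- function() fixture("hep_waves", function() {
  simulate_hep_cohort(n_subjects = 10, seed = 300, srate = 512,
                      duration = 120)
})

# 12-subject wSMI fixture: basal vs post-feedback seed maps on
# CSD-transformed 256 Hz data
fx_wsmi_cohort <- function() fixture("wsmi_cohort", function() {
  lay <- fx_layout()
  basal <- list()
  pf <- list()
  for (s in 1:12) {
    cfg <- sim_config(seed = 100 + s, srate = 256, duration = 120)
    e <- gen_ecg(cfg)
    for (cond in c("basal", "post-feedback")) {
      raw <- gen_scalp(cfg, e$r, cond, lay)
      rec <- csd_transform(preprocess_scalp(raw, reference = "average"), lay)
      m <- wsmi_seed_map(rec, lay, subject = as.character(s),
                         condition = cond)
      if (cond == "basal") basal[[s]] <- m else pf[[s]] <- m
    }
  }
  list(basal = basal, pf = pf, layout = lay)
})

# one simulated patient: preprocessed + epoched iEEG and per-contact
# time-frequency charts for both conditions (512 Hz, 90 s)
fx_ieeg <- function() fixture("ieeg", function() {
  cfg <- sim_config(seed = 77, srate = 512, duration = 90)
  e <- gen_ecg(cfg)
  det <- detect_r_peaks(e)
  out <- list(cfg = cfg, r = e$r)
  for (cond in c("basal", "exteroception")) {
    raw <- gen_ieeg(cfg, e$r, cond)
    rec <- ieeg_preprocess(raw)
    ep <- ieeg_epochs(rec, det, condition = cond)
    out[[cond]] <- list(raw = raw, rec = rec, epochs = ep,
                        chart = tf_chart(ep, channel = "posterior-insula",
                                         keep_epochs = TRUE))
  }
  out
})

# brute-force within-subject ANOVA oracle: explicit sums of squares
anova_oracle <- function(X) {
  # X: subjects x conditions
  n <- nrow(X); k <- ncol(X)
  g <- mean(X)
  ss_cond <- n * sum((colMeans(X) - g)^2)
  ss_err <- sum((X - outer(rowMeans(X), rep(1, k)) -
                   outer(rep(1, n), colMeans(X)) + g)^2)
  ms_cond <- ss_cond / (k - 1)
  ms_err <- ss_err / ((k - 1) * (n - 1))
  list(F = ms_cond / ms_err, ms_error = ms_err,
       df = c(k - 1, (k - 1) * (n - 1)))
}

# exhaustive-count wSMI reference: explicit double loop over the 6 x 6
# joint alphabet, independent of the tabulate-based implementation
wsmi_oracle <- function(a, b, clamp = TRUE) {
  n <- length(a)
  val <- 0
  for (sa in 0:5) {
    for (sb in 0:5) {
      if (sb == sa || sb == (5L - sa)) next  # identical / opposed weights
      pab <- sum(a == sa & b == sb) / n
      if (pab == 0) next
      pa <- sum(a == sa) / n
      pb <- sum(b == sb) / n
      val <- val + pab * log(pab / (pa * pb))
    }
  }
  val <- val / log(6)
  if (clamp) max(0, val) else val
}

# matrix-to-wide helper for cohort tables
cohort_wide <- function(tab) {
  m <- stats::reshape(tab, idvar = "subject", timevar = "condition",
                      direction = "wide")
  as.matrix(m[, -1L])
}
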