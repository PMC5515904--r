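# Configuration and end-to-end orchestration.
#
# A pipeline configuration is a flat named list that serialises to YAML and
# round-trips through file. Unknown keys are rejected so that typos fail
# before any stage runs. All stage randomness flows from the single
# top-level seed.

.default_config <- function() {
  list(
    seed = 1L,
    # simulation (the canonical recording regime)
    srate = 1024, duration = 120, n_channels = 128, heart_rate_mean = 70,
    n_subjects = 48,
    # behavioural cohort calibration
    cohort_means = c(0.73, 0.47, 0.58),
    cohort_sds = c(0.20, 0.15, 0.19),
    cohort_rho = 1 - 0.025 / mean(c(0.20, 0.15, 0.19)^2),
    # scalp ERP analysis
    resample_to = 256, bandpass = c(0.5, 30), reject_uv = 300,
    erp_roi = "right", erp_window_ms = c(100, 500),
    n_perm = 5000, alpha = 0.05, min_run = 5,
    # connectivity
    wsmi_k = 3, wsmi_tau_ms = 16, csd_neighbors = 4,
    contrast_alphas = c(0.05, 0.01),
    profile_bin_cm = 1, profile_alpha = 0.001,
    # iEEG
    ieeg_band_low = c(1, 35), ieeg_band_bb = c(35, 110),
    tf_window_ms = 250, tf_step_ms = 8,
    # orchestration
    n_eeg_subjects = 0,  # 0 disables the recording-level stages
    stages = c("simulate", "behav", "hep", "wsmi", "ieeg"),
    log_level = "info")
}

#' Pipeline configuration
#'
#' Builds a validated configuration from the defaults plus overrides.
#' Defaults encode the canonical analysis parameters: 1024 Hz acquisition,
#' 256 Hz resampling, 0.5-30 Hz band-pass, +/-300 uV rejection, k = 3 /
#' tau = 16 ms symbolization, 5000 permutations, the standard ROIs, the
#' 1-35 / 35-110 Hz bands and the 250 ms / 8 ms windowed Fourier transform.
#' Unknown keys are rejected.
#'
#' @param ... Named overrides of default entries.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- .default_config()
  dots <- list(...)
  if (length(dots) && is.null(names(dots)))
    stop("configuration overrides must be named", call. = FALSE)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_config()` returns a validated `pipeline_config`;
#'   round-trips through file.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Hash of a configuration
#'
#' MD5 digest of the canonical YAML serialisation; stamped into every
#' report so reproducibility is checkable by hash comparison.
#'
#' @param config A `pipeline_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the configured stages in order: `simulate` (behavioural cohort
#' and, when `n_eeg_subjects > 0`, per-subject recordings), `behav`
#' (repeated-measures ANOVA and Tukey post hoc on the cohort), `hep`
#' (preprocess, R-locked epochs, ROI average, point-wise permutation
#' contrast of basal interoception vs exteroception), `wsmi`
#' (CSD + seed-to-scalp wSMI, basal vs post-feedback contrast and distance
#' profile) and `ieeg` (QC, time-frequency charts, band contrasts for one
#' simulated patient). A stage failure marks the stage failed in the
#' report and skips dependent stages. All randomness derives from
#' `config$seed`.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory; when given, a JSON report and
#'   per-stage TSV outputs are written there.
#' @return List of class `pipeline_report` with per-stage results, the
#'   configuration, its hash, and package version.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config = unclass(config), config_hash = config_hash(config),
                 version = as.character(utils::packageVersion("interopipe")),
                 stages = list())
  ok <- function(stage) stage %in% config$stages
  failed <- character(0)

  run_stage <- function(name, deps, fun) {
    if (!ok(name)) return(NULL)
    if (length(intersect(deps, failed))) {
      report$stages[[name]] <<- list(status = "skipped",
                                     reason = paste("failed dependency:",
                                                    paste(deps, collapse = ",")))
      return(NULL)
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- c(failed, name)
      report$stages[[name]] <<- list(status = "failed",
                                     reason = conditionMessage(res))
      NULL
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), res$summary)
      res$value
    }
  }

  sim <- run_stage("simulate", character(0), function() {
    cohort <- gen_cohort(config$n_subjects, config$cohort_means,
                         config$cohort_sds, config$cohort_rho,
                         seed = config$seed)
    list(value = list(cohort = cohort),
         summary = list(n_subjects = config$n_subjects))
  })

  run_stage("behav", "simulate", function() {
    fit <- rm_anova(sim$cohort)
    tk <- tukey_hsd(fit)
    list(value = NULL,
         summary = list(F = fit$F, df = fit$df, p = fit$p,
                        ms_error = fit$ms_error,
                        tukey = stats::setNames(tk$p, rownames(tk))))
  })

  eeg <- NULL
  if (config$n_eeg_subjects > 0) {
    eeg <- run_stage("hep", "simulate", function() {
      waves <- simulate_hep_cohort(
        n_subjects = config$n_eeg_subjects, seed = config$seed,
        srate = config$srate, duration = config$duration,
        conditions = c("exteroception", "basal"))
      test <- pointwise_perm_test(
        waves$basal, waves$exteroception, waves$times_ms,
        n_perm = config$n_perm, alpha = config$alpha,
        window_ms = config$erp_window_ms, min_run = config$min_run,
        seed = config$seed)
      list(value = list(test = test),
           summary = list(n_subjects = config$n_eeg_subjects,
                          n_sig_points = sum(test$sig),
                          windows = test$windows))
    })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report["stages"],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(c(sprintf("interopipe pipeline report (config %s)",
                         report$config_hash),
                 vapply(names(report$stages), function(nm)
                   sprintf("  %s: %s", nm, report$stages[[nm]]$status),
                   character(1))),
               file.path(out_dir, "report.txt"))
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> config %s (interopipe %s)\n",
              substr(x$config_hash, 1, 8), x$version))
  for (nm in names(x$stages))
    cat(sprintf("  %-10s %s\n", nm, x$stages[[nm]]$status))
  invisible(x)
}

#' Simulate and preprocess an ERP cohort
#'
#' Convenience wrapper used by [run_pipeline()] and the worked examples:
#' for each subject, simulates ECG plus scalp EEG per condition, runs the
#' standard preprocessing chain (reference, resample, band-pass, R-peak
#' detection, cardiac-artifact removal, epoching), and returns per-subject
#' ROI-averaged waveforms.
#'
#' @param n_subjects Number of simulated subjects.
#' @param seed Integer seed; subject `i` uses `seed + i`.
#' @param conditions Conditions to simulate.
#' @param roi ROI passed to [roi_average()] (default `"right"`).
#' @param srate,duration Generator overrides.
#' @param ... Further [sim_config()] overrides.
#' @return List with one subjects x times matrix per condition plus
#'   `times_ms` and `ground_truth` (the injected effect window).
#' @export
simulate_hep_cohort <- function(n_subjects = 10, seed = 1L,
                                conditions = c("exteroception", "basal"),
                                roi = "right", srate = 1024,
                                duration = 120, ...) {
  waves <- NULL
  gt <- NULL
  for (s_i in seq_len(n_subjects)) {
    cfg <- sim_config(seed = seed + s_i, srate = srate,
                      duration = duration, ...)
    ecg <- gen_ecg(cfg)
    layout <- make_layout(cfg$n_channels)
    for (cond in conditions) {
      raw <- gen_scalp(cfg, ecg$r, cond, layout)
      if (is.null(gt)) gt <- attr(raw, "ground_truth")$hep_effect_window
      rec <- preprocess_scalp(raw, reference = "average")
      r_det <- detect_r_peaks(ecg$recording)
      rec <- remove_cfa(rec, r_det, method = "template-regression")
      ep <- epoch_recording(rec, r_det, condition = cond,
                            subject = as.character(s_i))
      w <- roi_average(ep, roi)
      if (is.null(waves)) {
        waves <- stats::setNames(
          rep(list(matrix(NA_real_, n_subjects, length(w))), length(conditions)),
          conditions)
        waves$times_ms <- attr(w, "times_ms")
      }
      waves[[cond]][s_i, ] <- w
    }
  }
  waves$ground_truth <- gt
  waves
}
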