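# Point-wise Monte-Carlo permutation comparison of per-subject waveforms,
# with a consecutive-sample run filter.

#' Run filter for significance masks
#'
#' Sets to `FALSE` every run of consecutive `TRUE` values shorter than
#' `min_run`; longer runs are untouched. Used to discard isolated
#' significant time points that are not sustained in time.
#'
#' @param mask Logical vector.
#' @param min_run Minimum run length to keep (default 5).
#' @return Logical vector of the same length.
#' @export
run_filter <- function(mask, min_run = 5) {
  mask <- as.logical(mask)
  if (!length(mask)) return(mask)
  r <- rle(mask)
  r$values[r$values & r$lengths < min_run] <- FALSE
  inverse.rle(r)
}

# contiguous TRUE runs -> data frame of (start_ms, end_ms)
.mask_windows <- function(mask, times) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_ms = times[starts[keep]], end_ms = times[ends[keep]])
}

#' Point-wise paired permutation test between two waveform sets
#'
#' Compares two paired sets of per-subject waveforms (e.g. ROI-averaged
#' event-locked potentials for two conditions) with a paired t statistic at
#' every time point. The null distribution is built by Monte-Carlo
#' resampling of the within-subject difference waveforms: on each of
#' `n_perm` draws, subjects are resampled with replacement (the
#' bootstrapping element) and each resampled difference is given a random
#' sign, and the per-point t values of the draw are recorded. Two-tailed
#' p-values use the add-one estimator `(b + 1) / (n_perm + 1)`. Points with
#' `p < alpha` inside the analysis window are then passed through
#' [run_filter()] so that only effects sustained for at least `min_run`
#' consecutive samples are reported.
#'
#' @param a,b Numeric matrices, subjects x time points, same dimensions and
#'   subject order (paired design). Row names, when present, must agree.
#' @param times_ms Time axis in ms, length `ncol(a)`. Defaults to the
#'   `times_ms` attribute of `a` or `b`.
#' @param n_perm Number of Monte-Carlo draws (default 5000).
#' @param alpha Per-point significance level (default 0.05).
#' @param window_ms Analysis window in ms (default 100-500); the mask is
#'   forced to `FALSE` outside it.
#' @param min_run Minimum significant run length in samples (default 5).
#' @param seed Integer seed for the Monte-Carlo draws.
#' @param null `"signflip-bootstrap"` (default) or `"signflip"` (pure
#'   sign-flip permutation, no subject resampling).
#' @return List of class `pointwise_test`: `times_ms`, `t`, `p`, `sig`
#'   (post run-filter logical mask), `windows` (data frame of significant
#'   runs in ms), `n_perm`, `alpha`, `window_ms`.
#' @export
pointwise_perm_test <- function(a, b, times_ms = NULL, n_perm = 5000,
                                alpha = 0.05, window_ms = c(100, 500),
                                min_run = 5, seed = 1L,
                                null = c("signflip-bootstrap", "signflip")) {
  null <- match.arg(null)
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("`a` and `b` must have identical dimensions (paired design)",
         call. = FALSE)
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("`a` and `b` must contain the same subjects in the same order",
         call. = FALSE)
  n <- nrow(a)
  if (n < 5) stop("need at least 5 subjects", call. = FALSE)
  if (is.null(times_ms))
    times_ms <- attr(a, "times_ms") %||% attr(b, "times_ms") %||%
      seq_len(ncol(a))
  d <- a - b
  tstat <- function(m) {
    mu <- colMeans(m)
    se <- sqrt((colSums(m^2) - nrow(m) * mu^2) / (nrow(m) - 1) / nrow(m))
    mu / pmax(se, .Machine$double.eps)
  }
  t_obs <- tstat(d)
  set.seed(seed)
  exceed <- integer(ncol(d))
  for (p_i in seq_len(n_perm)) {
    idx <- if (null == "signflip-bootstrap")
      sample.int(n, n, replace = TRUE) else seq_len(n)
    s <- sample(c(-1, 1), n, replace = TRUE)
    t_null <- tstat(s * d[idx, , drop = FALSE])
    exceed <- exceed + (abs(t_null) >= abs(t_obs))
  }
  p <- (exceed + 1) / (n_perm + 1)
  in_window <- times_ms >= window_ms[1L] & times_ms <= window_ms[2L]
  sig <- p < alpha & in_window
  sig <- run_filter(sig, min_run)
  structure(list(times_ms = times_ms, t = t_obs, p = p, sig = sig,
                 windows = .mask_windows(sig, times_ms),
                 n_perm = n_perm, alpha = alpha, window_ms = window_ms),
            class = "pointwise_test")
}

#' @export
print.pointwise_test <- function(x, ...) {
  cat(sprintf("<pointwise_test> %d points, %d permutations, alpha = %g\n",
              length(x$t), x$n_perm, x$alpha))
  if (nrow(x$windows)) {
    cat("significant windows (ms):\n")
    print(x$windows, row.names = FALSE)
  } else cat("no significant windows\n")
  invisible(x)
}
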