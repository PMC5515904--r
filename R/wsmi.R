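# Weighted symbolic mutual information (wSMI) connectivity.
#
# Signals are converted to ordinal-pattern symbols (the rank ordering of
# k = 3 samples spaced tau apart; 3! = 6 patterns) and pairwise information
# sharing is the plug-in mutual information over the 6 x 6 joint symbol
# distribution, with binary weights that zero out identical symbol pairs
# (a possible common source) and sign-opposed pairs (the two sides of one
# dipole). Values are normalised by ln(k!) so the scale is unitless.

#' Current-source-density (neighbour-subtraction) transform
#'
#' Spatially sharpens a multichannel recording by subtracting, from each
#' channel, the mean of its `n_neighbors` nearest channels (Euclidean
#' distance on the electrode layout). The transform is linear.
#'
#' @param rec An `eeg_recording`.
#' @param layout A `channel_layout` covering all channels of `rec`.
#' @param n_neighbors Number of nearest neighbours to subtract (default 4).
#' @return The transformed `eeg_recording`.
#' @export
csd_transform <- function(rec, layout, n_neighbors = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  idx <- match(rec$labels, layout$label)
  if (anyNA(idx)) stop("layout does not cover all channels", call. = FALSE)
  nch <- ncol(rec$data)
  if (nch < n_neighbors + 1L)
    stop("need more channels than `n_neighbors`", call. = FALSE)
  pos <- as.matrix(layout[idx, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(pos))
  out <- rec$data
  for (ch in seq_len(nch)) {
    nb <- order(dm[ch, ])[2:(n_neighbors + 1L)]  # skip self
    out[, ch] <- rec$data[, ch] -
      rowMeans(rec$data[, nb, drop = FALSE])
  }
  rec$data <- out
  rec
}

#' Ordinal-pattern symbolization
#'
#' Transforms a signal into discrete symbols defined by the rank ordering
#' of `k = 3` samples separated by `tau_ms` (`tau` is rounded to the
#' nearest whole number of samples; 16 ms at 256 Hz gives 4 samples,
#' i.e. 15.625 ms, emphasising roughly 10-20 Hz structure). Ties are broken
#' by temporal order (the earlier sample ranks lower). Codes 0..5 index the
#' six rank patterns in lexicographic order; symbols are invariant under
#' any strictly increasing pointwise transform of the signal.
#'
#' @param x Numeric signal.
#' @param srate Sampling rate in Hz.
#' @param k Pattern length; only `k = 3` is supported.
#' @param tau_ms Temporal separation between pattern samples in ms
#'   (default 16).
#' @return Integer vector of symbol codes (0..5) of length
#'   `length(x) - (k - 1) * tau_samples`, with attributes `k` and
#'   `tau_samples`.
#' @export
symbolize <- function(x, srate, k = 3, tau_ms = 16) {
  if (k != 3) stop("only k = 3 is supported (6 symbols)", call. = FALSE)
  tau <- max(1L, as.integer(round(tau_ms / 1000 * srate)))
  n <- length(x) - 2L * tau
  if (n < 1L) stop("signal too short for the requested tau", call. = FALSE)
  x0 <- x[seq_len(n)]
  x1 <- x[seq_len(n) + tau]
  x2 <- x[seq_len(n) + 2L * tau]
  # ranks with ties broken by temporal order (earlier sample ranks lower)
  r1 <- 1L + (x1 < x0) + (x2 < x0)
  r2 <- 1L + (x0 <= x1) + (x2 < x1)
  r3 <- 1L + (x0 <= x2) + (x1 <= x2)
  # lexicographic code over the 6 rank patterns: (1,2,3)=0 ... (3,2,1)=5
  code <- (r1 - 1L) * 2L + (r2 > r3)
  structure(as.integer(code), k = 3L, tau_samples = tau)
}

#' Sign-opposed symbol
#'
#' The symbol obtained by negating the underlying signal (rank reversal).
#' For the lexicographic coding used here, `opposed(code) = 5 - code`.
#'
#' @param code Integer symbol code(s) in 0..5.
#' @return Integer code(s) of the opposed pattern.
#' @export
opposed_symbol <- function(code) {
  stopifnot(all(code %in% 0:5))
  5L - as.integer(code)
}

#' Weighted symbolic mutual information between two symbol streams
#'
#' Plug-in mutual information over the 6 x 6 joint symbol distribution,
#' multiplied by binary weights that are zero when the two symbols are
#' identical or sign-opposed, and normalised by `ln(6)`:
#' `wSMI = (1/ln 6) * sum w(sa, sb) p(sa, sb) ln[p(sa, sb) / (p(sa) p(sb))]`.
#' Empty joint cells contribute zero. The measure is symmetric in its
#' arguments and exactly zero for a stream paired with itself or with its
#' negation.
#'
#' @param a,b Integer symbol streams (codes 0..5) of equal length, as
#'   returned by [symbolize()].
#' @param clamp Clamp small negative plug-in estimates to zero (default
#'   `TRUE`; the population value is non-negative but the finite-sample
#'   plug-in estimate can dip slightly below zero).
#' @return Scalar wSMI value (unitless, below 1).
#' @export
wsmi_pair <- function(a, b, clamp = TRUE) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b))
    stop("symbol streams must have equal length", call. = FALSE)
  n <- length(a)
  joint <- matrix(tabulate(a * 6L + b + 1L, nbins = 36L), 6L, 6L,
                  byrow = TRUE) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  w <- matrix(1, 6L, 6L)
  diag(w) <- 0
  w[cbind(1:6, 6:1)] <- 0  # sign-opposed patterns
  denom <- outer(pa, pb)
  nz <- joint > 0 & w > 0
  v <- sum(joint[nz] * log(joint[nz] / denom[nz])) / log(6)
  if (clamp) max(0, v) else v
}

#' Seed-to-scalp wSMI map
#'
#' Computes [wsmi_pair()] for every (seed electrode, non-seed electrode)
#' pair of a recording, after symbolizing each channel once. Intended to be
#' run on current-source-density transformed, 256 Hz continuous data.
#'
#' @param rec An `eeg_recording` (typically CSD-transformed).
#' @param layout A `channel_layout` (used for pair distances).
#' @param seed_roi Character vector of seed electrode labels (default: the
#'   right-frontal seed, electrodes 62-69 and 73-77).
#' @param k,tau_ms Symbolization parameters (see [symbolize()]).
#' @param subject,condition Identifiers stored on the result.
#' @return Data frame of class `wsmi_matrix` with columns `seed`, `target`,
#'   `distance_cm`, `value`, one row per pair.
#' @export
wsmi_seed_map <- function(rec, layout, seed_roi = hep_rois()$seed,
                          k = 3, tau_ms = 16,
                          subject = NA_character_,
                          condition = NA_character_) {
  stopifnot(inherits(rec, "eeg_recording"))
  seed_roi <- as.character(seed_roi)
  if (!all(seed_roi %in% rec$labels))
    stop("seed ROI labels missing from recording", call. = FALSE)
  targets <- setdiff(rec$labels, seed_roi)
  syms <- lapply(seq_len(ncol(rec$data)), function(ch)
    symbolize(rec$data[, ch], rec$srate, k = k, tau_ms = tau_ms))
  names(syms) <- rec$labels
  dm <- distance_matrix(layout)
  grid <- expand.grid(seed = seed_roi, target = targets,
                      stringsAsFactors = FALSE)
  grid$distance_cm <- dm[cbind(grid$seed, grid$target)]
  grid$value <- vapply(seq_len(nrow(grid)), function(i)
    wsmi_pair(syms[[grid$seed[i]]], syms[[grid$target[i]]]), numeric(1))
  attr(grid, "subject") <- subject
  attr(grid, "condition") <- condition
  class(grid) <- c("wsmi_matrix", "data.frame")
  grid
}

# stack a list of per-subject wsmi_matrix objects into a value matrix
# (subjects x pairs), verifying that pairs agree
.wsmi_stack <- function(ms) {
  key <- paste(ms[[1L]]$seed, ms[[1L]]$target)
  vals <- vapply(ms, function(m) {
    if (!identical(paste(m$seed, m$target), key))
      stop("wSMI matrices have mismatching pairs", call. = FALSE)
    m$value
  }, numeric(length(key)))
  t(vals)  # subjects x pairs
}

#' Paired condition contrast of wSMI matrices
#'
#' Per-pair two-tailed paired t-tests between two sets of per-subject wSMI
#' matrices, with significance masks at the requested alpha levels. The t
#' statistic is signed so that positive values mean `a > b`.
#'
#' @param a,b Lists of `wsmi_matrix` objects (one per subject, same
#'   subjects in the same order, identical pair sets).
#' @param alphas Numeric vector of significance levels (default 0.05 and
#'   0.01).
#' @return Data frame with columns `seed`, `target`, `distance_cm`,
#'   `mean_a`, `mean_b`, `t`, `p`, and one logical column `sig_<alpha>`
#'   per requested level.
#' @export
wsmi_compare <- function(a, b, alphas = c(0.05, 0.01)) {
  if (length(a) != length(b))
    stop("paired design: need the same subjects in both conditions",
         call. = FALSE)
  if (length(a) < 3) stop("insufficient data: need at least 3 subjects",
                          call. = FALSE)
  va <- .wsmi_stack(a)
  vb <- .wsmi_stack(b)
  d <- va - vb
  n <- nrow(d)
  mu <- colMeans(d)
  se <- sqrt(apply(d, 2L, stats::var) / n)
  tv <- mu / pmax(se, .Machine$double.eps)
  p <- 2 * stats::pt(abs(tv), df = n - 1L, lower.tail = FALSE)
  out <- a[[1L]][, c("seed", "target", "distance_cm")]
  out$mean_a <- colMeans(va)
  out$mean_b <- colMeans(vb)
  out$t <- tv
  out$p <- p
  for (al in alphas) out[[sprintf("sig_%g", al)]] <- p < al
  out
}

#' wSMI as a function of inter-electrode distance
#'
#' Sorts seed-to-scalp pairs by Euclidean distance, averages wSMI within
#' 1 cm distance bins per subject and condition, and tests each bin with a
#' two-tailed sign-flip permutation test on the paired subject differences.
#' Empty bins are skipped.
#'
#' @param a,b Lists of per-subject `wsmi_matrix` objects for the two
#'   conditions (paired).
#' @param bin_width Bin width in cm (default 1).
#' @param alpha Per-bin significance level (default 0.001).
#' @param n_perm Number of sign-flip draws (default 5000).
#' @param seed Integer seed.
#' @return Data frame of class `wsmi_profile`: one row per non-empty bin
#'   with `distance_cm` (bin centre), `n_pairs`, `mean_a`, `mean_b`,
#'   `diff`, `p`, `sig`.
#' @export
wsmi_distance_profile <- function(a, b, bin_width = 1, alpha = 0.001,
                                  n_perm = 5000, seed = 1L) {
  if (length(a) != length(b) || length(a) < 2)
    stop("need at least 2 paired subjects", call. = FALSE)
  va <- .wsmi_stack(a)  # subjects x pairs
  vb <- .wsmi_stack(b)
  dist <- a[[1L]]$distance_cm
  bins <- floor(dist / bin_width)
  ub <- sort(unique(bins))
  set.seed(seed)
  n <- nrow(va)
  rows <- lapply(ub, function(bn) {
    sel <- bins == bn
    ma <- rowMeans(va[, sel, drop = FALSE])
    mb <- rowMeans(vb[, sel, drop = FALSE])
    d <- ma - mb
    obs <- mean(d)
    flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
    null <- as.numeric(flips %*% d) / n
    p <- (sum(abs(null) >= abs(obs)) + 1) / (n_perm + 1)
    data.frame(distance_cm = (bn + 0.5) * bin_width, n_pairs = sum(sel),
               mean_a = mean(ma), mean_b = mean(mb), diff = obs, p = p,
               sig = p < alpha)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("wsmi_profile", "data.frame")
  out
}
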