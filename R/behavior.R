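# Heartbeat-detection performance scoring and behavioural statistics.
#
# The accuracy index is a matching-based score on a 0..1 scale with higher
# values indicating better performance. The task, as described in the heartbeat-detection literature,
# states the scale and direction but the exact formula lives in
# supplementary material that is not reproduced here; the definition below
# is the package's own, chosen to satisfy every stated property: bounded in
# [0, 1], 1 for perfect synchrony, 0 for no taps, decreasing in tap jitter,
# and penalising both missed beats and spurious extra taps. This is flagged
# prominently: scores from this index are comparable within the package,
# not necessarily identical to other implementations of the task.

#' Heartbeat-detection accuracy index
#'
#' Greedy nearest-neighbour matching of taps to target events. Each tap and
#' each target is used at most once; a match is only allowed within half
#' the local inter-target interval (the smaller of the gaps to the two
#' neighbouring targets). A matched pair scores
#' `1 - |dt| / (half local inter-target interval)`; the index is the sum of
#' pair scores divided by `max(n_targets, n_taps)`, so both misses and
#' extra taps lower the score. Numerical round-off is clamped into
#' \code{[0, 1]}.
#'
#' The index is invariant to shifting all times by a constant and to
#' reversing time on the whole record.
#'
#' @param targets An `event_series` (or numeric vector of seconds) of
#'   target events (heartbeats or auditory beats). Must be non-empty.
#' @param taps An `event_series` (or numeric vector) of keypress times.
#'   Empty taps score 0.
#' @return Accuracy score in \code{[0, 1]}.
#' @export
accuracy_index <- function(targets, taps) {
  tg <- if (inherits(targets, "event_series")) targets$times else sort(as.numeric(targets))
  tp <- if (inherits(taps, "event_series")) taps$times else sort(as.numeric(taps))
  if (!length(tg)) stop("`targets` must be non-empty", call. = FALSE)
  if (!length(tp)) return(0)
  nt <- length(tg)
  # half the local inter-target interval (radius of the match window)
  if (nt == 1L) {
    radius <- rep(Inf, 1L)
  } else {
    gaps <- diff(tg)
    radius <- pmin(c(gaps[1L], gaps), c(gaps, gaps[nt - 1L])) / 2
  }
  # candidate matches: for each tap, the targets flanking it
  lo <- findInterval(tp, tg)
  cand_i <- c(pmax(lo, 1L), pmin(lo + 1L, nt))
  cand_tap <- rep(seq_along(tp), 2L)
  dt <- abs(tp[cand_tap] - tg[cand_i])
  ok <- dt <= radius[cand_i]
  cand_i <- cand_i[ok]; cand_tap <- cand_tap[ok]; dt <- dt[ok]
  ord <- order(dt)
  used_t <- rep(FALSE, nt)
  used_p <- rep(FALSE, length(tp))
  total <- 0
  for (m in ord) {
    i <- cand_i[m]; j <- cand_tap[m]
    if (used_t[i] || used_p[j]) next
    used_t[i] <- TRUE; used_p[j] <- TRUE
    total <- total + (1 - dt[m] / radius[i])
  }
  min(1, max(0, total / max(nt, length(tp))))
}

#' Repeated-measures one-way ANOVA on an accuracy table
#'
#' Classical within-subject ANOVA with subject and condition effects and
#' the subject-by-condition interaction as the error term, fitted with
#' [stats::aov()]. No sphericity correction is applied (uncorrected degrees
#' of freedom are reported). Subjects with incomplete data across
#' conditions are dropped listwise; the dropped count is reported.
#'
#' @param table Data frame with columns `subject`, `condition`, `accuracy`
#'   (optionally `block`; blocks are averaged to one value per
#'   subject-condition first).
#' @return List of class `rm_anova` with elements `F`, `df` (numerator,
#'   denominator), `p`, `ms_error`, `means` (per-condition), `n` (complete
#'   subjects), `n_dropped`, and `table` (the complete-case table used).
#' @export
rm_anova <- function(table) {
  stopifnot(all(c("subject", "condition", "accuracy") %in% names(table)))
  tab <- stats::aggregate(accuracy ~ subject + condition, data = table,
                          FUN = mean)
  tab$subject <- factor(tab$subject)
  tab$condition <- factor(tab$condition)
  k <- nlevels(tab$condition)
  counts <- table(tab$subject)
  complete <- names(counts)[counts == k]
  n_dropped <- nlevels(tab$subject) - length(complete)
  if (length(complete) < 2)
    stop("insufficient data: fewer than 2 subjects with complete data",
         call. = FALSE)
  if (n_dropped > 0)
    message(sprintf("rm_anova: dropped %d subject(s) with incomplete data",
                    n_dropped))
  tab <- droplevels(tab[tab$subject %in% complete, ])
  fit <- stats::aov(accuracy ~ condition + Error(subject), data = tab)
  s <- summary(fit)[["Error: Within"]][[1L]]
  Fv <- s["condition", "F value"]
  df1 <- s["condition", "Df"]
  df2 <- s["Residuals", "Df"]
  mse <- s["Residuals", "Mean Sq"]
  structure(list(
    F = unname(Fv), df = c(df1, df2),
    p = unname(stats::pf(Fv, df1, df2, lower.tail = FALSE)),
    ms_error = unname(mse),
    means = tapply(tab$accuracy, tab$condition, mean),
    n = length(complete), n_dropped = n_dropped, table = tab),
    class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.2f, p = %.3g (MS_error = %.4g, n = %d)\n",
              x$df[1L], x$df[2L], x$F, x$p, x$ms_error, x$n))
  invisible(x)
}

#' Tukey HSD post hoc test after a repeated-measures ANOVA
#'
#' Studentized-range test on all condition pairs, using the error mean
#' square and denominator degrees of freedom of the within-subject ANOVA:
#' `q = |mean_i - mean_j| / sqrt(MS_error / n)`, with p-values from
#' [stats::ptukey()].
#'
#' @param fit An `rm_anova` object.
#' @return Data frame with one row per condition pair: `a`, `b`, `diff`
#'   (mean of `a` minus mean of `b`), `q` and `p`.
#' @export
tukey_hsd <- function(fit) {
  stopifnot(inherits(fit, "rm_anova"))
  m <- fit$means
  k <- length(m)
  se <- sqrt(fit$ms_error / fit$n)
  pairs <- utils::combn(names(m), 2L)
  out <- data.frame(a = pairs[1L, ], b = pairs[2L, ])
  out$diff <- m[out$a] - m[out$b]
  out$q <- abs(out$diff) / se
  out$p <- stats::ptukey(out$q, nmeans = k, df = fit$df[2L],
                         lower.tail = FALSE)
  rownames(out) <- paste(out$a, "vs", out$b)
  out
}
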