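#' Multichannel recording container
#'
#' A lightweight container for a multichannel electrophysiological time
#' series. Data are stored as a samples x channels numeric matrix in
#' microvolts, together with the sampling rate and channel labels.
#'
#' @param data Numeric matrix, samples x channels (microvolts). A vector is
#'   treated as a single channel.
#' @param srate Sampling rate in Hz (positive scalar).
#' @param labels Character vector of channel labels, one per column.
#' @param kind One of `"scalp"`, `"ecg"`, `"ieeg"`.
#' @return An object of class `eeg_recording`: a list with elements
#'   `data`, `srate`, `labels`, `kind`.
#' @export
new_recording <- function(data, srate, labels = NULL, kind = "scalp") {
  if (is.vector(data)) data <- matrix(data, ncol = 1L)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("`srate` must be a positive scalar (Hz)", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(data)))
  labels <- as.character(labels)
  if (length(labels) != ncol(data))
    stop("one label per channel required", call. = FALSE)
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  kind <- match.arg(kind, c("scalp", "ecg", "ieeg"))
  structure(list(data = data, srate = srate, labels = labels, kind = kind),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channel(s), %d samples @ %g Hz (%.1f s)\n",
              x$kind, ncol(x$data), nrow(x$data), x$srate,
              nrow(x$data) / x$srate))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Ordered event timestamps
#'
#' Holds an ordered series of event times in seconds (R peaks, keyboard
#' taps, or auditory beats), tagged with the event kind.
#'
#' @param times Numeric vector of timestamps in seconds.
#' @param kind Free-text tag, e.g. `"r-peak"`, `"tap"`, `"beat"`.
#' @return An object of class `event_series`.
#' @export
event_series <- function(times, kind = "event") {
  times <- as.numeric(times)
  if (anyNA(times)) stop("event times must not contain NA", call. = FALSE)
  if (is.unsorted(times)) times <- sort(times)
  structure(list(times = times, kind = as.character(kind)[1L]),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s: %d events", x$kind, length(x$times)))
  if (length(x$times) > 1L)
    cat(sprintf(" over %.1f s (median interval %.0f ms)",
                diff(range(x$times)), 1000 * stats::median(diff(x$times))))
  cat("\n")
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$times)

#' Set of event-locked epochs
#'
#' Epoched data are stored as an epochs x channels x samples array with a
#' per-epoch rejection mask. Rejected epochs are excluded from all averages
#' computed by the package.
#'
#' @param data Numeric array, epochs x channels x samples (microvolts).
#' @param times_ms Numeric vector of sample times in ms relative to the
#'   time-locking event, length `dim(data)[3]`.
#' @param srate Sampling rate in Hz.
#' @param labels Channel labels, length `dim(data)[2]`.
#' @param rejected Logical mask, one entry per epoch.
#' @param condition,subject Optional identifiers carried along.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times_ms, srate, labels,
                      rejected = rep(FALSE, dim(data)[1L]),
                      condition = NA_character_, subject = NA_character_) {
  stopifnot(length(dim(data)) == 3L,
            length(times_ms) == dim(data)[3L],
            length(labels) == dim(data)[2L],
            length(rejected) == dim(data)[1L])
  structure(list(data = data, times_ms = as.numeric(times_ms), srate = srate,
                 labels = as.character(labels), rejected = as.logical(rejected),
                 condition = condition, subject = subject),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs (%d rejected), %d channels, %d samples @ %g Hz, %0.f..%0.f ms\n",
    dim(x$data)[1L], sum(x$rejected), dim(x$data)[2L], dim(x$data)[3L],
    x$srate, min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Number of retained (non-rejected) epochs
#' @param x An `epoch_set`.
#' @return Integer count.
#' @export
n_retained <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  sum(!x$rejected)
}
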