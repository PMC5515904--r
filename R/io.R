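# Plain-text interchange formats.
#
# Recordings travel as tab-separated matrices with a small '#'-prefixed
# metadata header (srate, kind, unit); events as one timestamp in seconds
# per line under a kind header; accuracy tables and electrode positions as
# TSV. All formats round-trip exactly at the stored precision.

#' Write / read a recording as a tab-separated matrix
#'
#' The file starts with `# srate=<Hz>`, `# kind=<scalp|ecg|ieeg>` and
#' `# unit=uV` comment lines, followed by a header row of channel labels
#' and one row per sample. Values are written with full precision
#' (17 significant digits), so a round-trip reproduces the data to within
#' double-precision quantisation.
#'
#' @param rec An `eeg_recording`.
#' @param path File path.
#' @param format Only `"tsv"` is supported.
#' @param srate Optional expected sampling rate: `read_recording()` errors
#'   if the file header disagrees.
#' @return `read_recording()` returns an `eeg_recording`.
#' @export
write_recording <- function(rec, path, format = "tsv") {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format, "tsv")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# srate=%.10g", rec$srate),
               sprintf("# kind=%s", rec$kind),
               "# unit=uV",
               paste(rec$labels, collapse = "\t")), con)
  utils::write.table(format(rec$data, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, format = "tsv", srate = NULL) {
  format <- match.arg(format, "tsv")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 10L)
  meta_lines <- grep("^#", hdr, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  if (is.null(meta$srate))
    stop("malformed header: missing '# srate=' line (byte offset 0)",
         call. = FALSE)
  fsrate <- as.numeric(meta$srate)
  if (!is.null(srate) && abs(fsrate - srate) > 1e-9)
    stop(sprintf("sampling-rate mismatch: file %g Hz, expected %g Hz",
                 fsrate, srate), call. = FALSE)
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  new_recording(as.matrix(dat), fsrate, colnames(dat),
                kind = meta$kind %||% "scalp")
}

#' Write / read event timestamps
#'
#' Plain text: a `# kind=<tag>` header line, then one timestamp in seconds
#' per line.
#'
#' @param events An `event_series`.
#' @param path File path.
#' @return `read_events()` returns an `event_series`.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_series"))
  writeLines(c(sprintf("# kind=%s", events$kind),
               sprintf("%.9f", events$times)), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  kind <- "event"
  k <- grep("^#\\s*kind=", lines)
  if (length(k)) kind <- sub("^#\\s*kind=", "", lines[k[1L]])
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  event_series(as.numeric(lines), kind)
}

#' Write / read a behavioural accuracy table
#'
#' Tab-separated with columns `subject`, `condition`, `accuracy` (and any
#' extra columns preserved).
#'
#' @param table Data frame.
#' @param path File path.
#' @return `read_accuracy_table()` returns a data frame with `subject` and
#'   `condition` as factors.
#' @export
write_accuracy_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_accuracy_table
#' @export
read_accuracy_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("subject", "condition", "accuracy")
  if (!all(need %in% names(df)))
    stop("accuracy table must have columns subject, condition, accuracy",
         call. = FALSE)
  df$subject <- factor(df$subject)
  df$condition <- factor(df$condition)
  df
}
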