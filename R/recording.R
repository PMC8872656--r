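#' Multichannel array recording
#'
#' Container for a time x 12-channel matrix of sensor pressure samples.
#'
#' @param samples numeric matrix, one column per channel (12 columns).
#' @param fs sampling rate in Hz.
#' @param layout a [channel_layout()].
#' @param subject_id free-text subject identifier.
#' @param group group label, one of `"healthy"`, `"hypertensive"`,
#'   `"unknown"`.
#' @return An object of class `array_recording`.
#' @export
array_recording <- function(samples, fs = 100, layout = channel_layout(),
                            subject_id = "anonymous", group = "unknown") {
  samples <- as.matrix(samples)
  if (ncol(samples) != 12L)
    stop("samples must have exactly 12 channel columns, got ", ncol(samples))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive number")
  if (anyNA(samples) || !all(is.finite(samples)))
    stop("samples contain missing or non-finite values")
  group <- match.arg(group, c("healthy", "hypertensive", "unknown"))
  colnames(samples) <- sprintf("ch%02d", 1:12)
  structure(list(samples = samples, fs = fs, layout = layout,
                 meta = list(subject_id = subject_id, group = group)),
            class = "array_recording")
}

#' @export
print.array_recording <- function(x, ...) {
  cat(sprintf("array_recording: %d samples x 12 channels @ %g Hz (%.1f s)\n",
              nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat(sprintf("  subject: %s  group: %s\n",
              x$meta$subject_id, x$meta$group))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an [array_recording()].
#' @export
recording_duration <- function(recording) {
  nrow(recording$samples) / recording$fs
}

#' Read a recording from delimited text
#'
#' Expects a comma-delimited file with a header row
#' `time,ch01,...,ch12`: a time column in seconds followed by the twelve
#' channel columns. The time column must be monotone increasing with a
#' spacing consistent (within 1\%) with the declared sampling rate.
#'
#' @param path path to the file.
#' @param fs declared sampling rate in Hz.
#' @param layout a [channel_layout()].
#' @param subject_id,group metadata; `subject_id` defaults to the file
#'   base name.
#' @return An [array_recording()].
#' @export
read_recording <- function(path, fs = 100, layout = channel_layout(),
                           subject_id = NULL, group = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) != 13L)
    stop("recording format error: expected 13 columns (time + 12 channels), got ",
         ncol(df))
  tm <- df[[1]]
  if (anyNA(df)) stop("ingest error: file contains missing values")
  if (any(diff(tm) <= 0))
    stop("recording format error: time column is not strictly increasing")
  dt <- diff(tm)
  if (any(abs(dt - 1 / fs) > 0.01 / fs))
    stop(sprintf(
      "recording format error: time spacing (median %.6g s) inconsistent with fs = %g Hz",
      stats::median(dt), fs))
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  array_recording(as.matrix(df[, -1]), fs = fs, layout = layout,
                  subject_id = subject_id, group = group)
}

#' Write a recording to delimited text
#'
#' Inverse of [read_recording()]; writes `time,ch01..ch12` with time in
#' seconds starting at 0.
#'
#' @param recording an [array_recording()].
#' @param path output file path.
#' @export
write_recording <- function(recording, path) {
  n <- nrow(recording$samples)
  df <- data.frame(time = (seq_len(n) - 1) / recording$fs,
                   recording$samples, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
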