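#' Multichannel EEG recording
#'
#' Container for a multichannel time series: a numeric matrix with one
#' column per channel (samples in rows), the sampling rate, channel labels
#' and subject/group metadata. All pipeline stages accept and return this
#' class.
#'
#' @param data Numeric matrix, samples x channels. All values must be finite.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param channel_labels Character vector, one label per column of `data`.
#'   Defaults to the column names of `data`.
#' @param subject_id Identifier string for the recording.
#' @param group One of `"control"`, `"patient"`, `"simulated-control"`,
#'   `"simulated-patient"`, `"simulated-lesion"`, or `"unknown"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = colnames(data),
                          subject_id = "s1", group = "unknown") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) {
    stop("EEG data contains non-finite samples", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(ncol(data)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != ncol(data)) {
    stop(sprintf("channel count (%d) does not match label count (%d)",
                 ncol(data), length(channel_labels)), call. = FALSE)
  }
  groups <- c("control", "patient", "simulated-control", "simulated-patient",
              "simulated-lesion", "unknown")
  if (!group %in% groups) {
    stop("unknown group tag: ", group, call. = FALSE)
  }
  colnames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = as.character(subject_id), group = group),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, ncol(x$data), nrow(x$data), x$fs,
              nrow(x$data) / x$fs))
  invisible(x)
}

#' @rdname eeg_recording
#' @param rec An `eeg_recording`.
#' @export
n_channels <- function(rec) ncol(rec$data)

#' @rdname eeg_recording
#' @export
n_samples <- function(rec) nrow(rec$data)

#' Read / write EEG as CSV
#'
#' The CSV layout is one column per channel with a header row of channel
#' labels, one sample per row.
#'
#' @param path File path.
#' @param fs Sampling frequency in Hz of the stored recording.
#' @inheritParams eeg_recording
#' @return `read_eeg_csv()` returns an [eeg_recording()]; `write_eeg_csv()`
#'   returns `path` invisibly.
#' @export
read_eeg_csv <- function(path, fs, subject_id = basename(path),
                         group = "unknown") {
  df <- read.csv(path, check.names = FALSE)
  eeg_recording(as.matrix(df), fs = fs, channel_labels = names(df),
                subject_id = subject_id, group = group)
}

#' @rdname read_eeg_csv
#' @param rec Recording to write.
#' @export
write_eeg_csv <- function(rec, path) {
  write.csv(as.data.frame(rec$data), path, row.names = FALSE)
  invisible(path)
}
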