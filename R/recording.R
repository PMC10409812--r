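#' EEG recording container
#'
#' A light S3 container for a multichannel EEG recording: a channels-by-samples
#' numeric matrix in microvolts plus sampling rate, channel labels and the
#' current reference state. Everything derived from a recording (events, wave
#' inventories, features, reports) is returned as a tibble.
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of 10-20 electrode names, one per row.
#' @param reference reference state, `"as-recorded"` or
#'   `"contralateral-mastoid"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, channel_labels,
                          reference = c("as-recorded", "contralateral-mastoid")) {
  reference <- match.arg(reference)
  if (!is.matrix(signal) || !is.numeric(signal)) {
    abort("`signal` must be a numeric channels x samples matrix")
  }
  assert_scalar_num(fs, "fs", lo = 1e-9)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(signal)) {
    abort("one channel label per signal row is required")
  }
  if (anyDuplicated(channel_labels)) abort("channel labels must be unique")
  rownames(signal) <- channel_labels
  structure(
    list(signal = signal, fs = fs, channel_labels = channel_labels,
         reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.2f h), reference: %s\n",
    nrow(x$signal), ncol(x$signal), x$fs,
    ncol(x$signal) / x$fs / 3600, x$reference))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an [eeg_recording()].
#' @return duration in seconds.
#' @export
duration_s <- function(rec) ncol(rec$signal) / rec$fs

#' Extract one channel as a numeric vector
#' @param rec an [eeg_recording()].
#' @param channel channel label.
#' @return numeric vector of samples in microvolts.
#' @export
channel_signal <- function(rec, channel) {
  if (!channel %in% rec$channel_labels) {
    abort(sprintf("channel '%s' not present in recording", channel))
  }
  rec$signal[channel, ]
}

#' 20-s epoch grid of a recording
#'
#' Epoch `i` (1-based) covers the half-open sample interval
#' `[(i-1)*20*fs, i*20*fs)`. An incomplete trailing epoch is dropped.
#'
#' @param rec an [eeg_recording()], or a duration in seconds when `fs` given.
#' @param fs sampling rate, only when `rec` is a duration.
#' @return A tibble with `epoch_index`, `start_s`, `end_s`, `start_sample`,
#'   `end_sample` (half-open, 1-based samples).
#' @export
epoch_grid <- function(rec, fs = NULL) {
  if (inherits(rec, "eeg_recording")) {
    dur <- duration_s(rec); fs <- rec$fs
  } else {
    dur <- rec
    if (is.null(fs)) abort("`fs` is required when `rec` is a duration")
  }
  n <- floor(dur / EPOCH_S)
  tibble(
    epoch_index = seq_len(n),
    start_s = (seq_len(n) - 1) * EPOCH_S,
    end_s = seq_len(n) * EPOCH_S,
    start_sample = (seq_len(n) - 1) * EPOCH_S * fs + 1,
    end_sample = seq_len(n) * EPOCH_S * fs
  )
}

# channel-name normalisation shared by the EDF reader and re-referencing:
# strip modality prefixes, case-fold to 10-20 capitalisation, map A1/A2 to
# the mastoid labels M1/M2
normalize_channel_label <- function(label) {
  lab <- trimws(sub("^\\s*EEG[ _-]*", "", label, ignore.case = TRUE))
  lab <- sub("[-_].*$", "", lab)  # drop reference suffix such as "C3-A2"
  lab <- toupper(lab)
  lab[lab == "A1"] <- "M1"
  lab[lab == "A2"] <- "M2"
  # canonical capitalisation: letters upper, except z for midline sites
  lab <- gsub("Z", "z", lab)
  lab
}

# laterality from the 10-20 label: odd digit = left, even = right, z = midline
channel_side <- function(label) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", label)))
  ifelse(grepl("z$", label), "midline",
         ifelse(is.na(num), "midline", ifelse(num %% 2L == 1L, "left", "right")))
}
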