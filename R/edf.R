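## EDF / EDF+ 16-bit read and write.
## The format is fixed-layout ASCII headers plus little-endian int16 data
## records; see the format's published field table. Only what the pipeline
## needs is implemented: uniform-per-channel sampling (with
## resample-to-lowest for mixed rates), physical scaling to microvolts, and
## skipping of EDF+ annotation channels.

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' Writes 16-bit EDF with 1-s data records, physical dimension uV and a
#' per-channel symmetric physical range. The signal is truncated to a whole
#' number of seconds.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param patient_id,recording_id free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient_id = "X", recording_id = "simulated") {
  fs <- rec$fs
  if (fs != round(fs)) abort("EDF writer requires an integer sampling rate")
  n_rec <- floor(ncol(rec$signal) / fs)
  if (n_rec < 1) abort("recording shorter than one 1-s data record")
  ns <- nrow(rec$signal)
  sig <- rec$signal[, seq_len(n_rec * fs), drop = FALSE]

  phys_max <- pmax(1, ceiling(apply(abs(sig), 1, max) * 1.05))
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient_id, 80), edf_pad(recording_id, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(edf_pad(paste("EEG", rec$channel_labels), 16), collapse = ""), con, eos = NULL)
  writeChar(paste0(edf_pad(rep("AgAgCl electrode", ns), 80), collapse = ""), con, eos = NULL)
  writeChar(paste0(edf_pad(rep("uV", ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(edf_pad(-phys_max, 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(edf_pad(phys_max, 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(edf_pad(rep(dig_min, ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(edf_pad(rep(dig_max, ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(edf_pad(rep("", ns), 80), collapse = ""), con, eos = NULL)
  writeChar(paste0(edf_pad(rep(fs, ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(edf_pad(rep("", ns), 32), collapse = ""), con, eos = NULL)

  scale <- (dig_max - dig_min) / (2 * phys_max)
  dig <- round((sig + phys_max) * scale) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  # interleave per record: for each 1-s record, all channels sequentially
  arr <- array(t(dig), dim = c(fs, n_rec, ns))        # sample x record x ch
  out <- aperm(arr, c(1, 3, 2))                       # sample x ch x record
  writeBin(as.integer(out), con, size = 2, endian = "little")
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) {
    raw <- readChar(con, w, useBytes = TRUE)
    if (length(raw) == 0 || nchar(raw, type = "bytes") < w) {
      abort("corrupt EDF header: file truncated")
    }
    trimws(raw)
  }
  version <- rd(8)
  if (version != "0") abort("corrupt EDF header: unsupported version field")
  h <- list(
    version = version, patient_id = rd(80), recording_id = rd(80),
    startdate = rd(8), starttime = rd(8),
    header_bytes = as.integer(rd(8)), reserved = rd(44),
    n_records = as.integer(rd(8)), record_dur = as.numeric(rd(8)),
    ns = as.integer(rd(4))
  )
  if (is.na(h$ns) || h$ns < 1) abort("corrupt EDF header: bad signal count")
  rdn <- function(w) vapply(seq_len(h$ns), function(i) rd(w), character(1))
  h$labels <- rdn(16); h$transducer <- rdn(80); h$phys_dim <- rdn(8)
  h$phys_min <- as.numeric(rdn(8)); h$phys_max <- as.numeric(rdn(8))
  h$dig_min <- as.numeric(rdn(8)); h$dig_max <- as.numeric(rdn(8))
  h$prefilter <- rdn(80); h$spr <- as.integer(rdn(8)); h$sig_reserved <- rdn(32)
  if (any(is.na(h$spr)) || any(h$spr < 1)) {
    abort("corrupt EDF header: bad samples-per-record")
  }
  h
}

#' Read an EDF/EDF+ recording
#'
#' Applies physical scaling (output in the file's physical units, uV for
#' recordings written by this package), normalizes channel labels (strips
#' an `EEG` prefix, drops reference suffixes, maps A1/A2 to M1/M2) and skips
#' EDF+ annotation channels. Channels with mixed sampling rates are resampled
#' to the lowest rate (integer ratios only) with a warning.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort(sprintf("EDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)

  n_rec <- h$n_records
  total_per_rec <- sum(h$spr)
  data <- readBin(con, integer(), n = n_rec * total_per_rec, size = 2,
                  endian = "little")
  if (length(data) < n_rec * total_per_rec) {
    abort("corrupt EDF: data shorter than header promises")
  }
  arr <- matrix(data, nrow = total_per_rec, ncol = n_rec)
  offsets <- c(0L, cumsum(h$spr))

  keep <- !grepl("EDF Annotations", h$labels, fixed = TRUE)
  labels <- normalize_channel_label(h$labels[keep])

  sigs <- lapply(which(keep), function(i) {
    rows <- (offsets[i] + 1L):offsets[i + 1L]
    d <- as.vector(arr[rows, , drop = FALSE])
    g <- (h$phys_max[i] - h$phys_min[i]) / (h$dig_max[i] - h$dig_min[i])
    (d - h$dig_min[i]) * g + h$phys_min[i]
  })
  fs_all <- h$spr[keep] / h$record_dur

  fs <- min(fs_all)
  if (length(unique(fs_all)) > 1L) {
    warn(sprintf("mixed per-channel sampling rates; resampling all to %g Hz", fs))
    sigs <- purrr::map2(sigs, fs_all, function(x, f) {
      r <- f / fs
      if (r == 1) return(x)
      if (r != round(r)) abort("non-integer sampling-rate ratio in EDF")
      lp <- signal::butter(6, 0.8 / r, "low")
      signal::filtfilt(lp, x)[seq(1, length(x), by = r)]
    })
  }
  eeg_recording(do.call(rbind, sigs), fs, labels)
}
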