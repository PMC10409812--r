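#' Bandpass and notch filtering
#'
#' Zero-phase (forward-backward) filtering with the standard clinical chain:
#' a 0.3-40 Hz Butterworth bandpass realised as a 4th-order high-pass at
#' 0.3 Hz cascaded with a 4th-order low-pass at 40 Hz (the cascade is
#' numerically robust at the very low normalized high-pass edge), and a
#' 2nd-order IIR notch at 50 Hz with Q = 30. Pass-band gain stays within
#' +/-1 dB over 1-30 Hz and the notch attenuates 50 Hz by far more than
#' 20 dB.
#'
#' @param rec an [eeg_recording()].
#' @param band bandpass edges in Hz.
#' @param notch_hz notch (mains) frequency in Hz.
#' @return The filtered [eeg_recording()].
#' @export
bandpass_notch <- function(rec, band = c(0.3, 40), notch_hz = 50) {
  fs <- rec$fs
  if (fs <= 100) abort("sampling rate must exceed 100 Hz for a 50 Hz notch")
  hp <- signal::butter(4, band[1] / (fs / 2), "high")
  lp <- signal::butter(4, band[2] / (fs / 2), "low")
  nf <- design_notch(notch_hz, fs, q = 30)
  out <- rec
  for (i in seq_len(nrow(rec$signal))) {
    x <- signal::filtfilt(hp, rec$signal[i, ])
    x <- signal::filtfilt(lp, x)
    out$signal[i, ] <- signal::filtfilt(filt = nf$b, a = nf$a, x)
  }
  out
}

# 2nd-order IIR notch (constrained biquad): unit gain away from f0,
# zero at f0, bandwidth f0/Q
design_notch <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Re-reference to the contralateral mastoids
#'
#' Left (odd-numbered) channels are referenced against M2, right
#' (even-numbered) channels against M1, and midline (z) channels against the
#' averaged mastoids. The mastoid channels themselves are left as recorded.
#'
#' @param rec an [eeg_recording()] with `reference = "as-recorded"` and both
#'   mastoids present.
#' @return The re-referenced [eeg_recording()].
#' @export
reref_contralateral_mastoid <- function(rec) {
  if (rec$reference != "as-recorded") {
    abort("recording is already re-referenced")
  }
  for (m in c("M1", "M2")) {
    if (!m %in% rec$channel_labels) {
      abort(sprintf("mastoid channel %s is missing; cannot re-reference", m))
    }
  }
  m1 <- rec$signal["M1", ]; m2 <- rec$signal["M2", ]
  out <- rec
  for (ch in rec$channel_labels) {
    if (ch %in% c("M1", "M2")) next
    ref <- switch(channel_side(ch),
                  left = m2, right = m1, midline = (m1 + m2) / 2)
    out$signal[ch, ] <- rec$signal[ch, ] - ref
  }
  out$reference <- "contralateral-mastoid"
  out
}

#' Downsample to 128 Hz
#'
#' Identity for 128 Hz input; anti-aliased decimation by two (6th-order
#' zero-phase Butterworth at 0.8 x the target Nyquist) for 256 Hz input.
#' Other rates are rejected rather than silently resampled.
#'
#' @param rec an [eeg_recording()] at 128 or 256 Hz.
#' @return The recording at 128 Hz.
#' @export
downsample_128 <- function(rec) {
  if (rec$fs == 128) return(rec)
  if (rec$fs != 256) {
    abort(sprintf("unsupported sampling rate %g Hz (expected 128 or 256)", rec$fs))
  }
  lp <- signal::butter(6, 0.8 * 64 / 128, "low")
  keep <- seq(1, ncol(rec$signal), by = 2)
  sig <- matrix(0, nrow(rec$signal), length(keep),
                dimnames = list(rec$channel_labels, NULL))
  for (i in seq_len(nrow(rec$signal))) {
    sig[i, ] <- signal::filtfilt(lp, rec$signal[i, ])[keep]
  }
  eeg_recording(sig, 128, rec$channel_labels, reference = rec$reference)
}

#' Full preprocessing chain
#'
#' Fixed order: bandpass + notch filter, contralateral-mastoid
#' re-referencing, then downsampling to 128 Hz.
#'
#' @param rec an [eeg_recording()].
#' @inheritParams bandpass_notch
#' @return The preprocessed [eeg_recording()] at 128 Hz.
#' @export
preprocess_recording <- function(rec, band = c(0.3, 40), notch_hz = 50) {
  rec |>
    bandpass_notch(band = band, notch_hz = notch_hz) |>
    reref_contralateral_mastoid() |>
    downsample_128()
}
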