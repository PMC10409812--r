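#' Synthesize one slow wave
#'
#' Builds a negative half-sine of the requested peak amplitude and half-wave
#' duration, followed by a DC-balancing positive lobe (duration `1.5 d`,
#' amplitude `peak_amp / 1.5`, so the waveform integrates to zero). The
#' analytic ascending slope of the negative half-wave is the peak amplitude
#' divided by the time from the most negative peak to the second
#' zero-crossing, i.e. `peak_amp_uv / (halfwave_dur_s / 2)`.
#'
#' @param peak_amp_uv positive magnitude of the negative peak, uV.
#' @param halfwave_dur_s negative half-wave duration in seconds, within
#'   [0.25, 1.0] (waves outside this range are invisible to the detector).
#' @param fs sampling rate, Hz.
#' @param full_oscillation include the positive up-state lobe (default TRUE);
#'   `FALSE` returns only the negative half-wave.
#' @return A list with `samples` (numeric waveform, uV), `true_slope_uv_per_s`,
#'   `halfwave_samples` (sample count of the negative half-wave) and the echo
#'   of the inputs.
#' @export
synth_slow_wave <- function(peak_amp_uv, halfwave_dur_s, fs,
                            full_oscillation = TRUE) {
  if (peak_amp_uv <= 0) abort("`peak_amp_uv` must be > 0")
  if (halfwave_dur_s < 0.25 || halfwave_dur_s > 1.0) {
    abort("`halfwave_dur_s` must lie in [0.25, 1.0] s")
  }
  n_neg <- round(halfwave_dur_s * fs)
  t_neg <- seq_len(n_neg) - 0.5       # sample centers avoid exact-zero samples
  neg <- -peak_amp_uv * sin(pi * t_neg / n_neg)
  samples <- neg
  if (full_oscillation) {
    n_pos <- round(1.5 * halfwave_dur_s * fs)
    t_pos <- seq_len(n_pos) - 0.5
    samples <- c(neg, (peak_amp_uv / 1.5) * sin(pi * t_pos / n_pos))
  }
  list(samples = samples,
       true_slope_uv_per_s = peak_amp_uv / (halfwave_dur_s / 2),
       halfwave_samples = n_neg,
       peak_amp_uv = peak_amp_uv,
       halfwave_dur_s = halfwave_dur_s,
       fs = fs)
}

# biphasic epileptic spike transient: 20 ms negative lobe at the apex
# amplitude, 50 ms positive lobe at half amplitude, then a 300 ms slow
# after-wave (0.3x amplitude) that can register as a slow wave and so
# exercises the post-spike exclusion rule. Returns the waveform and the
# index of the negative apex within it.
synth_spike <- function(amp_uv, fs, after_wave = TRUE) {
  n1 <- max(3L, round(0.020 * fs))
  n2 <- max(3L, round(0.050 * fs))
  neg <- -amp_uv * sin(pi * (seq_len(n1) - 0.5) / n1)
  pos <- 0.5 * amp_uv * sin(pi * (seq_len(n2) - 0.5) / n2)
  w <- c(neg, pos)
  if (after_wave) {
    n3 <- round(0.300 * fs)
    w <- c(w, -0.3 * amp_uv * sin(pi * (seq_len(n3) - 0.5) / n3))
  }
  list(samples = w, apex_index = which.min(w[seq_len(n1)]))
}

# 1-s sleep-spindle burst: sigma-band sinusoid under a Hann envelope
synth_spindle <- function(fs, freq_hz = 13, amp_uv = 20, dur_s = 1) {
  n <- round(dur_s * fs)
  t <- (seq_len(n) - 1) / fs
  env <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  amp_uv * env * sin(2 * pi * freq_hz * t)
}
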