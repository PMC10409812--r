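#' Slow-wave band filter
#'
#' Zero-phase Chebyshev Type II band-pass used before slow-wave detection:
#' pass-band 0.5-4.0 Hz, stop-band edges 0.1 and 10 Hz, 40 dB stop-band
#' attenuation. The filter order is chosen by the standard Chebyshev-II
#' design equation from the (prewarped) band edges and attenuation.
#'
#' @param x numeric single-channel signal, uV.
#' @param fs sampling rate, Hz.
#' @param band pass-band edges in Hz.
#' @param stop stop-band edges in Hz.
#' @param rs stop-band attenuation in dB.
#' @param rp pass-band ripple bound (dB) used in the order equation.
#' @return Filtered signal, same length.
#' @export
sw_filter <- function(x, fs, band = c(0.5, 4.0), stop = c(0.1, 10),
                      rs = 40, rp = 3) {
  n <- cheby2_bandpass_order(band, stop, fs, rp, rs)
  flt <- signal::cheby2(n, rs, stop / (fs / 2), "pass")
  signal::filtfilt(flt, x)
}

# minimum Chebyshev-II order for a band-pass: transform to the low-pass
# prototype via bilinear prewarping, take the tighter of the two stop edges
cheby2_bandpass_order <- function(band, stop, fs, rp, rs) {
  wp <- 2 * fs * tan(pi * band / fs)
  ws <- 2 * fs * tan(pi * stop / fs)
  w0sq <- wp[1] * wp[2]
  bw <- wp[2] - wp[1]
  omega <- min(abs((ws^2 - w0sq) / (bw * ws)))
  ceiling(acosh(sqrt((10^(rs / 10) - 1) / (10^(rp / 10) - 1))) / acosh(omega))
}

#' Detect slow waves as negative half-waves between zero-crossings
#'
#' Scans a zero-mean (delta-filtered) signal for negative deflections between
#' a downward and the next upward zero-crossing separated by 0.25-1.0 s.
#' Zero-crossing times are linearly interpolated between samples; the peak is
#' the most negative sample in between; the ascending slope is the peak
#' magnitude divided by the time from the peak to the second zero-crossing.
#'
#' @param x numeric single-channel signal (after [sw_filter()] or otherwise
#'   band-limited and zero-mean), uV.
#' @param fs sampling rate, Hz.
#' @param min_dur_s,max_dur_s admissible half-wave duration bounds, seconds.
#' @param min_amp_uv optional amplitude floor (uV); 0 disables it.
#' @return A tibble with one row per wave: `zc1_s`, `peak_s`, `peak_amp_uv`,
#'   `zc2_s`, `slope_uv_per_s`, `dur_s`.
#' @export
detect_slow_waves <- function(x, fs, min_dur_s = 0.25, max_dur_s = 1.0,
                              min_amp_uv = 0) {
  empty <- tibble(zc1_s = numeric(0), peak_s = numeric(0),
                  peak_amp_uv = numeric(0), zc2_s = numeric(0),
                  slope_uv_per_s = numeric(0), dur_s = numeric(0))
  if (length(x) < 3) return(empty)
  neg <- x < 0
  d <- diff(neg)
  down <- which(d == 1L)    # sample j: x[j] >= 0, x[j+1] < 0
  up <- which(d == -1L)     # sample j: x[j] < 0,  x[j+1] >= 0
  if (!length(down) || !length(up)) return(empty)
  u_pos <- findInterval(down, up) + 1L
  ok <- u_pos <= length(up)
  down <- down[ok]
  u <- up[u_pos[ok]]
  if (!length(down)) return(empty)

  z1 <- (down - 1) / fs + (x[down] / (x[down] - x[down + 1L])) / fs
  z2 <- (u - 1) / fs + (x[u] / (x[u] - x[u + 1L])) / fs
  dur <- z2 - z1
  gate <- dur >= min_dur_s & dur <= max_dur_s
  down <- down[gate]; u <- u[gate]; z1 <- z1[gate]; z2 <- z2[gate]
  dur <- dur[gate]
  if (!length(down)) return(empty)

  pk_i <- vapply(seq_along(down), function(i) {
    seg <- (down[i] + 1L):u[i]
    seg[which.min(x[seg])]
  }, integer(1))
  amp <- -x[pk_i]
  peak_s <- (pk_i - 1) / fs
  waves <- tibble(zc1_s = z1, peak_s = peak_s, peak_amp_uv = amp,
                  zc2_s = z2, slope_uv_per_s = amp / (z2 - peak_s),
                  dur_s = dur)
  if (min_amp_uv > 0) waves <- waves[waves$peak_amp_uv >= min_amp_uv, ]
  waves
}

#' Exclude slow waves following epileptic spikes
#'
#' Removes every wave whose `[zc1, zc2]` interval overlaps the window
#' `[t_spike, t_spike + window_s]` of any spike (interval-overlap rule; set
#' `rule = "peak"` to require only the negative peak inside the window).
#' The operation is idempotent and returns a subset of its input.
#'
#' @param waves tibble from [detect_slow_waves()].
#' @param spike_times sorted numeric spike apex times, seconds.
#' @param window_s exclusion window after each spike, seconds.
#' @param rule `"overlap"` (default) or `"peak"`.
#' @return The retained waves, with an `excluded_post_spike` count attribute.
#' @export
exclude_post_spike <- function(waves, spike_times, window_s = 0.5,
                               rule = c("overlap", "peak")) {
  rule <- match.arg(rule)
  if (!length(spike_times) || !nrow(waves)) {
    attr(waves, "excluded_post_spike") <- 0L
    return(waves)
  }
  sp <- sort(spike_times)
  lo <- if (rule == "overlap") waves$zc1_s - window_s else waves$peak_s - window_s
  hi <- if (rule == "overlap") waves$zc2_s else waves$peak_s
  # wave hit iff some spike time lies in [lo, hi]
  n_hit <- findInterval(hi, sp) - findInterval(lo - 1e-12, sp)
  out <- waves[n_hit == 0L, ]
  attr(out, "excluded_post_spike") <- sum(n_hit > 0L)
  out
}

#' Amplitude-match first-hour and last-hour wave sets
#'
#' Histograms both sets' negative-peak amplitudes in shared bins of
#' `bin_width_uv` starting at 0 and, within each bin, keeps
#' `min(count_FH, count_LH)` waves per side, subsampling the larger side
#' uniformly (seeded). Fewer than `min_matched` surviving waves flags the
#' recording for exclusion.
#'
#' @param fh_waves,lh_waves wave tibbles from [detect_slow_waves()] for the
#'   first and last hour of NREM sleep.
#' @param bin_width_uv amplitude bin width, uV.
#' @param seed integer seed for the subsampling.
#' @param min_matched minimum matched-wave count per side.
#' @return A list of class `matched_waves`: `fh`, `lh` (equal-size tibbles),
#'   `n_matched`, `bin_width_uv`, `insufficient` flag.
#' @export
amplitude_match <- function(fh_waves, lh_waves, bin_width_uv = 10, seed = 1L,
                            min_matched = 250L) {
  if (!nrow(fh_waves) || !nrow(lh_waves)) {
    abort("both wave sets must be non-empty for amplitude matching")
  }
  bf <- floor(fh_waves$peak_amp_uv / bin_width_uv)
  bl <- floor(lh_waves$peak_amp_uv / bin_width_uv)
  keep_f <- integer(0); keep_l <- integer(0)
  withr::with_seed(seed, {
    for (b in sort(intersect(unique(bf), unique(bl)))) {
      fi <- which(bf == b); li <- which(bl == b)
      m <- min(length(fi), length(li))
      keep_f <- c(keep_f, fi[sample.int(length(fi), m)])
      keep_l <- c(keep_l, li[sample.int(length(li), m)])
    }
  })
  structure(
    list(fh = fh_waves[sort(keep_f), ], lh = lh_waves[sort(keep_l), ],
         n_matched = length(keep_f), bin_width_uv = bin_width_uv,
         insufficient = length(keep_f) < min_matched),
    class = "matched_waves"
  )
}

#' @export
print.matched_waves <- function(x, ...) {
  cat(sprintf("<matched_waves> %d matched per hour (bin %g uV)%s\n",
              x$n_matched, x$bin_width_uv,
              if (x$insufficient) " [INSUFFICIENT]" else ""))
  invisible(x)
}
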