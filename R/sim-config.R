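#' Configuration for the synthetic overnight-EEG generator
#'
#' Defines the study conditions the simulator emulates: an overnight pediatric
#' recording with a realistic hypnogram, 1/f background, delta slow
#' oscillations whose ascending slope declines (or not) from the first to the
#' last hour of NREM sleep, sigma spindles in N2, alpha in wake, and transient
#' epileptic spikes at per-channel Poisson rates with a designated focus
#' channel.
#'
#' Slow waves are generated as full slow oscillations: a negative half-sine of
#' duration `d` (the detectable negative half-wave) followed by a
#' DC-balancing positive lobe of duration `1.5 d`, as in the down-state /
#' up-state morphology of NREM slow oscillations. The analytic ascending slope
#' of each wave is `peak_amp / (d / 2)`. The overnight slope change is
#' injected through the half-wave duration at a fixed amplitude distribution,
#' so the change survives amplitude matching, as a physiological slope change
#' must.
#'
#' @param duration_s total recording duration in seconds (default 6 h).
#' @param fs sampling rate, 128 or 256 Hz.
#' @param channel_labels 10-20 channel names; must include the mastoids
#'   M1 and M2 for downstream re-referencing.
#' @param hypnogram_preset `"pediatric_night"` (cyclic W/N1/N2/N3/REM),
#'   `"nrem_dominant"` (short wake then N2/N3 only; used for compact
#'   recordings that still contain >= 360 NREM epochs), `"all_n2"`, or
#'   `"all_wake"`.
#' @param cycle_len_epochs sleep-cycle length in 20-s epochs (default 270,
#'   i.e. 90 min).
#' @param sw_amp_mean_fh,sw_amp_mean_lh mean negative-peak amplitude (uV) of
#'   slow waves in the first vs last hour of NREM sleep; intermediate epochs
#'   interpolate linearly.
#' @param sw_amp_sd_frac amplitude SD as a fraction of the mean.
#' @param sw_halfwave_dur_s mean negative half-wave duration in seconds; drawn
#'   uniformly in +/-20% around it, must stay within [0.25, 1.0].
#' @param slope_decline_frac injected relative change of the mean ascending
#'   slope from the first to the last hour of NREM sleep (e.g. -0.15 for the
#'   ~15% overnight decline seen in healthy children).
#' @param sw_rate_per_epoch expected slow-wave count per 20-s NREM epoch.
#' @param spike_rate_hz named per-channel Poisson spike rates (Hz); channels
#'   not named get `spike_rate_default_hz`. The maximum-rate channel is the
#'   designated focus and must be unique when any rate is positive.
#' @param spike_rate_default_hz rate for channels not named in
#'   `spike_rate_hz`; mastoids never carry spikes.
#' @param spike_amp_uv negative-apex amplitude of the spike transient (uV).
#' @param spindle_density spindles per N2 epoch.
#' @param noise_scale_uv standard deviation of the pink background noise (uV).
#' @param seed integer seed; the full simulation is bit-reproducible given the
#'   configuration.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(duration_s = 6 * 3600,
                       fs = 128,
                       channel_labels = c("F3", "C3", "O1", "F4", "M1", "M2"),
                       hypnogram_preset = c("pediatric_night", "nrem_dominant",
                                            "all_n2", "all_wake"),
                       cycle_len_epochs = 270,
                       sw_amp_mean_fh = 150,
                       sw_amp_mean_lh = 150,
                       sw_amp_sd_frac = 0.2,
                       sw_halfwave_dur_s = 0.55,
                       slope_decline_frac = -0.15,
                       sw_rate_per_epoch = 8,
                       spike_rate_hz = c(F3 = 0.2),
                       spike_rate_default_hz = 0.02,
                       spike_amp_uv = 150,
                       spindle_density = 3,
                       noise_scale_uv = 8,
                       seed = 1L) {
  hypnogram_preset <- match.arg(hypnogram_preset)
  assert_scalar_num(duration_s, "duration_s", lo = 0)
  if (!fs %in% c(128, 256)) abort("`fs` must be 128 or 256")
  channel_labels <- as.character(channel_labels)
  if (anyDuplicated(channel_labels)) abort("channel labels must be unique")
  assert_scalar_num(sw_halfwave_dur_s, "sw_halfwave_dur_s", lo = 0.25, hi = 1.0)
  if (sw_halfwave_dur_s * 1.2 > 1.0 || sw_halfwave_dur_s * 0.8 < 0.25) {
    abort("`sw_halfwave_dur_s` +/-20% must stay within [0.25, 1.0]")
  }
  assert_scalar_num(sw_rate_per_epoch, "sw_rate_per_epoch", lo = 0)
  assert_scalar_num(spike_rate_default_hz, "spike_rate_default_hz", lo = 0)
  assert_scalar_num(spike_amp_uv, "spike_amp_uv", lo = 0)
  assert_scalar_num(spindle_density, "spindle_density", lo = 0)
  assert_scalar_num(noise_scale_uv, "noise_scale_uv", lo = 0)
  assert_scalar_num(sw_amp_mean_fh, "sw_amp_mean_fh", lo = 0)
  assert_scalar_num(sw_amp_mean_lh, "sw_amp_mean_lh", lo = 0)
  assert_scalar_num(slope_decline_frac, "slope_decline_frac", lo = -0.9, hi = 2)
  if (any(spike_rate_hz < 0)) abort("spike rates must be >= 0")
  if (length(spike_rate_hz) && is.null(names(spike_rate_hz))) {
    abort("`spike_rate_hz` must be a named vector (channel -> rate)")
  }

  rates <- resolve_spike_rates(channel_labels, spike_rate_hz,
                               spike_rate_default_hz)
  if (max(rates) > 0 && sum(rates == max(rates)) != 1L) {
    abort("exactly one channel must carry the maximum spike rate (the focus)")
  }

  structure(
    list(duration_s = duration_s, fs = fs, channel_labels = channel_labels,
         hypnogram_preset = hypnogram_preset,
         cycle_len_epochs = as.integer(cycle_len_epochs),
         sw_amp_mean_fh = sw_amp_mean_fh, sw_amp_mean_lh = sw_amp_mean_lh,
         sw_amp_sd_frac = sw_amp_sd_frac,
         sw_halfwave_dur_s = sw_halfwave_dur_s,
         slope_decline_frac = slope_decline_frac,
         sw_rate_per_epoch = sw_rate_per_epoch,
         spike_rate_hz = rates,
         spike_amp_uv = spike_amp_uv, spindle_density = spindle_density,
         noise_scale_uv = noise_scale_uv, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# expand the (possibly partial) named rate vector over all channels;
# mastoids are reference electrodes and never carry spikes
resolve_spike_rates <- function(channel_labels, spike_rate_hz, default_hz) {
  rates <- setNames(rep(default_hz, length(channel_labels)), channel_labels)
  known <- intersect(names(spike_rate_hz), channel_labels)
  rates[known] <- spike_rate_hz[known]
  rates[channel_labels %in% c("M1", "M2")] <- 0
  rates
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %.2f h @ %g Hz, %d channels, preset '%s', seed %d\n",
    x$duration_s / 3600, x$fs, length(x$channel_labels),
    x$hypnogram_preset, x$seed))
  cat(sprintf("  slope change %+0.3f, SW %g/epoch ~%g uV, noise %g uV\n",
              x$slope_decline_frac, x$sw_rate_per_epoch,
              x$sw_amp_mean_fh, x$noise_scale_uv))
  cat(sprintf("  focus channel: %s\n", sim_focus_channel(x)))
  invisible(x)
}

#' Focus channel designated by a simulation configuration
#' @param config a [sim_config()].
#' @return channel label with the maximum spike rate, or `NA` if all rates 0.
#' @export
sim_focus_channel <- function(config) {
  r <- config$spike_rate_hz
  if (max(r) == 0) return(NA_character_)
  names(r)[which.max(r)]
}
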