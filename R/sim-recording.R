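#' Simulate an overnight EEG recording with full ground truth
#'
#' Renders a multichannel recording according to a [sim_config()]: 1/f pink
#' background on every channel, slow oscillations in NREM2/3 epochs whose
#' ascending slope changes from the first to the last hour of NREM sleep by
#' the injected fraction (in expectation), sigma spindles in N2, alpha in
#' wake, and biphasic epileptic spike transients at per-channel Poisson rates.
#' The returned ground truth carries the hypnogram, spike apex times, the full
#' slow-wave inventory with analytic slopes, and the injected overnight slope
#' change.
#'
#' The slope change is injected through the half-wave duration at a constant
#' amplitude distribution, scheduled over NREM epochs in chronological order:
#' the first 180 NREM epochs carry factor 1, the last 180 carry
#' `1 + slope_decline_frac`, intermediate epochs interpolate linearly (when
#' fewer than 360 NREM epochs exist the factor ramps across all of them).
#'
#' @param config a [sim_config()].
#' @param render_signal if `FALSE`, only the ground truth is generated (the
#'   event draws are identical either way); useful for fast ground-truth
#'   studies.
#' @return A list of class `sim_recording` with elements `recording`
#'   (an [eeg_recording()], or `NULL` when not rendered), `ground_truth`
#'   (class `sim_ground_truth`: `hypnogram`, `spikes`, `waves`,
#'   `injected_somnidex`, `insertion_counts`) and `config`.
#' @export
simulate_recording <- function(config, render_signal = TRUE) {
  if (!all(c("M1", "M2") %in% config$channel_labels)) {
    abort("channel labels must include the mastoids M1 and M2 (re-referencing downstream would be impossible)")
  }
  hyp <- simulate_hypnogram(config)
  gt <- withr::with_seed(child_seed(config$seed, 23L),
                         draw_ground_truth(config, hyp))
  rec <- NULL
  if (render_signal) {
    rec <- withr::with_seed(child_seed(config$seed, 31L),
                            render_sim_signal(config, hyp, gt))
    gt$insertion_counts <- attr(rec, "insertion_counts")
    attr(rec, "insertion_counts") <- NULL
  }
  structure(list(recording = rec, ground_truth = gt, config = config),
            class = "sim_recording")
}

# slope factor per NREM epoch (chronological NREM order)
slope_factor_schedule <- function(n_nrem, frac) {
  if (n_nrem == 0L) return(numeric(0))
  if (n_nrem >= 360L) {
    g <- numeric(n_nrem)
    g[seq_len(180L)] <- 1
    g[seq(n_nrem - 179L, n_nrem)] <- 1 + frac
    mid <- setdiff(seq_len(n_nrem), c(seq_len(180L), seq(n_nrem - 179L, n_nrem)))
    if (length(mid)) {
      g[mid] <- 1 + frac * (seq_along(mid)) / (length(mid) + 1)
    }
    g
  } else {
    1 + frac * (seq_len(n_nrem) - 1) / max(1L, n_nrem - 1L)
  }
}

draw_ground_truth <- function(config, hyp) {
  dur <- floor(config$duration_s / EPOCH_S) * EPOCH_S
  is_nrem <- nrem_mask(hyp)
  nrem_epochs <- hyp$epoch_index[is_nrem]
  g_sched <- slope_factor_schedule(length(nrem_epochs), config$slope_decline_frac)
  amp_sched <- if (length(nrem_epochs) >= 2L) {
    seq(config$sw_amp_mean_fh, config$sw_amp_mean_lh,
        length.out = length(nrem_epochs))
  } else {
    rep(config$sw_amp_mean_fh, length(nrem_epochs))
  }

  eeg_ch <- setdiff(config$channel_labels, c("M1", "M2"))

  ## slow waves: per channel, per NREM epoch, non-overlapping jittered slots
  waves <- vector("list", length(eeg_ch))
  names(waves) <- eeg_ch
  for (ch in eeg_ch) {
    n_per <- pmin(9L, rpois(length(nrem_epochs), config$sw_rate_per_epoch))
    tot <- sum(n_per)
    k_idx <- rep(seq_along(nrem_epochs), times = n_per)
    within <- sequence(n_per)
    g <- g_sched[k_idx]
    d0 <- runif(tot, 0.8, 1.2) * config$sw_halfwave_dur_s
    d <- pmin(1.0, pmax(0.25, d0 / g))
    mu <- amp_sched[k_idx]
    amp <- pmax(10, rnorm(tot, mu, config$sw_amp_sd_frac * mu))
    slot <- EPOCH_S / n_per[k_idx]
    jit <- runif(tot, 0, pmax(0, slot - 2.5 * d - 1 / config$fs))
    zc1 <- (nrem_epochs[k_idx] - 1) * EPOCH_S + (within - 1) * slot + jit
    waves[[ch]] <- tibble(
      epoch_index = nrem_epochs[k_idx], nrem_order = k_idx,
      zc1_s = zc1, peak_s = zc1 + d / 2, peak_amp_uv = amp,
      zc2_s = zc1 + d, slope_uv_per_s = amp / (d / 2)
    )
  }
  waves <- dplyr::bind_rows(waves, .id = "channel")

  ## spikes: homogeneous Poisson per channel over the epoched span
  spikes <- purrr::map(config$spike_rate_hz[eeg_ch], function(rate) {
    n_s <- rpois(1L, rate * dur)
    if (n_s == 0L) return(tibble(time_s = numeric(0)))
    tibble(time_s = sort(runif(n_s, 1, dur - 1)))
  })
  spikes <- dplyr::bind_rows(spikes, .id = "channel")

  ## spindle onsets in N2 epochs (shared draw so rendering is optional)
  n2_epochs <- if ("stage" %in% names(hyp)) hyp$epoch_index[hyp$stage == "N2"] else integer(0)
  n_sp <- rpois(length(n2_epochs), config$spindle_density)
  spindles <- tibble(
    time_s = rep((n2_epochs - 1) * EPOCH_S, times = n_sp) +
      runif(sum(n_sp), 0, EPOCH_S - 1.1))

  structure(
    list(hypnogram = hyp,
         spikes = spikes,
         waves = waves,
         spindles = spindles,
         injected_somnidex = config$slope_decline_frac,
         insertion_counts = NULL),
    class = "sim_ground_truth"
  )
}

render_sim_signal <- function(config, hyp, gt) {
  fs <- config$fs
  n <- floor(config$duration_s / EPOCH_S) * EPOCH_S * fs
  labs <- config$channel_labels
  sig <- matrix(0, nrow = length(labs), ncol = n, dimnames = list(labs, NULL))

  counts <- tibble(channel = labs, n_spikes = 0L, n_waves = 0L)

  for (ci in seq_along(labs)) {
    ch <- labs[ci]
    mastoid <- ch %in% c("M1", "M2")
    x <- pink_noise(n, config$noise_scale_uv * (if (mastoid) 0.5 else 1))
    if (!mastoid) {
      ## slow oscillations
      w_ch <- gt$waves[gt$waves$channel == ch, ]
      for (i in seq_len(nrow(w_ch))) {
        d <- w_ch$zc2_s[i] - w_ch$zc1_s[i]
        wf <- synth_slow_wave(w_ch$peak_amp_uv[i], d, fs)$samples
        i0 <- round(w_ch$zc1_s[i] * fs)
        idx <- i0 + seq_along(wf)
        idx <- idx[idx >= 1 & idx <= n]
        x[idx] <- x[idx] + wf[seq_along(idx)]
      }
      ## spikes (apex-aligned)
      s_ch <- gt$spikes$time_s[gt$spikes$channel == ch]
      if (length(s_ch)) {
        sp <- synth_spike(config$spike_amp_uv, fs)
        for (t in s_ch) {
          i0 <- round(t * fs) - sp$apex_index
          idx <- i0 + seq_along(sp$samples)
          idx <- idx[idx >= 1 & idx <= n]
          x[idx] <- x[idx] + sp$samples[seq_along(idx)]
        }
      }
      ## spindles
      if (nrow(gt$spindles)) {
        spin <- synth_spindle(fs)
        for (t in gt$spindles$time_s) {
          i0 <- round(t * fs)
          idx <- i0 + seq_along(spin)
          idx <- idx[idx >= 1 & idx <= n]
          x[idx] <- x[idx] + spin[seq_along(idx)] * runif(1, 0.8, 1.2)
        }
      }
      ## wake alpha
      w_ep <- hyp$epoch_index[hyp$stage == "W"]
      for (e in w_ep) {
        idx <- ((e - 1) * EPOCH_S * fs + 1):(e * EPOCH_S * fs)
        t <- (idx - 1) / fs
        x[idx] <- x[idx] + 25 * sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
      }
      counts$n_spikes[counts$channel == ch] <- length(s_ch)
      counts$n_waves[counts$channel == ch] <- nrow(w_ch)
    }
    sig[ci, ] <- x
  }
  rec <- eeg_recording(sig, fs, labs)
  attr(rec, "insertion_counts") <- counts
  rec
}

#' @export
print.sim_recording <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<sim_recording> %.2f h, %d NREM2/3 epochs, %d slow waves, %d spikes\n",
              x$config$duration_s / 3600, sum(nrem_mask(gt$hypnogram)),
              nrow(gt$waves), nrow(gt$spikes)))
  if (!is.null(x$recording)) print(x$recording)
  invisible(x)
}

#' Ground-truth overnight slope change of a simulation
#'
#' Relative change of the mean analytic ascending slope between the first and
#' last `n_epochs` NREM2/3 epochs (chronological NREM order) of a simulated
#' recording's wave inventory, on a single channel.
#'
#' @param gt a `sim_ground_truth` (from [simulate_recording()]).
#' @param channel channel label; defaults to the first wave-bearing channel.
#' @param n_epochs NREM epochs per hour-set (default 180 = 1 h).
#' @return the relative slope change `(LH - FH) / FH`.
#' @export
gt_slope_change <- function(gt, channel = NULL, n_epochs = 180L) {
  w <- gt$waves
  channel <- channel %||% w$channel[1]
  w <- w[w$channel == channel, ]
  n_nrem <- max(w$nrem_order)
  n_epochs <- min(n_epochs, floor(n_nrem / 2))
  fh <- w$slope_uv_per_s[w$nrem_order <= n_epochs]
  lh <- w$slope_uv_per_s[w$nrem_order > n_nrem - n_epochs]
  (mean(lh) - mean(fh)) / mean(fh)
}
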