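#' Select first-hour and last-hour NREM epochs
#'
#' The first hour (FH) is the chronologically first `n_epochs` NREM2/3 epochs
#' and the last hour (LH) the last `n_epochs`, regardless of contiguity. The
#' two sets must be disjoint, which requires at least `2 * n_epochs` NREM2/3
#' epochs.
#'
#' @param hypnogram a hypnogram tibble (binary `label` or 5-stage `stage`).
#' @param n_epochs epochs per hour-set (default 180 x 20 s = 1 h).
#' @return A list with `fh` and `lh` (epoch indices) and
#'   `insufficient_nrem` flag (when flagged, `fh`/`lh` are `NULL`).
#' @export
select_fh_lh <- function(hypnogram, n_epochs = 180L) {
  nrem <- hypnogram$epoch_index[nrem_mask(hypnogram)]
  if (length(nrem) < 2L * n_epochs) {
    return(list(fh = NULL, lh = NULL, insufficient_nrem = TRUE,
                n_nrem = length(nrem)))
  }
  list(fh = nrem[seq_len(n_epochs)],
       lh = nrem[seq(length(nrem) - n_epochs + 1L, length(nrem))],
       insufficient_nrem = FALSE, n_nrem = length(nrem))
}

#' Waves whose negative peak falls inside any of the given 20-s epochs
#' @param waves wave tibble from [detect_slow_waves()].
#' @param epoch_indices 1-based epoch indices.
#' @return The subset of `waves`.
#' @export
waves_in_epochs <- function(waves, epoch_indices) {
  ep <- floor(waves$peak_s / EPOCH_S) + 1L
  waves[ep %in% epoch_indices, ]
}

#' Overnight slope change (SOMNIDEX) from matched wave sets
#'
#' FH and LH are summarized as the mean (or median) ascending slope of the
#' matched waves; the index is `(LH - FH) / FH`, negative for the expected
#' overnight slope decline.
#'
#' @param matched a `matched_waves` object from [amplitude_match()].
#' @param summary `"mean"` (default) or `"median"`.
#' @param min_matched minimum matched waves per side.
#' @return A list with `fh_mean_slope_uv_per_s`, `lh_mean_slope_uv_per_s`,
#'   `somnidex`, `n_matched`, `insufficient_matched_waves`.
#' @export
compute_somnidex <- function(matched, summary = c("mean", "median"),
                             min_matched = 250L) {
  summary <- match.arg(summary)
  if (matched$n_matched < min_matched) {
    return(list(fh_mean_slope_uv_per_s = NA_real_,
                lh_mean_slope_uv_per_s = NA_real_,
                somnidex = NA_real_, n_matched = matched$n_matched,
                insufficient_matched_waves = TRUE))
  }
  f <- switch(summary, mean = mean, median = median)
  fh <- f(matched$fh$slope_uv_per_s)
  lh <- f(matched$lh$slope_uv_per_s)
  list(fh_mean_slope_uv_per_s = fh, lh_mean_slope_uv_per_s = lh,
       somnidex = (lh - fh) / fh, n_matched = matched$n_matched,
       insufficient_matched_waves = FALSE)
}

#' Classify the overnight slope change
#'
#' @param somnidex the overnight relative slope change.
#' @param cutoff symmetric cutoff `c`: `decrease` below `-c`, `increase`
#'   above `+c`, otherwise `no_change`.
#' @return `"decrease"`, `"no_change"` or `"increase"`.
#' @export
classify_change <- function(somnidex, cutoff = 0.025) {
  if (!is.finite(somnidex)) return(NA_character_)
  if (somnidex < -cutoff) "decrease"
  else if (somnidex > cutoff) "increase"
  else "no_change"
}

#' Screen a recording for eligibility
#'
#' A recording qualifies for overnight slope analysis when it lasts at least
#' 4 h and its (detected) hypnogram contains at least `2 * 180` NREM2/3
#' epochs, the minimum for disjoint first/last-hour selection and this
#' pipeline's proxy for "at least 4 h of sleep".
#'
#' @param rec an [eeg_recording()] (or a duration in seconds).
#' @param hypnogram hypnogram tibble for the recording.
#' @param min_duration_h minimum recording duration, hours.
#' @param min_nrem_epochs minimum NREM2/3 epoch count.
#' @return A list with `duration_ok`, `nrem_ok`, `eligible`.
#' @export
screen_recording <- function(rec, hypnogram, min_duration_h = 4,
                             min_nrem_epochs = 360L) {
  dur <- if (inherits(rec, "eeg_recording")) duration_s(rec) else rec
  duration_ok <- dur >= min_duration_h * 3600
  nrem_ok <- sum(nrem_mask(hypnogram)) >= min_nrem_epochs
  list(duration_ok = duration_ok, nrem_ok = nrem_ok,
       eligible = duration_ok && nrem_ok)
}
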