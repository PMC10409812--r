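#' Write a simulated recording with ground-truth sidecars
#'
#' Writes the recording to `recording.edf` plus two plain-text sidecars:
#' `hypnogram.csv` (`epoch_index,stage`) and `events.csv` (`channel,time_s,`
#' `type` with `zc1_s,peak_s,zc2_s,peak_amp_uv,slope_uv_per_s` filled for
#' slow waves).
#'
#' @param sim a `sim_recording` from [simulate_recording()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (is.null(sim$recording)) abort("simulation was not rendered; nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edf(sim$recording, file.path(dir, "recording.edf"))
  gt <- sim$ground_truth
  utils::write.csv(gt$hypnogram, file.path(dir, "hypnogram.csv"),
                   row.names = FALSE)
  ev <- dplyr::bind_rows(
    dplyr::mutate(gt$spikes, type = "spike",
                  zc1_s = NA_real_, peak_s = NA_real_, zc2_s = NA_real_,
                  peak_amp_uv = NA_real_, slope_uv_per_s = NA_real_),
    dplyr::transmute(gt$waves, channel = .data$channel,
                     time_s = .data$peak_s, type = "slow_wave",
                     zc1_s = .data$zc1_s, peak_s = .data$peak_s,
                     zc2_s = .data$zc2_s, peak_amp_uv = .data$peak_amp_uv,
                     slope_uv_per_s = .data$slope_uv_per_s)
  )
  ev <- dplyr::arrange(ev, .data$channel, .data$time_s)
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a hypnogram CSV
#' @param path CSV with `epoch_index` and `stage` (5-stage) or `label`
#'   (binary) columns.
#' @return A hypnogram tibble.
#' @export
read_hypnogram_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("stage" %in% names(df)) {
    df$stage <- factor(df$stage, levels = c("W", "N1", "N2", "N3", "REM"))
  }
  structure(df, class = c("hypnogram", class(tibble())))
}

#' Read an events CSV
#' @param path CSV written by [write_simulation()] or [detect_spikes()].
#' @return A tibble of events.
#' @export
read_events_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
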