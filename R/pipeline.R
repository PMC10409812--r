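#' Pipeline configuration
#'
#' One validated document of every tunable parameter of the automated
#' pipeline. Unknown keys are rejected; every key has a default.
#'
#' @param bandpass preprocessing bandpass edges, Hz.
#' @param notch_hz mains notch frequency, Hz.
#' @param sw_band slow-wave pass-band, Hz.
#' @param sw_stop slow-wave stop-band edges, Hz.
#' @param sw_stop_atten_db slow-wave stop-band attenuation, dB.
#' @param post_spike_window_s exclusion window after each spike, seconds.
#' @param post_spike_rule `"overlap"` or `"peak"`.
#' @param match_bin_uv amplitude-matching bin width, uV.
#' @param match_seed seed for matching subsampling.
#' @param min_matched minimum matched waves per hour-set.
#' @param fh_epochs NREM epochs per hour-set (180 = 1 h).
#' @param somnidex_cutoff category cutoff for [classify_change()].
#' @param slope_summary `"mean"` or `"median"` hourly slope summary.
#' @param min_amp_uv slow-wave amplitude floor, uV (0 = none).
#' @param spike_threshold spike posterior threshold (`NULL`: model default).
#' @param sleep_channels feature channels for the sleep detector.
#' @param min_duration_h screening: minimum recording duration, hours.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bandpass = c(0.3, 40), notch_hz = 50,
                            sw_band = c(0.5, 4.0), sw_stop = c(0.1, 10),
                            sw_stop_atten_db = 40,
                            post_spike_window_s = 0.5,
                            post_spike_rule = "overlap",
                            match_bin_uv = 10, match_seed = 1L,
                            min_matched = 250L, fh_epochs = 180L,
                            somnidex_cutoff = 0.025,
                            slope_summary = "mean", min_amp_uv = 0,
                            spike_threshold = NULL,
                            sleep_channels = c("F3", "C3", "O1"),
                            min_duration_h = 4) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config", hash = rlang::hash(cfg))
}

#' Run the full automated pipeline on one recording
#'
#' Preprocess, detect spikes on all channels, compute the SWI and focus
#' channel, detect NREM2/3 sleep, screen the recording, run the slow-wave
#' analysis on the focus channel (filter, detect, post-spike exclusion,
#' first/last-hour amplitude matching) and compute the overnight slope
#' change. Any stage failure produces a flagged report, never an error.
#'
#' @param input an EDF path, an [eeg_recording()], or a `sim_recording`.
#' @param spike_net,sleep_net trained models ([train_spike_net()],
#'   [train_sleep_net()]).
#' @param config a [pipeline_config()].
#' @param preprocessed set `TRUE` when `input` is already filtered,
#'   re-referenced and at 128 Hz.
#' @return A list of class `somnidex_report`.
#' @export
run_single <- function(input, spike_net, sleep_net,
                       config = pipeline_config(), preprocessed = FALSE) {
  report <- list(
    somnidex = NA_real_, fh_mean_slope_uv_per_s = NA_real_,
    lh_mean_slope_uv_per_s = NA_real_, n_matched = NA_integer_,
    swi_percent = NA_real_, focus_channel = NA_character_,
    category = NA_character_, duration_h = NA_real_,
    n_nrem_epochs = NA_integer_, n_spikes_focus = NA_integer_,
    exclusion_flags = character(0), error = NA_character_,
    provenance = list(config_hash = attr(config, "hash"),
                      spike_model_seed = spike_net$seed,
                      sleep_model_seed = sleep_net$seed,
                      match_seed = config$match_seed)
  )
  fail <- function(rep, flag, msg = NA_character_) {
    rep$exclusion_flags <- union(rep$exclusion_flags, flag)
    if (!is.na(msg)) rep$error <- msg
    structure(rep, class = "somnidex_report")
  }

  res <- tryCatch({
    rec <- if (is.character(input)) read_edf(input)
           else if (inherits(input, "sim_recording")) input$recording
           else input
    if (!preprocessed) rec <- preprocess_recording(rec, config$bandpass,
                                                   config$notch_hz)
    report$duration_h <- duration_s(rec) / 3600

    spikes <- detect_spikes(rec, spike_net, threshold = config$spike_threshold)

    feats <- spectral_features(rec, spikes, channels = config$sleep_channels)
    feats <- normalize_features(feats)
    hyp <- predict_sleep(sleep_net, feats)
    report$n_nrem_epochs <- sum(nrem_mask(hyp))

    swi <- compute_swi(spikes, hyp,
                       channels = setdiff(rec$channel_labels, c("M1", "M2")))
    report$focus_channel <- swi$focus_channel
    report$swi_percent <-
      swi$per_channel$swi_percent[swi$per_channel$channel == swi$focus_channel]

    scr <- screen_recording(rec, hyp, min_duration_h = config$min_duration_h,
                            min_nrem_epochs = 2L * config$fh_epochs)
    if (!scr$eligible) return(fail(report, "screening_failed"))

    sel <- select_fh_lh(hyp, config$fh_epochs)
    if (sel$insufficient_nrem) return(fail(report, "insufficient_nrem"))

    x <- sw_filter(channel_signal(rec, swi$focus_channel), rec$fs,
                   band = config$sw_band, stop = config$sw_stop,
                   rs = config$sw_stop_atten_db)
    waves <- detect_slow_waves(x, rec$fs, min_amp_uv = config$min_amp_uv)
    sp_focus <- spikes$time_s[spikes$channel == swi$focus_channel]
    report$n_spikes_focus <- length(sp_focus)
    waves <- exclude_post_spike(waves, sp_focus,
                                window_s = config$post_spike_window_s,
                                rule = config$post_spike_rule)

    fh_w <- waves_in_epochs(waves, sel$fh)
    lh_w <- waves_in_epochs(waves, sel$lh)
    if (!nrow(fh_w) || !nrow(lh_w)) {
      return(fail(report, "insufficient_matched_waves"))
    }
    matched <- amplitude_match(fh_w, lh_w, bin_width_uv = config$match_bin_uv,
                               seed = config$match_seed,
                               min_matched = config$min_matched)
    sx <- compute_somnidex(matched, summary = config$slope_summary,
                           min_matched = config$min_matched)
    if (sx$insufficient_matched_waves) {
      report$n_matched <- sx$n_matched
      return(fail(report, "insufficient_matched_waves"))
    }
    report$fh_mean_slope_uv_per_s <- sx$fh_mean_slope_uv_per_s
    report$lh_mean_slope_uv_per_s <- sx$lh_mean_slope_uv_per_s
    report$somnidex <- sx$somnidex
    report$n_matched <- sx$n_matched
    report$category <- classify_change(sx$somnidex, config$somnidex_cutoff)
    structure(report, class = "somnidex_report")
  }, error = function(e) fail(report, "error", conditionMessage(e)))
  res
}

#' @export
print.somnidex_report <- function(x, ...) {
  cat("<somnidex_report>\n")
  if (length(x$exclusion_flags)) {
    cat("  EXCLUDED:", paste(x$exclusion_flags, collapse = ", "), "\n")
    if (!is.na(x$error)) cat("  error:", x$error, "\n")
  }
  cat(sprintf("  focus %s | SWI %.2f%% | NREM epochs %s | matched waves %s\n",
              x$focus_channel, x$swi_percent,
              format(x$n_nrem_epochs), format(x$n_matched)))
  if (!is.na(x$somnidex)) {
    cat(sprintf("  FH %.1f -> LH %.1f uV/s | SOMNIDEX %+.4f (%s)\n",
                x$fh_mean_slope_uv_per_s, x$lh_mean_slope_uv_per_s,
                x$somnidex, x$category))
  }
  invisible(x)
}

#' Write a per-recording JSON report
#' @param report a `somnidex_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Run the pipeline over a cohort
#'
#' Applies [run_single()] to every recording; a failure in one recording
#' flags its row and never aborts the batch. Cohort statistics follow the
#' study design: Spearman correlation of the overnight slope change with the
#' SWI, category proportions, and (when an `age` column is supplied)
#' age correlations with FH/LH slopes and the slope change.
#'
#' @param inputs list of EDF paths / recordings / `sim_recording`s.
#' @param spike_net,sleep_net trained models.
#' @param config a [pipeline_config()].
#' @param ids optional recording identifiers.
#' @param age optional numeric age (years) per recording.
#' @param preprocessed passed to [run_single()].
#' @return A list of class `cohort_result`: `table` (one row per recording),
#'   `reports`, `correlations`, `category_proportions`.
#' @export
run_cohort <- function(inputs, spike_net, sleep_net,
                       config = pipeline_config(), ids = NULL, age = NULL,
                       preprocessed = FALSE) {
  if (!length(inputs)) abort("no recordings")
  ids <- ids %||% sprintf("rec%03d", seq_along(inputs))
  reports <- purrr::map(inputs, function(inp) {
    tryCatch(run_single(inp, spike_net, sleep_net, config,
                        preprocessed = preprocessed),
             error = function(e) {
               structure(list(somnidex = NA_real_, exclusion_flags = "error",
                              error = conditionMessage(e)),
                         class = "somnidex_report")
             })
  })
  names(reports) <- ids
  tab <- purrr::map(reports, tidy_report_row)
  tab <- dplyr::bind_rows(tab, .id = "id")
  if (!is.null(age)) tab$age <- age

  ok <- is.finite(tab$somnidex)
  correlations <- list()
  if (sum(ok) >= 3 && sd(tab$swi_percent[ok]) > 0 && sd(tab$somnidex[ok]) > 0) {
    correlations$somnidex_vs_swi <-
      spearman_cor(tab$somnidex[ok], tab$swi_percent[ok])
  }
  if (!is.null(age) && sum(ok) >= 3) {
    correlations$age_vs_fh_slope <-
      spearman_cor(tab$age[ok], tab$fh_mean_slope_uv_per_s[ok])
    correlations$age_vs_lh_slope <-
      spearman_cor(tab$age[ok], tab$lh_mean_slope_uv_per_s[ok])
    correlations$age_vs_somnidex <- spearman_cor(tab$age[ok], tab$somnidex[ok])
  }
  props <- table(factor(tab$category[ok],
                        levels = c("decrease", "no_change", "increase")))
  props <- as.list(props / max(1, sum(props)))

  structure(list(table = tab, reports = reports,
                 correlations = correlations,
                 category_proportions = props),
            class = "cohort_result")
}

tidy_report_row <- function(r) {
  tibble(
    somnidex = r$somnidex %||% NA_real_,
    fh_mean_slope_uv_per_s = r$fh_mean_slope_uv_per_s %||% NA_real_,
    lh_mean_slope_uv_per_s = r$lh_mean_slope_uv_per_s %||% NA_real_,
    n_matched = r$n_matched %||% NA_integer_,
    swi_percent = r$swi_percent %||% NA_real_,
    focus_channel = r$focus_channel %||% NA_character_,
    category = r$category %||% NA_character_,
    duration_h = r$duration_h %||% NA_real_,
    n_nrem_epochs = r$n_nrem_epochs %||% NA_integer_,
    excluded = length(r$exclusion_flags) > 0,
    exclusion_flags = paste(r$exclusion_flags, collapse = ";")
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d recordings, %d with SOMNIDEX\n",
              nrow(x$table), sum(is.finite(x$table$somnidex))))
  if (!is.null(x$correlations$somnidex_vs_swi)) {
    r <- x$correlations$somnidex_vs_swi
    cat(sprintf("  Spearman rho(somnidex, SWI) = %.3f (p = %.3g)\n",
                r$rho, r$p_value))
  }
  cat(sprintf("  categories: decrease %.0f%%, no_change %.0f%%, increase %.0f%%\n",
              100 * x$category_proportions$decrease,
              100 * x$category_proportions$no_change,
              100 * x$category_proportions$increase))
  invisible(x)
}
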