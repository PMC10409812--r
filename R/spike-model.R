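#' Spike-detector configuration
#'
#' Window classifier over the raw (preprocessed) signal: non-overlapping
#' 16-sample windows at 128 Hz (125 ms, step 125 ms), two LSTM layers with
#' dropout, softmax over spike / no-spike, Adam, six training epochs.
#'
#' @param window_samples samples per window.
#' @param lstm_units hidden units per LSTM layer (two layers).
#' @param dropout_p dropout probability.
#' @param training_epochs passes over the training data.
#' @param decision_threshold posterior threshold for the spike class.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed.
#' @return A list of class `spike_net_config`.
#' @export
spike_net_config <- function(window_samples = 16L, lstm_units = c(128L, 128L),
                             dropout_p = 0.1, training_epochs = 6L,
                             decision_threshold = 0.5, lr = 2e-3,
                             batch_size = 256L, seed = 1L) {
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    abort("`decision_threshold` must lie in (0, 1)")
  }
  if (dropout_p < 0 || dropout_p >= 1) abort("`dropout_p` must lie in [0, 1)")
  structure(list(window_samples = as.integer(window_samples),
                 lstm_units = as.integer(lstm_units), dropout_p = dropout_p,
                 training_epochs = as.integer(training_epochs),
                 decision_threshold = decision_threshold, lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "spike_net_config")
}

#' Cut a channel into classifier windows
#'
#' Standardizes the signal per recording (subtract median, divide by IQR, so
#' amplitude conventions across devices cancel) and cuts consecutive
#' non-overlapping windows of `window_samples` samples; the trailing partial
#' window is dropped. At 128 Hz the default window is 125 ms with step
#' 125 ms.
#'
#' @param x single-channel numeric signal, uV (128 Hz).
#' @param fs sampling rate, Hz.
#' @param window_samples samples per window.
#' @return A list with `windows` (matrix `n x window_samples`), `start_s`
#'   (window start times) and `step_s`.
#' @export
make_windows <- function(x, fs = 128, window_samples = 16L) {
  n_win <- floor(length(x) / window_samples)
  if (n_win == 0L) {
    warn("signal shorter than one window; returning empty window set")
    return(list(windows = matrix(numeric(0), 0, window_samples),
                start_s = numeric(0), step_s = window_samples / fs))
  }
  iqr <- diff(quantile(x, c(0.25, 0.75), names = FALSE))
  z <- (x - median(x)) / max(iqr, 1e-9)
  w <- matrix(z[seq_len(n_win * window_samples)], nrow = n_win,
              ncol = window_samples, byrow = TRUE)
  list(windows = w,
       start_s = (seq_len(n_win) - 1) * window_samples / fs,
       step_s = window_samples / fs)
}

#' Label windows from annotated spike times
#'
#' A window is positive iff any annotated spike time falls in
#' `[start, start + step)` (half-open).
#'
#' @param start_s window start times from [make_windows()].
#' @param spike_times sorted annotated spike times, seconds.
#' @param step_s window duration, seconds.
#' @return Integer vector of 0/1 labels.
#' @export
label_windows <- function(start_s, spike_times, step_s = 0.125) {
  if (!length(spike_times)) return(integer(length(start_s)))
  sp <- sort(spike_times)
  cnt <- findInterval(start_s + step_s - 1e-12, sp) - findInterval(start_s - 1e-12, sp)
  as.integer(cnt > 0)
}

windows_to_array <- function(w) {
  array(w, dim = c(nrow(w), ncol(w), 1L))
}

#' Train the spike-detection LSTM
#'
#' @param windows,labels training windows (matrix from [make_windows()]) and
#'   0/1 labels.
#' @param val_windows,val_labels held-out validation windows/labels (from
#'   different patients than the training windows).
#' @param config a [spike_net_config()].
#' @param n_restarts number of independently initialised trainings (seeds
#'   `seed, seed + 1000, ...`); the candidate with the best final validation
#'   kappa is kept. LSTM training lands in poor optima for some
#'   initialisations, and selecting on validation data is the standard remedy.
#' @return An `lstm_net` tagged for spike detection.
#' @export
train_spike_net <- function(windows, labels, val_windows = NULL,
                            val_labels = NULL, config = spike_net_config(),
                            n_restarts = 1L) {
  nets <- lapply(seq_len(n_restarts), function(k) {
    train_lstm(
      windows_to_array(windows), labels + 1L,
      x_val = if (!is.null(val_windows)) windows_to_array(val_windows),
      y_val = if (!is.null(val_labels)) val_labels + 1L,
      layer_sizes = config$lstm_units, n_classes = 2,
      epochs = config$training_epochs, dropout_p = config$dropout_p,
      lr = config$lr, batch_size = config$batch_size,
      seed = config$seed + 1000L * (k - 1L))
  })
  net <- nets[[select_best_net(nets)]]
  net$task <- "spike"
  net$decision_threshold <- config$decision_threshold
  net
}

# index of the candidate with the best final validation kappa (falls back to
# the lowest training loss when no validation data was supplied)
select_best_net <- function(nets) {
  score <- vapply(nets, function(n) {
    vk <- tail(n$history$val_kappa, 1)
    if (length(vk) && is.finite(vk)) vk else -tail(n$history$train_loss, 1)
  }, numeric(1))
  which.max(score)
}

#' Merge supra-threshold windows into spike events
#'
#' Maximal runs of consecutive windows with posterior above the threshold
#' become one event at the midpoint of the covered time span, carrying the
#' mean posterior of its windows.
#'
#' @param posterior spike-class posterior per window.
#' @param start_s window start times.
#' @param threshold decision threshold.
#' @param step_s window duration, seconds.
#' @return A tibble with `time_s`, `posterior`, `n_windows`.
#' @export
windows_to_events <- function(posterior, start_s, threshold = 0.5,
                              step_s = 0.125) {
  hit <- posterior >= threshold
  if (!any(hit)) {
    return(tibble(time_s = numeric(0), posterior = numeric(0),
                  n_windows = integer(0)))
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  tibble(
    time_s = (start_s[starts[runs]] + start_s[ends[runs]] + step_s) / 2,
    posterior = vapply(runs, function(i)
      mean(posterior[starts[i]:ends[i]]), numeric(1)),
    n_windows = r$lengths[runs]
  )
}

#' Detect spikes on every channel of a recording
#'
#' Applies the trained window classifier channel by channel and converts
#' window posteriors to events.
#'
#' @param rec a preprocessed [eeg_recording()] at 128 Hz.
#' @param net trained spike `lstm_net`.
#' @param threshold decision threshold (defaults to the model's).
#' @param channels channels to scan (default: all but the mastoids).
#' @return A `spike_events` tibble: `channel`, `time_s`, `posterior`.
#' @export
detect_spikes <- function(rec, net, threshold = NULL, channels = NULL) {
  threshold <- threshold %||% net$decision_threshold %||% 0.5
  channels <- channels %||% setdiff(rec$channel_labels, c("M1", "M2"))
  ev <- purrr::map(setNames(channels, channels), function(ch) {
    w <- make_windows(channel_signal(rec, ch), rec$fs)
    if (!nrow(w$windows)) return(tibble(time_s = numeric(0), posterior = numeric(0)))
    post <- predict_lstm(net, windows_to_array(w$windows))[, 2]
    windows_to_events(post, w$start_s, threshold, w$step_s)[, c("time_s", "posterior")]
  })
  out <- dplyr::bind_rows(ev, .id = "channel")
  class(out) <- c("spike_events", class(out))
  out
}

#' Spike-wave index per channel and focus-channel selection
#'
#' Splits every NREM2/3 epoch into two 10-s intervals and reports, per
#' channel, the percentage of NREM intervals containing at least one spike
#' (the SWI) plus the raw mean spike count per 10-s interval. The focus
#' channel is the SWI argmax, ties broken by the order of `channels`.
#'
#' @param events spike events tibble (`channel`, `time_s`).
#' @param hypnogram hypnogram tibble aligned to the recording's 20-s grid.
#' @param channels channel order for reporting and tie-breaks (default:
#'   order of appearance in `events`).
#' @return A list of class `swi_result`: `per_channel` tibble
#'   (`channel`, `swi_percent`, `spikes_per_10s`), `n_intervals`,
#'   `focus_channel`, `interval_len_s`.
#' @export
compute_swi <- function(events, hypnogram, channels = NULL) {
  channels <- channels %||% unique(events$channel)
  nrem_ep <- hypnogram$epoch_index[nrem_mask(hypnogram)]
  if (!length(nrem_ep)) abort("no NREM2/3 epochs: SWI undefined")
  # interval starts: two 10-s halves per NREM epoch
  int_start <- sort(c((nrem_ep - 1) * EPOCH_S, (nrem_ep - 1) * EPOCH_S + 10))
  n_int <- length(int_start)
  per <- purrr::map(setNames(channels, channels), function(ch) {
    t <- events$time_s[events$channel == ch]
    if (!length(t)) return(tibble(swi_percent = 0, spikes_per_10s = 0))
    cnt <- findInterval(int_start + 10 - 1e-12, sort(t)) -
      findInterval(int_start - 1e-12, sort(t))
    tibble(swi_percent = 100 * mean(cnt > 0), spikes_per_10s = mean(cnt))
  })
  per <- dplyr::bind_rows(per, .id = "channel")
  focus <- per$channel[which.max(per$swi_percent)]
  structure(list(per_channel = per, n_intervals = n_int,
                 interval_len_s = 10, focus_channel = focus),
            class = "swi_result")
}

#' @export
print.swi_result <- function(x, ...) {
  cat(sprintf("<swi_result> focus channel %s over %d NREM 10-s intervals\n",
              x$focus_channel, x$n_intervals))
  print(x$per_channel)
  invisible(x)
}
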