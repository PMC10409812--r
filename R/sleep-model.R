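#' Sleep-detector configuration
#'
#' Epoch classifier on spectral band-power features: two LSTM layers over an
#' 11-epoch context window (220 s, step one epoch), dropout, softmax over
#' NREM2/3 vs other, twenty training epochs.
#'
#' @param lstm_units hidden units per LSTM layer.
#' @param dropout_p dropout probability.
#' @param training_epochs passes over the training data.
#' @param context_epochs sequence length in 20-s epochs (odd, label at the
#'   center).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed.
#' @return A list of class `sleep_net_config`.
#' @export
sleep_net_config <- function(lstm_units = c(64L, 64L), dropout_p = 0.1,
                             training_epochs = 20L, context_epochs = 11L,
                             lr = 5e-3, batch_size = 64L, seed = 1L) {
  if (context_epochs %% 2L == 0L) {
    abort("`context_epochs` must be odd so the center epoch is well-defined")
  }
  structure(list(lstm_units = as.integer(lstm_units), dropout_p = dropout_p,
                 training_epochs = as.integer(training_epochs),
                 context_epochs = as.integer(context_epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "sleep_net_config")
}

sleep_bands <- list(alpha = c(8, 12), sigma = c(12, 16),
                    delta = c(0.75, 4.5), artifact = c(30, 40))
sleep_channels_default <- c("F3", "C3", "O1")

# Tukey (tapered cosine) window, taper ratio r
tukey_window <- function(n, r = 0.5) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < r / 2
  hi <- t > 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(2 * pi / r * (t[lo] - r / 2)))
  w[hi] <- 0.5 * (1 + cos(2 * pi / r * (t[hi] - 1 + r / 2)))
  w
}

# one-sided periodogram with taper, normalised so the sum over bins
# approximates the signal variance (Parseval); returns power per 0.25 Hz bin
tapered_periodogram <- function(x, w) {
  n <- length(x)
  X <- fft(x * w)
  p <- Mod(X)^2 / (n * sum(w^2) / n)
  half <- n %/% 2
  one <- p[1:(half + 1)]
  one[2:half] <- 2 * one[2:half]
  one / n
}

band_bins <- function(freqs, band, name) {
  # alpha/sigma: lower-edge inclusive, upper exclusive (12 Hz is sigma only);
  # delta and artifact include both edges
  if (name %in% c("alpha", "sigma")) {
    freqs >= band[1] & freqs < band[2]
  } else {
    freqs >= band[1] & freqs <= band[2]
  }
}

#' Spectral band-power features per 20-s epoch
#'
#' For each complete 20-s epoch and each of the channels (already referenced
#' against the contralateral mastoid by preprocessing), the five consecutive
#' 4-s sub-epochs are tapered with a Tukey (r = 0.5) window and
#' periodogram-averaged to 0.25 Hz resolution; band powers are the sums over
#' alpha (8-12 Hz), sigma (12-16 Hz), delta (0.75-4.5 Hz) and artifact
#' (30-40 Hz) bins. Sub-epochs overlapping a detected spike (+/- `margin_s`)
#' on any feature channel are excluded before averaging; an epoch with no
#' valid sub-epoch is flagged invalid.
#'
#' @param rec a preprocessed [eeg_recording()] at 128 Hz.
#' @param spikes spike events tibble (or `NULL` for none).
#' @param channels the three feature channels.
#' @param margin_s exclusion margin around spike times, seconds.
#' @return A tibble with `epoch_index`, `n_valid_subepochs`, `valid` and 12
#'   feature columns `<channel>_<band>` (uV^2).
#' @export
spectral_features <- function(rec, spikes = NULL,
                              channels = sleep_channels_default,
                              margin_s = 0.25) {
  if (rec$fs != 128) abort("features are defined at 128 Hz; preprocess first")
  missing <- setdiff(channels, rec$channel_labels)
  if (length(missing)) {
    abort(sprintf("required channel(s) absent: %s", paste(missing, collapse = ", ")))
  }
  grid <- epoch_grid(rec)
  n_ep <- nrow(grid)
  sub_len <- 4 * rec$fs
  w <- tukey_window(sub_len, 0.5)
  freqs <- (seq_len(sub_len %/% 2 + 1) - 1) / 4  # 0.25 Hz bins
  bins <- purrr::imap(sleep_bands, ~ band_bins(freqs, .x, .y))

  spike_times <- sort(unique(
    if (!is.null(spikes) && nrow(spikes)) spikes$time_s[spikes$channel %in% channels]
    else numeric(0)))

  # validity per (epoch, sub-epoch): no spike within [s0 - margin, s0 + 4 + margin)
  sub_start <- rep((grid$epoch_index - 1) * EPOCH_S, each = 5) +
    rep(0:4 * 4, times = n_ep)
  if (length(spike_times)) {
    n_in <- findInterval(sub_start + 4 + margin_s - 1e-12, spike_times) -
      findInterval(sub_start - margin_s - 1e-12, spike_times)
    sub_ok <- n_in == 0L
  } else {
    sub_ok <- rep(TRUE, length(sub_start))
  }
  sub_ok <- matrix(sub_ok, nrow = 5)  # sub-epoch x epoch

  feat <- matrix(0, n_ep, 4 * length(channels))
  colnames(feat) <- as.vector(outer(names(sleep_bands), channels,
                                    function(b, ch) paste(ch, b, sep = "_")))
  for (ch in channels) {
    x <- channel_signal(rec, ch)
    for (e in seq_len(n_ep)) {
      ok <- which(sub_ok[, e])
      if (!length(ok)) next
      acc <- numeric(length(freqs))
      for (s in ok) {
        i0 <- grid$start_sample[e] + (s - 1) * sub_len
        acc <- acc + tapered_periodogram(x[i0:(i0 + sub_len - 1)], w)
      }
      spec <- acc / length(ok)
      for (b in names(sleep_bands)) {
        feat[e, paste(ch, b, sep = "_")] <- sum(spec[bins[[b]]])
      }
    }
  }
  out <- tibble(epoch_index = grid$epoch_index,
                n_valid_subepochs = colSums(sub_ok))
  out <- dplyr::bind_cols(out, as_tibble(feat))
  out$valid <- out$n_valid_subepochs > 0
  out
}

#' Normalize features per recording
#'
#' Band powers are expressed as `log10` power relative to the recording's
#' mean broadband power (the mean of all band powers over valid epochs).
#' This removes amplifier/montage gain exactly -- scaling the signal by any
#' factor leaves the features untouched -- while preserving the spectral
#' shape that separates sleep states, so a recording without internal
#' contrast (for example all wake) still looks wake-like. Invalid epochs are
#' imputed from the nearest valid epoch and flagged.
#'
#' @param features tibble from [spectral_features()].
#' @param eps relative floor inside the log (scaled by the reference power).
#' @param min_valid minimum number of valid epochs required.
#' @return The tibble with feature columns normalized and an `imputed` flag.
#' @export
normalize_features <- function(features, eps = 1e-6, min_valid = 30L) {
  fcols <- feature_columns(features)
  if (!any(features$valid)) abort("all epochs invalid: cannot normalize")
  if (sum(features$valid) < min_valid) {
    abort(sprintf("fewer than %d valid epochs", min_valid))
  }
  out <- features
  valid_idx <- which(features$valid)
  # nearest-valid imputation (ties -> earlier epoch)
  nearest <- valid_idx[pmax(1, findInterval(seq_len(nrow(features)), valid_idx))]
  dist_lo <- abs(seq_len(nrow(features)) - nearest)
  nxt_pos <- pmin(length(valid_idx), findInterval(seq_len(nrow(features)), valid_idx) + 1)
  nxt <- valid_idx[pmax(1, nxt_pos)]
  use_next <- abs(seq_len(nrow(features)) - nxt) < dist_lo
  src <- ifelse(use_next, nxt, nearest)
  ref <- mean(colMeans(features[valid_idx, fcols]))
  for (cl in fcols) {
    v <- log10(features[[cl]] + eps * ref) - log10(ref)
    out[[cl]] <- v[src]  # valid epochs map to themselves
  }
  out$imputed <- !features$valid
  out
}

feature_columns <- function(features) {
  grep("_(alpha|sigma|delta|artifact)$", names(features), value = TRUE)
}

#' Build 11-epoch context sequences
#'
#' One sequence per epoch position, labelled/predicted at the center epoch;
#' the first and last `(context-1)/2` positions replicate the edge epoch.
#'
#' @param features normalized feature tibble.
#' @param context_epochs context length (odd).
#' @return A list with `X` (array `n x context x 12`) and `epoch_index`.
#' @export
make_sequences <- function(features, context_epochs = 11L) {
  fcols <- feature_columns(features)
  n <- nrow(features)
  if (n < context_epochs) {
    abort(sprintf("need at least %d epochs for the context window", context_epochs))
  }
  half <- (context_epochs - 1L) %/% 2L
  fmat <- as.matrix(features[, fcols])
  X <- array(0, dim = c(n, context_epochs, length(fcols)))
  for (k in seq_len(context_epochs)) {
    idx <- pmin(pmax(seq_len(n) + k - 1L - half, 1L), n)
    X[, k, ] <- fmat[idx, ]
  }
  list(X = X, epoch_index = features$epoch_index)
}

#' Training matrix for the sleep classifier from scored recordings
#'
#' @param features_list list of normalized feature tibbles (one per patient).
#' @param hypnogram_list matching list of ground-truth hypnograms.
#' @param config a [sleep_net_config()].
#' @return A list with `X` and `y` (1 = other, 2 = NREM2/3).
#' @export
sleep_training_set <- function(features_list, hypnogram_list,
                               config = sleep_net_config()) {
  parts <- purrr::map2(features_list, hypnogram_list, function(f, h) {
    s <- make_sequences(f, config$context_epochs)
    y <- as.integer(nrem_mask(h)[f$epoch_index]) + 1L
    list(X = s$X, y = y)
  })
  X <- do.call(abind_first, purrr::map(parts, "X"))
  list(X = X, y = unlist(purrr::map(parts, "y")))
}

# bind 3-D arrays along the first dimension
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Train the sleep-detection LSTM
#'
#' @param X,y training sequences and labels from [sleep_training_set()].
#' @param x_val,y_val optional validation data (patient-disjoint).
#' @param config a [sleep_net_config()].
#' @param n_restarts independently initialised trainings; the best candidate
#'   by final validation kappa is kept (see [train_spike_net()]).
#' @return An `lstm_net` tagged for sleep detection.
#' @export
train_sleep_net <- function(X, y, x_val = NULL, y_val = NULL,
                            config = sleep_net_config(), n_restarts = 1L) {
  nets <- lapply(seq_len(n_restarts), function(k) {
    train_lstm(X, y, x_val, y_val,
               layer_sizes = config$lstm_units, n_classes = 2,
               epochs = config$training_epochs,
               dropout_p = config$dropout_p, lr = config$lr,
               batch_size = config$batch_size,
               seed = config$seed + 1000L * (k - 1L))
  })
  net <- nets[[select_best_net(nets)]]
  net$task <- "sleep"
  net$context_epochs <- config$context_epochs
  net
}

#' Predict a binary hypnogram
#'
#' @param net trained sleep `lstm_net`.
#' @param features normalized feature tibble for one recording.
#' @return A hypnogram tibble with `epoch_index`, `label`
#'   (`"NREM23"`/`"other"`) and `posterior` (NREM2/3 class).
#' @export
predict_sleep <- function(net, features) {
  s <- make_sequences(features, net$context_epochs %||% 11L)
  post <- predict_lstm(net, s$X)[, 2]
  structure(
    tibble(epoch_index = s$epoch_index,
           label = ifelse(post >= 0.5, "NREM23", "other"),
           posterior = post),
    class = c("hypnogram", class(tibble())))
}
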