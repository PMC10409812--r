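# Shared fixtures, built lazily once per test session. The desk-scale study
# conditions: compact recordings (10-min spike-training segments, 1.5-h
# sleep-training nights, 2.3-h analysis nights on a 5-channel montage) and
# reduced network sizes (spike 2x12, sleep 2x16 units; best of several seeded restarts by validation kappa), which the full-scale
# configurations default to 2x128 / 2x64.

fixture_cache <- new.env(parent = emptyenv())

sim_channels_small <- c("F3", "C3", "O1", "M1", "M2")

cached <- function(key, build) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, build(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# one synthetic "patient" for spike training/testing: 10-min segment,
# focus-channel windows labelled from ground-truth apex times
spike_patient <- function(seed, duration_s = 600) {
  sim <- simulate_recording(sim_config(
    duration_s = duration_s, hypnogram_preset = "nrem_dominant",
    channel_labels = sim_channels_small, seed = seed))
  rec <- preprocess_recording(sim$recording)
  fc <- sim_focus_channel(sim$config)
  w <- make_windows(channel_signal(rec, fc), rec$fs)
  gt_times <- sim$ground_truth$spikes$time_s[sim$ground_truth$spikes$channel == fc]
  list(windows = w$windows, start_s = w$start_s, step_s = w$step_s,
       labels = label_windows(w$start_s, gt_times, w$step_s),
       gt_times = gt_times, sim = sim, rec = rec, focus = fc)
}

# one synthetic patient for sleep training/testing: 1.5-h night with
# ground-truth spikes used for sub-epoch exclusion
sleep_patient <- function(seed, duration_s = 1.5 * 3600,
                          preset = "pediatric_night") {
  sim <- simulate_recording(sim_config(
    duration_s = duration_s, hypnogram_preset = preset,
    channel_labels = sim_channels_small, seed = seed))
  rec <- preprocess_recording(sim$recording)
  feats <- normalize_features(spectral_features(rec, sim$ground_truth$spikes))
  list(features = feats, hypnogram = sim$ground_truth$hypnogram, sim = sim)
}

fixture_spike_net <- function() {
  cached("spike_net", function() {
    tr <- lapply(1:3, spike_patient)
    va <- spike_patient(4)
    train_spike_net(
      do.call(rbind, lapply(tr, `[[`, "windows")),
      unlist(lapply(tr, `[[`, "labels")),
      va$windows, va$labels,
      spike_net_config(lstm_units = c(12, 12), seed = 7),
      n_restarts = 3)
  })
}

fixture_sleep_net <- function() {
  cached("sleep_net", function() {
    tr <- lapply(11:13, sleep_patient)
    va <- sleep_patient(14)
    ts <- sleep_training_set(lapply(tr, `[[`, "features"),
                             lapply(tr, `[[`, "hypnogram"))
    vs <- sleep_training_set(list(va$features), list(va$hypnogram))
    train_sleep_net(ts$X, ts$y, vs$X, vs$y,
                    sleep_net_config(lstm_units = c(16, 16), seed = 7),
                    n_restarts = 2)
  })
}

fixture_spike_test_patients <- function() {
  cached("spike_test_patients", function() lapply(5:6, spike_patient))
}

fixture_sleep_test_patient <- function() {
  cached("sleep_test_patient", function() sleep_patient(15))
}

# a compact analysis night: >= 360 NREM epochs inside 2.3 h
recovery_night <- function(frac, seed) {
  simulate_recording(sim_config(
    duration_s = 2.3 * 3600, hypnogram_preset = "nrem_dominant",
    channel_labels = sim_channels_small, slope_decline_frac = frac,
    seed = seed))
}

recovery_config <- function() pipeline_config(min_duration_h = 2)

# permutation p-value for a kappa against label-shuffled nulls
kappa_perm_pvalue <- function(pred, truth, n_perm = 100, seed = 1) {
  obs <- cohens_kappa(confusion_from_labels(pred, truth))$kappa
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      k <- cohens_kappa(confusion_from_labels(pred, sample(truth)))$kappa
      if (is.na(k)) 0 else k
    }, numeric(1))
  })
  list(kappa = obs, p = (1 + sum(abs(perms) >= abs(obs))) / (1 + n_perm))
}
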