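test_that("hypnogram presets, determinism and degenerate durations behave", {
  h <- simulate_hypnogram(sim_config(duration_s = 400, hypnogram_preset = "all_n2"))
  expect_equal(nrow(h), 20)
  expect_true(all(h$stage == "N2"))

  cfg <- sim_config(duration_s = 3600, seed = 5)
  expect_identical(simulate_hypnogram(cfg), simulate_hypnogram(cfg))

  expect_error(simulate_hypnogram(sim_config(duration_s = 10)),
               "empty hypnogram")
})

test_that("default pediatric night has a plausible NREM2/3 fraction", {
  h <- simulate_hypnogram(sim_config(duration_s = 8 * 3600, seed = 1))
  frac <- mean(nrem_mask(h))
  expect_gte(frac, 0.4)
  expect_lte(frac, 0.8)
})

test_that("synthetic slow waves carry the analytic ascending slope", {
  w1 <- synth_slow_wave(100, 0.5, 128)
  expect_equal(w1$true_slope_uv_per_s, 400)
  w2 <- synth_slow_wave(75, 1.0, 128)
  expect_equal(w2$true_slope_uv_per_s, 150)
  # sampled minimum reaches the negative peak within quantization
  expect_equal(min(w1$samples), -100, tolerance = 2e-3)
  # zero net area for the full oscillation
  expect_lt(abs(sum(w1$samples)) / sum(abs(w1$samples)), 0.05)
  expect_error(synth_slow_wave(100, 0.2, 128), "0.25")
  expect_error(synth_slow_wave(100, 1.2, 128), "0.25")
  expect_error(synth_slow_wave(-5, 0.5, 128), "peak_amp_uv")
})

test_that("simulation is bit-reproducible and conserves inserted events", {
  cfg <- sim_config(duration_s = 240, hypnogram_preset = "nrem_dominant",
                    channel_labels = sim_channels_small, seed = 9)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$ground_truth$waves, b$ground_truth$waves)
  expect_identical(a$ground_truth$spikes, b$ground_truth$spikes)

  cnt <- a$ground_truth$insertion_counts
  for (ch in setdiff(sim_channels_small, c("M1", "M2"))) {
    expect_equal(cnt$n_spikes[cnt$channel == ch],
                 sum(a$ground_truth$spikes$channel == ch))
    expect_equal(cnt$n_waves[cnt$channel == ch],
                 sum(a$ground_truth$waves$channel == ch))
  }
})

test_that("zero spike rates give empty spike ground truth", {
  cfg <- sim_config(duration_s = 240, hypnogram_preset = "nrem_dominant",
                    channel_labels = sim_channels_small,
                    spike_rate_hz = c(F3 = 0), spike_rate_default_hz = 0,
                    seed = 2)
  sim <- simulate_recording(cfg, render_signal = FALSE)
  expect_equal(nrow(sim$ground_truth$spikes), 0)
})

test_that("per-channel spike counts follow the configured Poisson rates", {
  cfg <- sim_config(duration_s = 3600, hypnogram_preset = "nrem_dominant",
                    channel_labels = sim_channels_small, seed = 7)
  sim <- simulate_recording(cfg, render_signal = FALSE)
  n_f3 <- sum(sim$ground_truth$spikes$channel == "F3")
  expect_gte(n_f3, 720 * 0.7)
  expect_lte(n_f3, 720 * 1.3)
})

test_that("every ground-truth half-wave duration lies in the detectable range", {
  sim <- simulate_recording(sim_config(duration_s = 1200,
                                       hypnogram_preset = "nrem_dominant",
                                       channel_labels = sim_channels_small,
                                       seed = 3), render_signal = FALSE)
  d <- sim$ground_truth$waves$zc2_s - sim$ground_truth$waves$zc1_s
  expect_true(all(d >= 0.25 & d <= 1.0))
  w <- sim$ground_truth$waves
  expect_true(all(w$zc1_s < w$peak_s & w$peak_s < w$zc2_s))
  expect_equal(w$slope_uv_per_s, w$peak_amp_uv / (w$zc2_s - w$peak_s),
               tolerance = 1e-12)
})

test_that("injected overnight slope change is recovered in the ground truth", {
  for (frac in c(-0.15, 0, 0.10)) {
    ch <- vapply(1:10, function(s) {
      sim <- simulate_recording(sim_config(
        duration_s = 2.6 * 3600, hypnogram_preset = "nrem_dominant",
        channel_labels = sim_channels_small, slope_decline_frac = frac,
        seed = s), render_signal = FALSE)
      gt_slope_change(sim$ground_truth, channel = "F3")
    }, numeric(1))
    expect_lt(abs(mean(ch) - frac), 0.02)
  }
})

test_that("configurations without mastoids or a unique focus are rejected", {
  expect_error(
    simulate_recording(sim_config(duration_s = 120,
                                  channel_labels = c("F3", "C3"))),
    "mastoid")
  expect_error(sim_config(spike_rate_hz = c(F3 = 0.2, C3 = 0.2),
                          spike_rate_default_hz = 0.2),
               "focus")
})
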