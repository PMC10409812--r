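half_sine_signal <- function(amp, dur, fs = 128, total = 20, at = 10) {
  x <- numeric(total * fs)
  n <- round(dur * fs)
  seg <- -amp * sin(pi * (seq_len(n) - 0.5) / n)
  x[at * fs + seq_len(n)] <- seg
  x
}

test_that("the slow-wave filter meets its pass- and stop-band contracts", {
  fs <- 128
  t <- seq(0, 400 - 1 / fs, by = 1 / fs)
  amp_out <- function(f) {
    y <- sw_filter(100 * sin(2 * pi * f * t), fs)
    somnidex:::sine_amplitude(y, f, fs)
  }
  expect_equal(amp_out(1), 100, tolerance = 0.10)
  expect_lte(amp_out(20), 1)           # >= 40 dB above the stop edge
  expect_lte(amp_out(0.05), 1)         # >= 40 dB below the stop edge
})

test_that("an injected half-sine is recovered with the analytic slope", {
  x <- half_sine_signal(100, 0.5)
  w <- detect_slow_waves(x, 128)
  expect_equal(nrow(w), 1)
  expect_gte(w$peak_amp_uv, 95); expect_lte(w$peak_amp_uv, 105)
  expect_gte(w$slope_uv_per_s, 380); expect_lte(w$slope_uv_per_s, 420)
})

test_that("the 0.25-1.0 s duration gate rejects too-short and too-long waves", {
  expect_equal(nrow(detect_slow_waves(half_sine_signal(100, 0.2), 128)), 0)
  expect_equal(nrow(detect_slow_waves(half_sine_signal(100, 1.2), 128)), 0)
  expect_equal(nrow(detect_slow_waves(half_sine_signal(100, 0.6), 128)), 1)
})

test_that("detection matches analytic zero-crossings for sums of half-sines", {
  fs <- 128
  cases <- expand.grid(amp = c(40, 90, 150), dur = c(0.3, 0.55, 0.9))
  x <- numeric(fs * (2 * nrow(cases) + 4))
  truth <- list()
  for (i in seq_len(nrow(cases))) {
    at <- 2 * i
    n <- round(cases$dur[i] * fs)
    x[at * fs + seq_len(n)] <-
      -cases$amp[i] * sin(pi * (seq_len(n) - 0.5) / n)
    truth[[i]] <- c(zc1 = at, zc2 = at + cases$dur[i],
                    peak = at + cases$dur[i] / 2)
  }
  w <- detect_slow_waves(x, fs)
  expect_equal(nrow(w), nrow(cases))
  tol_zc <- 1 / fs + 1e-6    # zero-crossings are interpolated
  tol_pk <- 2 / fs + 1e-6    # peaks are sample-quantized (half-sample phase)
  for (i in seq_len(nrow(cases))) {
    expect_lt(abs(w$zc1_s[i] - truth[[i]]["zc1"]), tol_zc)
    expect_lt(abs(w$zc2_s[i] - truth[[i]]["zc2"]), tol_zc)
    expect_lt(abs(w$peak_s[i] - truth[[i]]["peak"]), tol_pk)
  }
})

test_that("post-spike exclusion uses interval overlap, is idempotent, a subset", {
  waves <- tibble::tibble(zc1_s = c(10.3, 10.6, 50.0),
                          peak_s = c(10.5, 10.8, 50.3),
                          peak_amp_uv = c(80, 90, 100),
                          zc2_s = c(10.8, 11.1, 50.6),
                          slope_uv_per_s = c(200, 250, 300),
                          dur_s = c(0.5, 0.5, 0.6))
  out <- exclude_post_spike(waves, 10.0)
  expect_equal(out$zc1_s, c(10.6, 50.0))      # overlap with [10, 10.5] removed
  expect_equal(attr(out, "excluded_post_spike"), 1L)

  # wave starting 0.6 s after the spike is retained
  out2 <- exclude_post_spike(waves[2, ], 10.0)
  expect_equal(nrow(out2), 1)

  # idempotent and a subset
  out3 <- exclude_post_spike(out, 10.0)
  expect_equal(out3$zc1_s, out$zc1_s)
  expect_true(all(out$zc1_s %in% waves$zc1_s))

  # no spikes: identity
  expect_equal(nrow(exclude_post_spike(waves, numeric(0))), 3)

  # peak-only rule keeps a wave that merely grazes the window
  grazing <- tibble::tibble(zc1_s = 10.4, peak_s = 10.7, peak_amp_uv = 80,
                            zc2_s = 11.0, slope_uv_per_s = 200, dur_s = 0.6)
  expect_equal(nrow(exclude_post_spike(grazing, 10.0, rule = "overlap")), 0)
  expect_equal(nrow(exclude_post_spike(grazing, 10.0, rule = "peak")), 1)
})

fake_waves <- function(amps) {
  tibble::tibble(zc1_s = seq_along(amps), peak_s = seq_along(amps) + 0.2,
                 peak_amp_uv = amps, zc2_s = seq_along(amps) + 0.5,
                 slope_uv_per_s = amps / 0.3, dur_s = 0.5)
}

test_that("amplitude matching equalizes per-bin counts", {
  fh <- fake_waves(c(rep(45, 10), rep(55, 4)))
  lh <- fake_waves(c(rep(44, 7), rep(57, 9)))
  m <- amplitude_match(fh, lh, bin_width_uv = 10, min_matched = 1)
  expect_equal(m$n_matched, 7 + 4)
  bf <- table(floor(m$fh$peak_amp_uv / 10))
  bl <- table(floor(m$lh$peak_amp_uv / 10))
  expect_equal(bf, bl)

  # identical sets match completely
  m2 <- amplitude_match(fh, fh, min_matched = 1)
  expect_equal(m2$n_matched, nrow(fh))

  # disjoint amplitude support -> zero matches -> exclusion flag
  m3 <- amplitude_match(fake_waves(rep(35, 5)), fake_waves(rep(65, 5)),
                        min_matched = 250)
  expect_equal(m3$n_matched, 0)
  expect_true(m3$insufficient)

  expect_error(amplitude_match(fh[0, ], lh), "non-empty")
})

test_that("matched sets agree in mean amplitude within one bin width", {
  withr::with_seed(9, {
    for (i in 1:10) {
      fh <- fake_waves(pmax(10, rnorm(300, 120, 40)))
      lh <- fake_waves(pmax(10, rnorm(260, 100, 35)))
      m <- amplitude_match(fh, lh, bin_width_uv = 10, seed = i,
                           min_matched = 1)
      expect_lte(abs(mean(m$fh$peak_amp_uv) - mean(m$lh$peak_amp_uv)), 10)
      expect_equal(nrow(m$fh), nrow(m$lh))
    }
  })
  # deterministic under a fixed seed
  fh <- fake_waves(pmax(10, withr::with_seed(1, rnorm(100, 120, 30))))
  lh <- fake_waves(pmax(10, withr::with_seed(2, rnorm(80, 110, 30))))
  expect_identical(amplitude_match(fh, lh, seed = 5, min_matched = 1),
                   amplitude_match(fh, lh, seed = 5, min_matched = 1))
})

test_that("detector recalls simulated waves with accurate peak times", {
  # sparse, quiet inventory isolates detector fidelity from the wave-packing
  # effects of a dense night; a 20 uV floor keeps microvolt noise ripples
  # out of the precision denominator
  sim <- simulate_recording(sim_config(
    duration_s = 600, hypnogram_preset = "nrem_dominant",
    channel_labels = sim_channels_small, noise_scale_uv = 1,
    sw_rate_per_epoch = 4,
    spike_rate_hz = c(F3 = 0), spike_rate_default_hz = 0, seed = 12))
  x <- sw_filter(channel_signal(sim$recording, "F3"), 128)
  det <- detect_slow_waves(x, 128, min_amp_uv = 20)
  gt <- sim$ground_truth$waves[sim$ground_truth$waves$channel == "F3", ]
  hit <- vapply(gt$peak_s, function(t) any(abs(det$peak_s - t) <= 0.05),
                logical(1))
  matched_det <- vapply(det$peak_s, function(t) any(abs(gt$peak_s - t) <= 0.05),
                        logical(1))
  expect_gte(mean(hit), 0.9)           # recall
  expect_gte(mean(matched_det), 0.9)   # precision
})
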