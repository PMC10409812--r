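test_that("windowing cuts non-overlapping 125-ms windows with start times", {
  x <- withr::with_seed(1, rnorm(1280, sd = 20))
  w <- make_windows(x, fs = 128)
  expect_equal(nrow(w$windows), 80)
  expect_equal(w$start_s, (0:79) * 0.125)
  expect_equal(w$step_s, 0.125)

  # trailing partial window dropped
  w2 <- make_windows(x[1:100], fs = 128)
  expect_equal(nrow(w2$windows), 6)

  # constant signal standardizes to all-zero windows
  wc <- make_windows(rep(5, 160), fs = 128)
  expect_true(all(wc$windows == 0))

  expect_warning(we <- make_windows(x[1:10], fs = 128), "shorter")
  expect_equal(nrow(we$windows), 0)
})

test_that("window labels follow the half-open interval rule", {
  starts <- (0:15) * 0.125
  lab <- label_windows(starts, 1.0)
  expect_equal(which(lab == 1), 9)          # window starting at 1.000 s
  expect_equal(label_windows(starts, numeric(0)), integer(16))
  # a spike exactly on a boundary belongs to the later window
  lab2 <- label_windows(starts, 0.125)
  expect_equal(lab2[1], 0L)
  expect_equal(lab2[2], 1L)
})

test_that("supra-threshold runs merge into midpoint events", {
  starts <- (0:3) * 0.125
  ev <- windows_to_events(c(0, .9, .9, 0), starts, threshold = 0.5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time_s, 0.25)
  expect_equal(ev$posterior, 0.9)

  expect_equal(nrow(windows_to_events(c(.1, .2, .3), starts[1:3], 0.5)), 0)

  ev2 <- windows_to_events(c(.9, 0, .9), starts[1:3], 0.5)
  expect_equal(nrow(ev2), 2)

  # property: event count never exceeds supra-threshold window count and
  # every event time lies inside one of its run's span
  withr::with_seed(4, {
    for (i in 1:20) {
      post <- runif(40)
      st <- (seq_len(40) - 1) * 0.125
      ev <- windows_to_events(post, st, 0.6)
      expect_lte(nrow(ev), sum(post >= 0.6))
      if (nrow(ev)) {
        inside <- vapply(ev$time_s, function(t) {
          k <- floor(t / 0.125) + 1
          any(post[pmax(1, k - 1):pmin(40, k + 1)] >= 0.6)
        }, logical(1))
        expect_true(all(inside))
      }
    }
  })
})

test_that("SWI counts spike-bearing 10-s NREM intervals as a percentage", {
  # 30 NREM epochs -> 60 intervals; spikes in 3 distinct intervals -> 5%
  hyp <- tibble::tibble(epoch_index = 1:30,
                        label = rep("NREM23", 30))
  ev <- tibble::tibble(channel = "F3", time_s = c(5, 25, 45))
  swi <- compute_swi(ev, hyp)
  expect_equal(swi$n_intervals, 60)
  expect_equal(swi$per_channel$swi_percent, 5.0)

  ev0 <- tibble::tibble(channel = character(0), time_s = numeric(0))
  expect_equal(compute_swi(ev0, hyp, channels = "F3")$per_channel$swi_percent, 0)

  # adding a spike never lowers the SWI
  withr::with_seed(5, {
    times <- sort(runif(10, 0, 600))
    for (k in 1:9) {
      a <- compute_swi(tibble::tibble(channel = "F3", time_s = times[1:k]), hyp)
      b <- compute_swi(tibble::tibble(channel = "F3", time_s = times[1:(k + 1)]), hyp)
      expect_gte(b$per_channel$swi_percent, a$per_channel$swi_percent)
    }
  })

  wake <- tibble::tibble(epoch_index = 1:10, label = rep("other", 10))
  expect_error(compute_swi(ev, wake), "SWI undefined")
})

test_that("trained detector recovers events with high sensitivity and precision", {
  net <- fixture_spike_net()
  pats <- fixture_spike_test_patients()
  tol <- 0.125 + 1 / 128
  for (p in pats) {
    post <- predict_lstm(net, somnidex:::windows_to_array(p$windows))[, 2]
    ev <- windows_to_events(post, p$start_s, 0.5, p$step_s)
    sens <- mean(vapply(p$gt_times, function(t)
      any(abs(ev$time_s - t) <= tol), logical(1)))
    prec <- mean(vapply(ev$time_s, function(t)
      any(abs(p$gt_times - t) <= tol), logical(1)))
    expect_gte(sens, 0.8)
    expect_gte(prec, 0.8)
  }
})

test_that("detection performance degrades when the noise floor rises", {
  net <- fixture_spike_net()
  ev_quality <- function(noise) {
    sim <- simulate_recording(sim_config(
      duration_s = 600, hypnogram_preset = "nrem_dominant",
      channel_labels = sim_channels_small, noise_scale_uv = noise,
      seed = 21))
    rec <- preprocess_recording(sim$recording)
    w <- make_windows(channel_signal(rec, "F3"), rec$fs)
    post <- predict_lstm(net, somnidex:::windows_to_array(w$windows))[, 2]
    ev <- windows_to_events(post, w$start_s)
    gt <- sim$ground_truth$spikes$time_s[sim$ground_truth$spikes$channel == "F3"]
    tol <- 0.125 + 1 / 128
    mean(vapply(gt, function(t) any(abs(ev$time_s - t) <= tol), logical(1)))
  }
  expect_gte(ev_quality(8), ev_quality(40))
})
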