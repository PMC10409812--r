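pure_tone_rec <- function(f, amp = 50, dur = 620, fs = 128) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * f * t)
  eeg_recording(rbind(x, x, x), fs, c("F3", "C3", "O1"))
}

test_that("band powers separate a pure alpha tone from the other bands", {
  f <- spectral_features(pure_tone_rec(10), NULL)
  for (ch in c("F3", "C3", "O1")) {
    a <- f[[paste0(ch, "_alpha")]]
    for (b in c("sigma", "delta", "artifact")) {
      expect_true(all(a > 100 * f[[paste0(ch, "_", b)]]))
    }
  }
  # 12 feature columns, 5 valid sub-epochs everywhere
  expect_length(somnidex:::feature_columns(f), 12)
  expect_true(all(f$n_valid_subepochs == 5))
})

test_that("epochs whose sub-epochs are all spike-contaminated are invalid", {
  rec <- pure_tone_rec(10, dur = 620)
  spikes <- tibble::tibble(channel = "F3", time_s = c(2, 6, 10, 14, 18))
  f <- spectral_features(rec, spikes)
  expect_equal(f$n_valid_subepochs[1], 0)
  expect_false(f$valid[1])
  expect_true(all(f$valid[-1]))
})

test_that("periodogram normalization satisfies Parseval within 5%", {
  fs <- 128
  x <- withr::with_seed(8, rnorm(fs * 200, sd = 30))
  w <- somnidex:::tukey_window(4 * fs, 0.5)
  sums <- vapply(seq_len(50), function(k) {
    seg <- x[((k - 1) * 4 * fs + 1):(k * 4 * fs)]
    sum(somnidex:::tapered_periodogram(seg - mean(seg), w))
  }, numeric(1))
  expect_equal(mean(sums), var(x), tolerance = 0.05)
})

test_that("normalization removes gain exactly and imputes invalid epochs", {
  sim <- simulate_recording(sim_config(duration_s = 1200,
                                       hypnogram_preset = "nrem_dominant",
                                       channel_labels = sim_channels_small,
                                       seed = 6))
  prec <- preprocess_recording(sim$recording)
  f <- spectral_features(prec, sim$ground_truth$spikes)
  fn <- normalize_features(f)
  # global gain invariance (a gain g scales every band power by g^2)
  f2 <- f
  for (cl in somnidex:::feature_columns(f2)) f2[[cl]] <- f2[[cl]] * 16
  fn2 <- normalize_features(f2)
  for (cl in somnidex:::feature_columns(fn)) {
    expect_equal(fn2[[cl]], fn[[cl]], tolerance = 1e-12)
  }
  # an invalid epoch copies its nearest valid neighbour and is flagged
  f3 <- f
  f3$valid[10] <- FALSE
  fn3 <- normalize_features(f3)
  expect_true(fn3$imputed[10])
  expect_equal(unlist(fn3[10, somnidex:::feature_columns(fn3)]),
               unlist(fn3[9, somnidex:::feature_columns(fn3)]),
               tolerance = 1e-12)
  # all-invalid input is an error
  f4 <- f; f4$valid <- FALSE
  expect_error(normalize_features(f4), "invalid")
  expect_error(normalize_features(f[1:10, ]), "30")
})

test_that("context sequences are centered with edge replication", {
  f <- tibble::tibble(epoch_index = 1:100)
  withr::with_seed(2, {
    for (b in c("alpha", "sigma", "delta", "artifact")) {
      for (ch in c("F3", "C3", "O1")) f[[paste(ch, b, sep = "_")]] <- rnorm(100)
    }
  })
  s <- make_sequences(f, 11)
  expect_equal(dim(s$X), c(100, 11, 12))
  fmat <- as.matrix(f[, somnidex:::feature_columns(f)])
  # position 51 spans epochs 46..56
  expect_equal(s$X[51, , ], fmat[46:56, ], ignore_attr = TRUE)
  # position 1 replicates the first epoch over the left half
  expect_equal(s$X[1, , ], fmat[c(1, 1, 1, 1, 1, 1, 2, 3, 4, 5, 6), ],
               ignore_attr = TRUE)
  expect_error(make_sequences(f[1:5, ], 11), "at least 11")
})

test_that("the trained sleep detector rejects an all-wake recording", {
  net <- fixture_sleep_net()
  sim <- simulate_recording(sim_config(duration_s = 2400,
                                       hypnogram_preset = "all_wake",
                                       channel_labels = sim_channels_small,
                                       seed = 31))
  rec <- preprocess_recording(sim$recording)
  fn <- normalize_features(spectral_features(rec, NULL))
  hyp <- predict_sleep(net, fn)
  expect_lte(mean(hyp$label == "NREM23"), 0.1)
})

test_that("detected NREM2/3 epoch count tracks ground truth within 15%", {
  net <- fixture_sleep_net()
  p <- fixture_sleep_test_patient()
  hyp <- predict_sleep(net, p$features)
  expect_equal(nrow(hyp), nrow(p$hypnogram))
  n_true <- sum(nrem_mask(p$hypnogram))
  n_pred <- sum(hyp$label == "NREM23")
  expect_lte(abs(n_pred - n_true) / n_true, 0.15)
  # determinism of prediction
  expect_identical(hyp, predict_sleep(net, p$features))
})
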