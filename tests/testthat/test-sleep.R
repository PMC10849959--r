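test_that("epoching yields one periodogram per full epoch", {
  fs <- 100
  rec <- recording(rnorm(60 * fs), rnorm(60 * fs), fs)
  psd <- epoch_spectrogram(rec, epoch_s = 5)
  expect_identical(nrow(psd$psd), 12L)
  # trailing partial epoch dropped
  rec2 <- recording(rnorm(63 * fs), rnorm(63 * fs), fs)
  expect_identical(nrow(epoch_spectrogram(rec2, 5)$psd), 12L)
  expect_error(epoch_spectrogram(recording(rnorm(10), rnorm(10), fs), 5),
               "shorter than one epoch")
  # frequency resolution at fs = 1500, 5-s epochs is 0.2 Hz
  rec3 <- recording(rnorm(5 * 1500), rnorm(5 * 1500), 1500)
  expect_equal(diff(epoch_spectrogram(rec3, 5)$freq[1:2]), 0.2)
})

test_that("periodogram satisfies Parseval against time-domain power", {
  set.seed(42)
  fs <- 250
  x <- rnorm(20 * fs)
  rec <- recording(x, x, fs)
  psd <- epoch_spectrogram(rec, epoch_s = 5)
  df <- diff(psd$freq[1:2])
  spe <- 5 * fs
  for (e in 1:4) {
    seg <- x[(e - 1) * spe + seq_len(spe)]
    expect_equal(sum(psd$psd[e, ]) * df, mean(seg^2), tolerance = 0.01)
  }
})

test_that("a pure 2 Hz sinusoid concentrates power in the delta band", {
  fs <- 500
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  rec <- recording(sin(2 * pi * 2 * t), rep(0, length(t)), fs)
  psd <- epoch_spectrogram(rec, 5)
  for (e in seq_len(nrow(psd$psd)))
    expect_equal(psd$freq[which.max(psd$psd[e, ])], 2, tolerance = 0.21)
  feats <- extract_features(psd, rec$emg, fs)
  expect_true(all(feats$power_delta > 10 * feats$power_theta))
  expect_true(all(feats$emg_rms == 0))
})

test_that("band integrals follow the trapezoid rule with edge interpolation", {
  freq <- seq(0, 30, by = 0.2)
  h <- 2.5
  flat <- rep(h, length(freq))
  expect_equal(gliasleep:::band_integral(freq, flat, 0.5, 4), 3.5 * h)
  expect_equal(gliasleep:::band_integral(freq, flat, 6, 9), 3 * h)
  expect_equal(gliasleep:::band_integral(freq, flat, 0, 25), 25 * h)
  # the weight-vector form is the same linear functional
  dens <- runif(length(freq))
  w <- gliasleep:::band_weights(freq, 0.5, 4)
  expect_equal(sum(w * dens),
               gliasleep:::band_integral(freq, dens, 0.5, 4))
})

test_that("classification follows the EMG gate then the theta/delta gate", {
  feats <- data.frame(epoch_index = 0:3,
                      power_delta = c(10, 10, 1, 1),
                      power_theta = c(1, 1, 9, 1),
                      power_total_0_25 = 20,
                      theta_delta_ratio = c(0.1, 0.1, 9, 1),
                      emg_rms = c(50, 1, 1, 50))
  h <- classify_epochs(feats, emg_threshold = 10, smooth = FALSE)
  expect_identical(h$states, c("W", "N", "R", "W"))
  # single epoch in, single label out
  h1 <- classify_epochs(feats[2, ], emg_threshold = 10)
  expect_identical(length(h1), 1L)
  # all high EMG -> all wake
  feats$emg_rms <- 100
  expect_true(all(classify_epochs(feats, emg_threshold = 10)$states == "W"))
  # non-finite feature labeled W with a warning
  feats$emg_rms <- c(1, 1, 1, 1)
  feats$theta_delta_ratio[2] <- NaN
  expect_warning(h2 <- classify_epochs(feats, emg_threshold = 10,
                                       smooth = FALSE),
                 "non-finite")
  expect_identical(h2$states[2], "W")
})

test_that("isolated single-epoch states are smoothed away", {
  feats <- data.frame(epoch_index = 0:4, power_delta = 10, power_theta = 1,
                      power_total_0_25 = 20, theta_delta_ratio = 0.1,
                      emg_rms = c(1, 1, 50, 1, 1))
  expect_identical(classify_epochs(feats, emg_threshold = 10,
                                   smooth = FALSE)$states[3], "W")
  expect_identical(classify_epochs(feats, emg_threshold = 10,
                                   smooth = TRUE)$states[3], "N")
})

test_that("manual override replaces requested epoch labels", {
  feats <- data.frame(epoch_index = 0:2, power_delta = 10, power_theta = 1,
                      power_total_0_25 = 20, theta_delta_ratio = 0.1,
                      emg_rms = 1)
  h <- classify_epochs(feats, emg_threshold = 10,
                       override = data.frame(epoch_index = 1, state = "R"))
  expect_identical(h$states, c("N", "R", "N"))
})

test_that("episodes are maximal runs that tile the session", {
  h <- hyp_from_runs(list(c("N", 3), c("W", 2), c("R", 1)))
  ep <- merge_episodes(h)
  expect_equal(ep$state, c("N", "W", "R"))
  expect_equal(ep$start_s, c(0, 15, 25))
  expect_equal(ep$duration_s, c(15, 10, 5))
  # single-state hypnogram: one episode spanning the session
  ep1 <- merge_episodes(hypnogram(rep("W", 7), 5))
  expect_identical(nrow(ep1), 1L)
  expect_equal(ep1$duration_s, 35)
  # round trip and tiling on random hypnograms
  set.seed(1)
  for (i in 1:20) {
    states <- sample(c("W", "N", "R"), 50, replace = TRUE)
    hi <- hypnogram(states, 5)
    epi <- merge_episodes(hi)
    expect_equal(sum(epi$duration_s), 50 * 5)
    back <- unlist(mapply(rep, epi$state, epi$duration_s / 5,
                          SIMPLIFY = FALSE), use.names = FALSE)
    expect_identical(back, states)
    expect_true(all(head(epi$state, -1) != tail(epi$state, -1)))
  }
})

test_that("state metrics compute percentages, durations and rates", {
  h <- hyp_from_runs(list(c("N", 3), c("W", 2), c("R", 1)))
  m <- state_metrics(h, bin_s = 30)
  p <- m$percent_time
  expect_equal(p$percent[p$state == "N"], 50)
  expect_equal(p$percent[p$state == "W"], 100 / 3)
  expect_equal(p$percent[p$state == "R"], 100 / 6)
  expect_equal(sum(p$percent), 100)
  expect_equal(unname(m$mean_episode_duration_s), c(10, 15, 5))
  hours <- 30 / 3600
  expect_equal(unname(m$episodes_per_hour), c(1, 1, 1) / hours)
  # all-N hypnogram: 100% N, absent states get NA duration and 0 rate
  mN <- state_metrics(hypnogram(rep("N", 12), 5), bin_s = 60)
  expect_true(all(mN$percent_time$percent[mN$percent_time$state == "N"] == 100))
  expect_true(is.na(mN$mean_episode_duration_s[["W"]]))
  expect_equal(mN$episodes_per_hour[["W"]], 0)
  # per-bin percentages always sum to 100
  set.seed(2)
  hr <- hypnogram(sample(c("W", "N", "R"), 240, replace = TRUE), 5)
  mr <- state_metrics(hr, bin_s = 300)
  sums <- tapply(mr$percent_time$percent, mr$percent_time$bin_start_s, sum)
  expect_true(all(abs(sums - 100) < 1e-6))
  expect_error(state_metrics(h, bin_s = 7), "multiple")
  expect_error(state_metrics(h, bin_s = 2), "at least one epoch")
})

test_that("normalized state spectra integrate to one over 0-25 Hz", {
  set.seed(3)
  fs <- 250
  rec <- recording(rnorm(600 * fs), rnorm(600 * fs), fs)
  h <- hypnogram(rep(c("N", "W"), 60), 5)
  sp <- normalized_spectrum(rec, h, "N")
  expect_equal(gliasleep:::band_integral(sp$freq_hz, sp$density, 0, 25), 1,
               tolerance = 1e-9)
  # white-noise EEG: flat at 1/25 within the sampling error of 60 epochs
  lowhalf <- mean(sp$density[sp$freq_hz < 12.5])
  highhalf <- mean(sp$density[sp$freq_hz >= 12.5])
  expect_lt(abs(lowhalf - highhalf) / (1 / 25), 0.1)
  expect_lt(sd(sp$density) / mean(sp$density), 0.3)
  # a state with a single epoch equals that epoch's normalized PSD
  h2 <- hypnogram(c("R", rep(c("N", "W"), length.out = 19)), 5)
  sp1 <- normalized_spectrum(rec, h2, "R")
  psd <- epoch_spectrogram(rec, 5)
  keep <- psd$freq <= 25
  ref <- psd$psd[1, keep] /
    gliasleep:::band_integral(psd$freq, psd$psd[1, ], 0, 25)
  expect_equal(sp1$density, unname(ref), tolerance = 1e-12)
  expect_error(normalized_spectrum(rec, h, "R"), "R absent")
})

test_that("automatic scoring recovers hidden states on synthetic sessions", {
  ses <- gen_sleep_session(sleep_synth_config(duration_s = 900, seed = 0))
  hyp <- score_recording(ses$recording)
  expect_gte(mean(hyp$states == ses$truth$hypnogram_true$states), 0.9)
  # scoring-derived metrics close to truth-derived metrics
  m_est <- state_metrics(hyp, 900)
  m_tru <- state_metrics(ses$truth$hypnogram_true, 900)
  expect_lt(max(abs(m_est$percent_time$percent -
                      m_tru$percent_time$percent)), 10)
})
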