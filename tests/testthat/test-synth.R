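test_that("generators are pure functions of their configuration", {
  cfg <- sleep_synth_config(duration_s = 60, seed = 1)
  a <- gen_sleep_session(cfg)
  b <- gen_sleep_session(cfg)
  expect_identical(a, b)

  ca_cfg <- calcium_synth_config(n_rois = 2, duration_s = 300, seed = 1)
  expect_identical(gen_calcium(ca_cfg), gen_calcium(ca_cfg))

  sn_cfg <- sensor_synth_config(n_rois = 2, duration_s = 4000,
                                treatment_time_s = 600, seed = 1)
  expect_identical(gen_sensor(sn_cfg), gen_sensor(sn_cfg))

  v_cfg <- volume_synth_config(c(20L, 30L, 30L), n_spheres = 3,
                               radius_um = c(2, 4), n_boutons = 20,
                               seed = 1)
  expect_identical(gen_volume(v_cfg), gen_volume(v_cfg))

  # different seeds: different noise, identical injected truth
  s1 <- gen_sensor(sensor_synth_config(n_rois = 2, duration_s = 4000,
                                       treatment_time_s = 600,
                                       effect_size_z = -2, seed = 1))
  s2 <- gen_sensor(sensor_synth_config(n_rois = 2, duration_s = 4000,
                                       treatment_time_s = 600,
                                       effect_size_z = -2, seed = 2))
  expect_false(identical(s1$raw$traces, s2$raw$traces))
  expect_identical(s1$truth$effect_true, s2$truth$effect_true)
})

test_that("an absorbing transition matrix pins the hypnogram to its state", {
  cfg <- sleep_synth_config(duration_s = 300,
                            transition_matrix = diag(3),
                            initial_state = "N", seed = 3)
  ses <- gen_sleep_session(cfg)
  expect_true(all(ses$truth$hypnogram_true$states == "N"))
})

test_that("configuration validation rejects bad inputs", {
  bad_tm <- matrix(c(0.5, 0.4, 0.0, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE)
  expect_error(sleep_synth_config(60, transition_matrix = bad_tm), "sum to 1")
  expect_error(sleep_synth_config(60, epoch_s = 5.0001), "integer frame")
  expect_error(calcium_synth_config(n_rois = 1, decay_tau = 0))
  expect_error(sensor_synth_config(treatment_time_s = 0), "inside")
  expect_error(volume_synth_config(c(5L, 5L, 5L), radius_um = c(10, 12)),
               "fit inside")
  expect_error(gen_volume(volume_synth_config(c(20L, 20L, 20L),
                                              n_spheres = 0,
                                              n_boutons = 5)),
               "no microglia")
  expect_error(gen_calcium(calcium_synth_config(n_rois = 1,
                                                duration_s = 0.5)),
               "single frame")
})

test_that("generated EEG band powers separate the hidden states", {
  cfg <- sleep_synth_config(duration_s = 1200, seed = 7)
  ses <- gen_sleep_session(cfg)
  st <- ses$truth$hypnogram_true$states
  delta <- oracle_epoch_band_power(ses$recording$eeg, cfg$fs, cfg$epoch_s,
                                   0.5, 4)
  theta <- oracle_epoch_band_power(ses$recording$eeg, cfg$fs, cfg$epoch_s,
                                   6, 9)
  dn <- delta[st == "N"]; dw <- delta[st == "W"]
  expect_gte(length(dn), 5); expect_gte(length(dw), 5)
  # NREM delta configured 10x wake delta: nearly every epoch pair ordered
  frac <- mean(outer(dn, dw, `>`))
  expect_gt(frac, 0.95)
  # theta/delta ratio orders REM above NREM on state means
  expect_gte(sum(st == "R"), 3)
  expect_gt(mean(theta[st == "R"] / delta[st == "R"]),
            mean(theta[st == "N"] / delta[st == "N"]))
  # EMG RMS separates wake
  spe <- cfg$fs * cfg$epoch_s
  emg_rms <- sqrt(colMeans(matrix(ses$recording$emg^2, nrow = spe)))
  expect_gt(min(emg_rms[st == "W"]), max(emg_rms[st != "W"]))
})

test_that("hypnogram state occupancy converges to the stationary distribution", {
  tm <- gliasleep:::default_transition_matrix()
  pi0 <- gliasleep:::stationary_distribution(tm)
  states <- gliasleep:::with_local_seed(11, {
    gliasleep:::simulate_markov_states(tm, 10000)
  })
  # thin to roughly independent samples (episode correlation time ~ tens of
  # epochs), then chi-squared goodness of fit at alpha = 0.01
  thin <- states[seq(1, length(states), by = 100)]
  counts <- table(factor(thin, levels = c("W", "N", "R")))
  p <- suppressWarnings(chisq.test(counts, p = pi0)$p.value)
  expect_gt(p, 0.01)
  # raw occupancy close to stationary in total variation
  occ <- as.numeric(table(factor(states, levels = c("W", "N", "R")))) /
    length(states)
  expect_lt(sum(abs(occ - pi0)) / 2, 0.05)
})

test_that("calcium generator honours rate, kernel and noiselessness", {
  # zero rate: no events, trace = baseline + drift + noise
  ca0 <- gen_calcium(calcium_synth_config(n_rois = 2, duration_s = 600,
                                          event_rate = 0, seed = 5))
  expect_identical(nrow(ca0$truth$events_true), 0L)
  expect_lt(max(abs(ca0$traces$traces - 100)), 5 + 5 * 10)

  # noiseless, driftless single event: peak dF/F equals the true amplitude
  # up to one frame of decay discretization
  cfg1 <- calcium_synth_config(n_rois = 1, duration_s = 1200,
                               event_rate = 0.05, noise_sd = 0,
                               drift_amplitude = 0, seed = 7)
  ca1 <- gen_calcium(cfg1)
  tru <- ca1$truth$events_true
  expect_identical(nrow(tru), 1L)
  fr <- ca1$traces$frame_rate
  dff_max <- max(ca1$traces$traces[, 1]) / 100 - 1
  a <- tru$amplitude[1]
  expect_lte(dff_max, a + 1e-12)
  expect_gte(dff_max, a * exp(-(1 / fr) / cfg1$decay_tau) - 1e-12)

  # Poisson total count: rate 2/min, 40 min, 10 ROIs => 99% interval of 800
  ca2 <- gen_calcium(calcium_synth_config(n_rois = 10, duration_s = 2400,
                                          event_rate = 2, seed = 17))
  n_ev <- nrow(ca2$truth$events_true)
  expect_gte(n_ev, qpois(0.005, 800))
  expect_lte(n_ev, qpois(0.995, 800))
})

test_that("sensor generator injects the configured step", {
  # null effect: pre/post window means agree within 4 SE
  s0 <- gen_sensor(sensor_synth_config(n_rois = 10, duration_s = 7200,
                                       treatment_time_s = 2400,
                                       effect_size_z = 0, seed = 4))
  d <- delta_z(s0$session)$delta_z
  n_frames <- 20 * 60 * 1.68
  se <- sqrt(2 / n_frames / 10)
  expect_lt(abs(d), 4 * se * 3)  # generous: baseline estimation adds noise

  # strong fast-onset suppression recovered by the window contrast
  s3 <- gen_sensor(sensor_synth_config(n_rois = 10, duration_s = 7200,
                                       treatment_time_s = 2400,
                                       effect_size_z = -3,
                                       effect_onset_tau = 300, seed = 4))
  expect_lt(abs(delta_z(s3$session)$delta_z - (-3)), 0.3)
})

test_that("volume generator geometry matches its analytic ground truth", {
  cfg <- volume_synth_config(c(40L, 60L, 60L), n_spheres = 6,
                             n_boutons = 100, seed = 9)
  vol <- gen_volume(cfg)
  sp <- vol$truth$spheres
  b <- vol$scene$boutons
  # independent recomputation of the analytic distances
  d_oracle <- vapply(seq_len(nrow(b)), function(i) {
    p <- c(b$z_um[i], b$y_um[i], b$x_um[i])
    min(pmax(0, sqrt((p[1] - sp$z_um)^2 + (p[2] - sp$y_um)^2 +
                       (p[3] - sp$x_um)^2) - sp$radius_um))
  }, 0)
  expect_equal(vol$truth$distances_true, d_oracle, tolerance = 1e-12)
  # every foreground voxel centre lies inside some sphere
  fg <- which(vol$scene$mask, arr.ind = TRUE)
  sel <- fg[seq(1, nrow(fg), length.out = min(200, nrow(fg))), , drop = FALSE]
  vs <- cfg$voxel_size_um
  inside <- vapply(seq_len(nrow(sel)), function(i) {
    p <- (sel[i, ] - 1) * vs
    any(sqrt((p[1] - sp$z_um)^2 + (p[2] - sp$y_um)^2 +
               (p[3] - sp$x_um)^2) <= sp$radius_um + 1e-9)
  }, TRUE)
  expect_true(all(inside))
})
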