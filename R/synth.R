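#' Synthetic data generators with embedded ground truth
#'
#' Every pipeline input — EEG/EMG sleep sessions, ROI calcium traces,
#' GRAB-sensor pharmacology sessions and 3D microglia/bouton scenes — can be
#' generated from a seeded configuration so that all downstream stages are
#' testable against known truth without any recorded data.
#'
#' @name synth
NULL

default_bands <- function() {
  list(delta = c(0.5, 4), theta = c(6, 9), broad = c(0.5, 25))
}

default_transition_matrix <- function() {
  # epoch-resolution (5 s) Markov chain giving episode durations on the
  # scale seen in mouse polysomnography: wake/NREM bouts of a couple of
  # minutes, REM bouts of about a minute, REM entered only from NREM
  m <- matrix(c(
    0.960, 0.040, 0.000,
    0.035, 0.955, 0.010,
    0.070, 0.010, 0.920
  ), nrow = 3, byrow = TRUE, dimnames = list(STATES, STATES))
  m
}

default_band_power <- function() {
  # per-state variance (uV^2) contributed by each band-limited component;
  # NREM delta 10x wake delta, REM theta 6x NREM theta
  matrix(c(
    20, 20, 40,
    200, 20, 40,
    20, 120, 40
  ), nrow = 3, byrow = TRUE,
  dimnames = list(STATES, c("delta", "theta", "broad")))
}

#' Configuration for synthetic EEG/EMG sleep sessions
#'
#' @param duration_s session duration in seconds.
#' @param fs sampling rate in Hz (default 1500).
#' @param epoch_s scoring epoch length in seconds (default 5).
#' @param transition_matrix 3x3 row-stochastic matrix over states (W, N, R)
#'   at epoch resolution. Default: a chain with realistic mouse episode
#'   durations.
#' @param band_power 3x3 matrix (rows W/N/R, columns delta/theta/broad) of
#'   per-state variance contributed by each band-limited EEG component
#'   (delta 0.5-4 Hz, theta 6-9 Hz, broadband 0.5-25 Hz), in uV^2.
#' @param emg_amp named numeric (W, N, R): per-state EMG RMS amplitude (uV).
#' @param seed integer RNG seed.
#' @param initial_state optional initial state; default draws from the
#'   stationary distribution of `transition_matrix`.
#' @return a `sleep_synth_config` list.
#' @export
sleep_synth_config <- function(duration_s,
                               fs = 1500,
                               epoch_s = 5,
                               transition_matrix = default_transition_matrix(),
                               band_power = default_band_power(),
                               emg_amp = c(W = 30, N = 5, R = 5),
                               seed = 0L,
                               initial_state = NULL) {
  stopifnot(duration_s > 0, fs > 0, epoch_s > 0)
  tm <- as.matrix(transition_matrix)
  if (!all(dim(tm) == c(3L, 3L)))
    stop("transition_matrix must be 3x3 over states W, N, R")
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9))
    stop("transition_matrix rows must be nonnegative and sum to 1")
  dimnames(tm) <- list(STATES, STATES)
  bp <- as.matrix(band_power)
  if (!all(dim(bp) == c(3L, 3L)) || any(bp < 0))
    stop("band_power must be a nonnegative 3x3 matrix (states x bands)")
  dimnames(bp) <- list(STATES, c("delta", "theta", "broad"))
  bands <- default_bands()
  if (fs <= 2 * max(vapply(bands, max, 0)))
    stop("fs must exceed twice the highest synthesized band edge")
  if (abs(epoch_s * fs - round(epoch_s * fs)) > 1e-9)
    stop("epoch_s * fs must be an integer frame count")
  if (length(emg_amp) != 3L) stop("emg_amp must give one RMS per state")
  names(emg_amp) <- STATES
  if (!is.null(initial_state)) assert_state(initial_state)
  structure(list(duration_s = duration_s, fs = fs, epoch_s = epoch_s,
                 transition_matrix = tm, band_power = bp,
                 emg_amp = emg_amp, bands = bands,
                 seed = as.integer(seed), initial_state = initial_state),
            class = "sleep_synth_config")
}

stationary_distribution <- function(tm) {
  e <- eigen(t(tm))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

simulate_markov_states <- function(tm, n, initial_state = NULL) {
  states <- character(n)
  p0 <- if (is.null(initial_state)) stationary_distribution(tm) else
    as.numeric(STATES == initial_state)
  states[1] <- sample(STATES, 1L, prob = p0)
  for (i in seq_len(n - 1L))
    states[i + 1L] <- sample(STATES, 1L, prob = tm[states[i], ])
  states
}

# Synthesize EEG epochs in the frequency domain: each epoch's spectrum gets
# independent complex Gaussian coefficients confined to the configured
# bands, with per-bin variance set so the expected time-domain variance of
# each band component equals the epoch state's band power. Epochs are
# independent; inverse FFTs are batched.
synth_eeg_epochs <- function(states, cfg, spe) {
  n_epochs <- length(states)
  nf <- spe %/% 2L               # positive-frequency bins 1..nf-1 usable
  freq <- (seq_len(nf - 1L)) * cfg$fs / spe   # bins k = 1 .. nf-1
  state_idx <- match(states, STATES)
  # per-bin variance for each state: sum over bands covering the bin
  var_state <- matrix(0, nf - 1L, 3L)
  for (b in colnames(cfg$band_power)) {
    edges <- cfg$bands[[b]]
    inb <- freq >= edges[1] & freq <= edges[2]
    m <- sum(inb)
    if (m == 0L) stop("band ", b, " contains no frequency bins")
    for (s in 1:3)
      var_state[inb, s] <- var_state[inb, s] +
        cfg$band_power[s, b] * spe^2 / (2 * m)
  }
  active <- which(rowSums(var_state) > 0)
  eeg <- numeric(n_epochs * spe)
  chunk <- 512L
  for (i0 in seq(1L, n_epochs, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n_epochs)
    ne <- length(idx)
    sdmat <- sqrt(var_state[active, state_idx[idx], drop = FALSE] / 2)
    co <- matrix(complex(real = rnorm(length(sdmat)) * sdmat,
                         imaginary = rnorm(length(sdmat)) * sdmat),
                 nrow = length(active))
    spec <- matrix(0 + 0i, spe, ne)
    spec[active + 1L, ] <- co
    spec[spe + 1L - active, ] <- Conj(co)
    seg <- Re(stats::mvfft(spec, inverse = TRUE)) / spe
    eeg[(idx[1] - 1L) * spe + seq_len(ne * spe)] <- as.numeric(seg)
  }
  eeg
}

#' Generate a synthetic EEG/EMG sleep session
#'
#' Hidden states are drawn from a first-order Markov chain at epoch
#' resolution. The EEG is a sum of band-limited Gaussian noise components
#' (delta, theta, broadband) whose per-epoch variances follow the
#' configured per-state band powers; the EMG is white noise whose RMS is
#' amplitude-modulated by state. Identical seeds give bit-identical output.
#'
#' @param cfg a [sleep_synth_config()].
#' @return list with `recording` (a [recording()]) and `truth` (list with
#'   `hypnogram_true`, a [hypnogram()]).
#' @export
gen_sleep_session <- function(cfg) {
  stopifnot(inherits(cfg, "sleep_synth_config"))
  spe <- as.integer(round(cfg$epoch_s * cfg$fs))  # samples per epoch
  n_epochs <- floor(cfg$duration_s / cfg$epoch_s)
  if (n_epochs < 1L) stop("duration_s shorter than one epoch")
  n <- n_epochs * spe
  with_local_seed(cfg$seed, {
    states <- simulate_markov_states(cfg$transition_matrix, n_epochs,
                                     cfg$initial_state)
    eeg <- synth_eeg_epochs(states, cfg, spe)
    amp <- unname(cfg$emg_amp[match(states, STATES)])
    emg <- rnorm(n) * rep(amp, each = spe)
    list(recording = recording(eeg, emg, fs = cfg$fs),
         truth = list(hypnogram_true = hypnogram(states, cfg$epoch_s)))
  })
}

#' Configuration for synthetic ROI calcium traces
#'
#' Traces emulate microglia GCaMP recordings: a slowly drifting baseline
#' with sparse transients (instantaneous rise, exponential decay) and
#' additive Gaussian noise. The defaults describe infrequent, high-contrast
#' microglia transients: 0.2 events per minute per ROI, peak amplitudes of
#' about 1.0 dF/F (SD 0.15, so essentially all peaks exceed 5x the dF/F
#' noise SD of 0.1) and an 8-s decay constant.
#'
#' @param n_rois number of ROIs.
#' @param frame_rate imaging frame rate in Hz (default 0.84).
#' @param duration_s trace duration in seconds.
#' @param event_rate transient rate, events per minute per ROI.
#' @param event_amp `c(mean, sd)` of the Gaussian peak-amplitude (dF/F)
#'   distribution, truncated at 0.01.
#' @param decay_tau transient decay time constant in seconds.
#' @param baseline_level baseline fluorescence (a.u.).
#' @param drift_amplitude amplitude (a.u.) of a one-cycle sinusoidal
#'   baseline drift with random phase.
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param treatment_time_s optional treatment time; after it the event rate
#'   is multiplied by `post_rate_factor` (drug-response sessions).
#' @param post_rate_factor multiplicative post-treatment rate change.
#' @param seed integer RNG seed.
#' @export
calcium_synth_config <- function(n_rois,
                                 frame_rate = 0.84,
                                 duration_s = 2400,
                                 event_rate = 0.2,
                                 event_amp = c(mean = 1.0, sd = 0.15),
                                 decay_tau = 8,
                                 baseline_level = 100,
                                 drift_amplitude = 5,
                                 noise_sd = 10,
                                 treatment_time_s = NULL,
                                 post_rate_factor = 1,
                                 seed = 0L) {
  stopifnot(n_rois >= 1, frame_rate > 0, duration_s > 0,
            event_rate >= 0, decay_tau > 0, noise_sd >= 0,
            baseline_level > 0, post_rate_factor >= 0)
  if (!is.null(treatment_time_s))
    stopifnot(treatment_time_s > 0, treatment_time_s < duration_s)
  structure(list(n_rois = as.integer(n_rois), frame_rate = frame_rate,
                 duration_s = duration_s, event_rate = event_rate,
                 event_amp = event_amp, decay_tau = decay_tau,
                 baseline_level = baseline_level,
                 drift_amplitude = drift_amplitude, noise_sd = noise_sd,
                 treatment_time_s = treatment_time_s,
                 post_rate_factor = post_rate_factor,
                 seed = as.integer(seed)),
            class = "calcium_synth_config")
}

poisson_onsets <- function(rate_per_min, t0, t1) {
  k <- rpois(1L, rate_per_min * (t1 - t0) / 60)
  sort(runif(k, t0, t1))
}

#' Generate synthetic ROI calcium traces
#'
#' @param cfg a [calcium_synth_config()].
#' @return list with `traces` (a [roi_trace_set()]) and `truth` (list with
#'   `events_true`: data frame `roi`, `onset_s`, `amplitude`).
#' @export
gen_calcium <- function(cfg) {
  stopifnot(inherits(cfg, "calcium_synth_config"))
  n_frames <- floor(cfg$duration_s * cfg$frame_rate)
  if (n_frames < 1L) stop("duration_s too short for a single frame")
  t <- (seq_len(n_frames) - 1) / cfg$frame_rate
  with_local_seed(cfg$seed, {
    mat <- matrix(0, n_frames, cfg$n_rois)
    ev_list <- vector("list", cfg$n_rois)
    for (r in seq_len(cfg$n_rois)) {
      phase <- runif(1, 0, 2 * pi)
      drift <- cfg$drift_amplitude * sin(2 * pi * t / cfg$duration_s + phase)
      if (is.null(cfg$treatment_time_s)) {
        onsets <- poisson_onsets(cfg$event_rate, 0, cfg$duration_s)
      } else {
        onsets <- c(
          poisson_onsets(cfg$event_rate, 0, cfg$treatment_time_s),
          poisson_onsets(cfg$event_rate * cfg$post_rate_factor,
                         cfg$treatment_time_s, cfg$duration_s))
      }
      amps <- pmax(0.01, rnorm(length(onsets),
                               cfg$event_amp[["mean"]], cfg$event_amp[["sd"]]))
      tr <- cfg$baseline_level + drift
      for (i in seq_along(onsets)) {
        after <- t >= onsets[i]
        tr[after] <- tr[after] +
          amps[i] * cfg$baseline_level *
          exp(-(t[after] - onsets[i]) / cfg$decay_tau)
      }
      mat[, r] <- tr + rnorm(n_frames, 0, cfg$noise_sd)
      ev_list[[r]] <- if (length(onsets))
        data.frame(roi = r, onset_s = onsets, amplitude = amps)
      else data.frame(roi = integer(), onset_s = numeric(),
                      amplitude = numeric())
    }
    list(traces = roi_trace_set(mat, cfg$frame_rate),
         truth = list(events_true = do.call(rbind, ev_list)))
  })
}

#' Configuration for synthetic GRAB-sensor sessions
#'
#' A treatment applied at `treatment_time_s` shifts every ROI by
#' `effect_size_z` baseline-SD units through a saturating exponential step
#' (time constant `effect_onset_tau`), emulating the gradual, tens-of-minutes
#' responses of chemogenetic manipulations. Optional per-state level offsets
#' couple the trace to a hypnogram.
#'
#' @param n_rois ROIs per session (8-12 is typical; default 10).
#' @param frame_rate Hz (default 1.68).
#' @param duration_s total recording length (default 10800 s = 3 h).
#' @param treatment_time_s treatment time (default 2400 s, i.e. a 40-min
#'   baseline).
#' @param effect_size_z signed plateau of the treatment step, in baseline-SD
#'   units.
#' @param effect_onset_tau onset time constant in seconds (default 600).
#' @param state_coupling optional named numeric (subset of W/N/R): additive
#'   level offset per state, in baseline-SD units. Requires a hypnogram at
#'   generation time.
#' @param baseline_level baseline fluorescence (a.u.).
#' @param noise_sd additive Gaussian noise SD (a.u.); also the unit in which
#'   `effect_size_z` and `state_coupling` are expressed.
#' @param seed integer RNG seed.
#' @export
sensor_synth_config <- function(n_rois = 10,
                                frame_rate = 1.68,
                                duration_s = 10800,
                                treatment_time_s = 2400,
                                effect_size_z = 0,
                                effect_onset_tau = 600,
                                state_coupling = NULL,
                                baseline_level = 100,
                                noise_sd = 5,
                                seed = 0L) {
  stopifnot(n_rois >= 1, frame_rate > 0, duration_s > 0,
            effect_onset_tau > 0, noise_sd > 0, baseline_level > 0)
  if (!(treatment_time_s > 0 && treatment_time_s < duration_s))
    stop("treatment_time_s must lie strictly inside the recording")
  if (!is.null(state_coupling)) {
    state_coupling <- unlist(state_coupling)
    if (is.null(names(state_coupling)) ||
        !all(names(state_coupling) %in% STATES))
      stop("state_coupling must be named with states W/N/R")
  }
  structure(list(n_rois = as.integer(n_rois), frame_rate = frame_rate,
                 duration_s = duration_s,
                 treatment_time_s = treatment_time_s,
                 effect_size_z = effect_size_z,
                 effect_onset_tau = effect_onset_tau,
                 state_coupling = state_coupling,
                 baseline_level = baseline_level, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sensor_synth_config")
}

#' Generate a synthetic GRAB-sensor session
#'
#' @param cfg a [sensor_synth_config()].
#' @param hyp optional [hypnogram()] covering the recording; required when
#'   `cfg$state_coupling` is set.
#' @return list with `raw` (a [roi_trace_set()] of raw fluorescence),
#'   `session` (a [sensor_session()] z-scored against the pre-treatment
#'   baseline) and `truth` (list with `effect_true` per ROI).
#' @export
gen_sensor <- function(cfg, hyp = NULL) {
  stopifnot(inherits(cfg, "sensor_synth_config"))
  n_frames <- floor(cfg$duration_s * cfg$frame_rate)
  if (n_frames < 2L) stop("duration_s too short")
  t <- (seq_len(n_frames) - 1) / cfg$frame_rate
  offset <- numeric(n_frames)
  if (!is.null(cfg$state_coupling)) {
    if (is.null(hyp)) stop("state_coupling requires a hypnogram")
    stopifnot(inherits(hyp, "hypnogram"))
    epoch_of <- pmin(floor(t / hyp$epoch_s) + 1L, length(hyp$states))
    lev <- c(W = 0, N = 0, R = 0)
    lev[names(cfg$state_coupling)] <- cfg$state_coupling
    offset <- unname(lev[hyp$states[epoch_of]])
  }
  step <- ifelse(t > cfg$treatment_time_s,
                 1 - exp(-(t - cfg$treatment_time_s) / cfg$effect_onset_tau),
                 0)
  with_local_seed(cfg$seed, {
    mat <- matrix(0, n_frames, cfg$n_rois)
    for (r in seq_len(cfg$n_rois)) {
      mat[, r] <- cfg$baseline_level +
        cfg$noise_sd * (cfg$effect_size_z * step + offset) +
        rnorm(n_frames, 0, cfg$noise_sd)
    }
    raw <- roi_trace_set(mat, cfg$frame_rate)
    session <- session_zscore(raw,
                              treatment_time_s = cfg$treatment_time_s,
                              baseline_window = c(0, cfg$treatment_time_s))
    list(raw = raw, session = session,
         truth = list(effect_true = rep(cfg$effect_size_z, cfg$n_rois)))
  })
}

#' Configuration for synthetic microglia/bouton volumes
#'
#' @param shape_voxels integer `(z, y, x)` voxel counts.
#' @param voxel_size_um `(z, y, x)` physical voxel size in micrometres;
#'   default `c(1, 0.41, 0.41)` (light-sheet geometry: 1-um z step,
#'   0.41-um xy pixel).
#' @param n_spheres number of spherical "microglia".
#' @param radius_um `c(min, max)` sphere radius range in um.
#' @param n_boutons number of bouton points, uniform over the volume.
#' @param seed integer RNG seed.
#' @export
volume_synth_config <- function(shape_voxels,
                                voxel_size_um = c(1, 0.41, 0.41),
                                n_spheres = 10,
                                radius_um = c(3, 6),
                                n_boutons = 200,
                                seed = 0L) {
  shape_voxels <- as.numeric(unlist(shape_voxels))
  voxel_size_um <- as.numeric(unlist(voxel_size_um))
  radius_um <- as.numeric(unlist(radius_um))
  stopifnot(length(shape_voxels) == 3L, all(shape_voxels >= 1),
            length(voxel_size_um) == 3L, all(voxel_size_um > 0),
            n_spheres >= 0, n_boutons >= 0,
            length(radius_um) == 2L, all(radius_um > 0),
            radius_um[1] <= radius_um[2])
  ext <- (shape_voxels - 1) * voxel_size_um
  if (n_spheres > 0 && any(ext < 2 * radius_um[2]))
    stop("spheres of the requested radius cannot fit inside the volume")
  structure(list(shape_voxels = as.integer(shape_voxels),
                 voxel_size_um = as.numeric(voxel_size_um),
                 n_spheres = as.integer(n_spheres),
                 radius_um = radius_um, n_boutons = as.integer(n_boutons),
                 seed = as.integer(seed)),
            class = "volume_synth_config")
}

#' Generate a synthetic 3D microglia mask with bouton points
#'
#' Microglia are rasterized spheres on an anisotropic voxel grid (a voxel is
#' foreground if its centre lies inside any sphere); boutons are uniform
#' points in physical coordinates. The true minimal distance of each bouton
#' to the microglia surface is analytic: `max(0, |p - c| - r)` minimized
#' over spheres.
#'
#' @param cfg a [volume_synth_config()].
#' @return list with `scene` (a [volume_scene()]) and `truth` (list with
#'   `distances_true` in um and `spheres`, a data frame of centres/radii).
#' @export
gen_volume <- function(cfg) {
  stopifnot(inherits(cfg, "volume_synth_config"))
  if (cfg$n_spheres == 0L && cfg$n_boutons > 0L)
    stop("cannot request bouton distances in a scene with no microglia")
  dims <- cfg$shape_voxels            # (z, y, x)
  vs <- cfg$voxel_size_um
  ext <- (dims - 1) * vs
  with_local_seed(cfg$seed, {
    radii <- runif(cfg$n_spheres, cfg$radius_um[1], cfg$radius_um[2])
    centres <- matrix(0, cfg$n_spheres, 3L)   # (z, y, x) physical um
    for (i in seq_len(cfg$n_spheres))
      centres[i, ] <- vapply(1:3, function(a)
        runif(1, radii[i], ext[a] - radii[i]), 0)
    mask <- array(FALSE, dim = dims)
    zc <- (seq_len(dims[1]) - 1) * vs[1]
    yc <- (seq_len(dims[2]) - 1) * vs[2]
    xc <- (seq_len(dims[3]) - 1) * vs[3]
    for (i in seq_len(cfg$n_spheres)) {
      iz <- which(abs(zc - centres[i, 1]) <= radii[i])
      iy <- which(abs(yc - centres[i, 2]) <= radii[i])
      ix <- which(abs(xc - centres[i, 3]) <= radii[i])
      if (!length(iz) || !length(iy) || !length(ix)) next
      dz2 <- (zc[iz] - centres[i, 1])^2
      dy2 <- (yc[iy] - centres[i, 2])^2
      dx2 <- (xc[ix] - centres[i, 3])^2
      sub <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= radii[i]^2
      mask[iz, iy, ix] <- mask[iz, iy, ix] | sub
    }
    boutons <- data.frame(
      x_um = runif(cfg$n_boutons, 0, ext[3]),
      y_um = runif(cfg$n_boutons, 0, ext[2]),
      z_um = runif(cfg$n_boutons, 0, ext[1]))
    dtrue <- vapply(seq_len(cfg$n_boutons), function(b) {
      p <- c(boutons$z_um[b], boutons$y_um[b], boutons$x_um[b])
      min(pmax(0, sqrt(colSums((t(centres) - p)^2)) - radii))
    }, 0)
    list(scene = volume_scene(mask, vs, boutons),
         truth = list(distances_true = dtrue,
                      spheres = data.frame(z_um = centres[, 1],
                                           y_um = centres[, 2],
                                           x_um = centres[, 3],
                                           radius_um = radii)))
  })
}
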