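#' Sleep scoring from EEG/EMG
#'
#' Per-epoch FFT spectral features plus EMG amplitude are classified into
#' wake (W), NREM (N) and REM (R); consecutive epochs of the same state are
#' merged into episodes, from which time-in-state percentages, mean episode
#' durations and episode rates are computed.
#'
#' @name sleep
NULL

#' Per-epoch power spectral density of the EEG
#'
#' The recording is cut into non-overlapping epochs (a trailing partial
#' epoch is dropped) and each epoch gets a one-sided periodogram. With 5-s
#' epochs the frequency resolution is 0.2 Hz. Parseval holds: the PSD
#' integrated over frequency equals the epoch mean square.
#'
#' @param rec a [recording()].
#' @param epoch_s epoch length in seconds (default 5).
#' @return list of class `epoch_psd`: `psd` (epochs x frequencies matrix,
#'   uV^2/Hz), `freq` (Hz), `epoch_s`, `fs`.
#' @export
epoch_spectrogram <- function(rec, epoch_s = 5) {
  stopifnot(inherits(rec, "recording"))
  epoch_psd_series(rec$eeg, rec$fs, epoch_s)
}

# One-sided per-epoch periodogram of a series; trailing partial epoch
# dropped. Satisfies Parseval: sum(psd_row) * df = mean(epoch^2).
epoch_psd_series <- function(x, fs, epoch_s) {
  spe <- as.integer(round(epoch_s * fs))
  n_epochs <- floor(length(x) / spe)
  if (n_epochs < 1L) stop("recording shorter than one epoch")
  nf <- spe %/% 2L + 1L
  freq <- (seq_len(nf) - 1) * fs / spe
  psd <- matrix(0, n_epochs, nf)
  # one-sided scaling: double everything except DC (and Nyquist if present)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (spe %% 2L == 0L) dbl[nf] <- 1
  # batch the per-epoch FFTs through mvfft in chunks to bound memory
  chunk <- 256L
  for (i0 in seq(1L, n_epochs, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n_epochs)
    seg <- matrix(x[(idx[1] - 1L) * spe + seq_len(spe * length(idx))],
                  nrow = spe)
    xf <- stats::mvfft(seg)
    p <- (Mod(xf[seq_len(nf), , drop = FALSE])^2) / (fs * spe)
    psd[idx, ] <- t(p * dbl)
  }
  structure(list(psd = psd, freq = freq, epoch_s = epoch_s, fs = fs),
            class = "epoch_psd")
}

# Trapezoid integral of a sampled spectrum over [lo, hi], with linear
# interpolation at the band edges.
band_integral <- function(freq, dens, lo, hi) {
  if (hi > max(freq) || lo < min(freq))
    stop("band edges outside the sampled frequency range")
  inside <- freq > lo & freq < hi
  fgrid <- c(lo, freq[inside], hi)
  dgrid <- c(approx(freq, dens, lo)$y, dens[inside], approx(freq, dens, hi)$y)
  sum(diff(fgrid) * (head(dgrid, -1) + tail(dgrid, -1)) / 2)
}

# band_integral as a weight vector over the frequency grid (the integral is
# linear in the density), so many epochs reduce to one matrix product.
band_weights <- function(freq, lo, hi) {
  w <- numeric(length(freq))
  support <- which(freq >= lo - diff(freq[1:2]) & freq <= hi + diff(freq[1:2]))
  for (j in support) {
    e <- numeric(length(freq)); e[j] <- 1
    w[j] <- band_integral(freq, e, lo, hi)
  }
  w
}

#' Per-epoch scoring features
#'
#' Band powers are trapezoid integrals of the per-epoch PSD over delta
#' (0.5-4 Hz), theta (6-9 Hz) and 0-25 Hz. The EMG is band-passed to
#' 10-300 Hz (ideal per-epoch spectral band-pass) and summarized as
#' per-epoch RMS via Parseval.
#'
#' @param psd an `epoch_psd` from [epoch_spectrogram()].
#' @param emg EMG series covering the same span as the PSD epochs.
#' @param fs EMG sampling rate (Hz).
#' @param epoch_s epoch length (seconds); must match `psd`.
#' @param emg_band EMG band-pass edges in Hz.
#' @return data frame of class `epoch_features`: `epoch_index` (0-based),
#'   `power_delta`, `power_theta`, `power_total_0_25`, `theta_delta_ratio`,
#'   `emg_rms`.
#' @export
extract_features <- function(psd, emg, fs, epoch_s = psd$epoch_s,
                             emg_band = c(10, 300)) {
  stopifnot(inherits(psd, "epoch_psd"))
  if (abs(epoch_s - psd$epoch_s) > 1e-12)
    stop("epoch_s does not match the PSD epoching")
  n_epochs <- nrow(psd$psd)
  spe <- as.integer(round(epoch_s * fs))
  if (length(emg) < n_epochs * spe)
    stop("EMG does not cover the epoched span")
  hi <- min(emg_band[2], fs / 2 * 0.999)
  emg_psd <- epoch_psd_series(emg[seq_len(n_epochs * spe)], fs, epoch_s)
  w_emg <- band_weights(emg_psd$freq, emg_band[1], hi)
  emg_rms <- sqrt(pmax(0, as.numeric(emg_psd$psd %*% w_emg)))
  pd <- as.numeric(psd$psd %*% band_weights(psd$freq, 0.5, 4))
  pt <- as.numeric(psd$psd %*% band_weights(psd$freq, 6, 9))
  p25 <- as.numeric(psd$psd %*% band_weights(psd$freq, 0, 25))
  out <- data.frame(epoch_index = seq_len(n_epochs) - 1L,
                    power_delta = pd, power_theta = pt,
                    power_total_0_25 = p25,
                    theta_delta_ratio = ifelse(pd > 0, pt / pd, NA_real_),
                    emg_rms = emg_rms)
  class(out) <- c("epoch_features", "data.frame")
  out
}

# Midpoint (in log space) of a deterministic 2-class 1-D k-means of
# log EMG RMS; used as the default wake gate.
emg_threshold_kmeans <- function(emg_rms) {
  lx <- log(pmax(emg_rms, .Machine$double.eps))
  if (length(unique(lx)) < 2L) return(exp(max(lx) + 1))
  init <- matrix(quantile(lx, c(0.25, 0.75), names = FALSE), ncol = 1)
  if (diff(init) < 1e-12) init[2, 1] <- init[2, 1] + 1e-6
  km <- kmeans(matrix(lx, ncol = 1), centers = init)
  exp(mean(range(km$centers)))
}

#' Classify epochs into wake/NREM/REM
#'
#' Decision rule per epoch: high EMG -> W; else theta/delta ratio above
#' `ratio_threshold` -> R; else N. The EMG threshold defaults to the
#' midpoint of a 2-class clustering of log EMG RMS. An optional smoothing
#' pass relabels isolated single-epoch states flanked by identical states.
#' Epochs with non-finite features are labeled W with a warning.
#'
#' @param features an `epoch_features` data frame.
#' @param emg_threshold EMG RMS wake gate; `NULL` (default) = data-driven.
#' @param ratio_threshold theta/delta REM gate (default 1.5).
#' @param smooth relabel isolated single epochs (default `TRUE`).
#' @param override optional data frame (`epoch_index`, `state`) of manual
#'   corrections applied last (0-based indices).
#' @param epoch_s epoch length for the returned hypnogram.
#' @return a [hypnogram()].
#' @export
classify_epochs <- function(features, emg_threshold = NULL,
                            ratio_threshold = 1.5, smooth = TRUE,
                            override = NULL, epoch_s = 5) {
  stopifnot(nrow(features) >= 1L, is.finite(ratio_threshold))
  bad <- !is.finite(features$emg_rms) | !is.finite(features$theta_delta_ratio)
  if (any(bad))
    warning(sum(bad), " epoch(s) with non-finite features labeled W")
  if (is.null(emg_threshold))
    emg_threshold <- emg_threshold_kmeans(features$emg_rms[!bad])
  if (!is.finite(emg_threshold)) stop("emg_threshold must be finite")
  s <- ifelse(features$emg_rms > emg_threshold, "W",
              ifelse(features$theta_delta_ratio > ratio_threshold, "R", "N"))
  s[bad] <- "W"
  if (smooth && length(s) >= 3L) {
    for (i in 2:(length(s) - 1L))
      if (s[i] != s[i - 1L] && s[i - 1L] == s[i + 1L]) s[i] <- s[i - 1L]
  }
  if (!is.null(override)) {
    stopifnot(all(c("epoch_index", "state") %in% names(override)))
    idx <- override$epoch_index + 1L
    if (any(idx < 1L | idx > length(s)))
      stop("override epoch_index out of range")
    s[idx] <- as.character(override$state)
  }
  hypnogram(s, epoch_s)
}

#' Score a recording end to end
#'
#' Convenience wrapper: [epoch_spectrogram()] + [extract_features()] +
#' [classify_epochs()].
#'
#' @param rec a [recording()].
#' @param epoch_s epoch length (default 5 s).
#' @param ... passed to [classify_epochs()].
#' @return a [hypnogram()].
#' @export
score_recording <- function(rec, epoch_s = 5, ...) {
  psd <- epoch_spectrogram(rec, epoch_s)
  feats <- extract_features(psd, rec$emg, rec$fs, epoch_s)
  classify_epochs(feats, epoch_s = epoch_s, ...)
}

#' Merge consecutive same-state epochs into episodes
#'
#' @param h a [hypnogram()].
#' @return data frame `state`, `start_s`, `duration_s`; episodes tile the
#'   session exactly and adjacent episodes differ in state.
#' @export
merge_episodes <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  r <- rle(h$states)
  ends <- cumsum(r$lengths)
  data.frame(state = r$values,
             start_s = (ends - r$lengths) * h$epoch_s,
             duration_s = r$lengths * h$epoch_s)
}

#' Brain-state metrics: time percentages, episode durations and rates
#'
#' @param h a [hypnogram()].
#' @param bin_s time-bin length for state percentages; must be a multiple of
#'   the epoch length (default 1800 s = 30 min). A trailing partial bin is
#'   summarized over the epochs it contains.
#' @return list of class `state_metrics`: `percent_time` (data frame
#'   `bin_start_s`, `state`, `percent`; per-bin percentages sum to 100),
#'   `mean_episode_duration_s` (named per state; `NA` if the state is
#'   absent), `episodes_per_hour` (named per state; 0 if absent).
#' @export
state_metrics <- function(h, bin_s = 1800) {
  stopifnot(inherits(h, "hypnogram"))
  if (bin_s < h$epoch_s) stop("bin_s must be at least one epoch")
  if (abs(bin_s / h$epoch_s - round(bin_s / h$epoch_s)) > 1e-9)
    stop("bin_s must be an integer multiple of epoch_s")
  epb <- as.integer(round(bin_s / h$epoch_s))
  n <- length(h$states)
  bin_of <- (seq_len(n) - 1L) %/% epb
  pt <- do.call(rbind, lapply(unique(bin_of), function(b) {
    sb <- h$states[bin_of == b]
    data.frame(bin_start_s = b * bin_s, state = STATES,
               percent = 100 * as.numeric(
                 table(factor(sb, levels = STATES))) / length(sb))
  }))
  ep <- merge_episodes(h)
  hours <- n * h$epoch_s / 3600
  med <- vapply(STATES, function(s) {
    d <- ep$duration_s[ep$state == s]
    if (length(d)) mean(d) else NA_real_
  }, 0)
  rate <- vapply(STATES, function(s) sum(ep$state == s) / hours, 0)
  structure(list(percent_time = pt, mean_episode_duration_s = med,
                 episodes_per_hour = rate),
            class = "state_metrics")
}

#' State-conditioned normalized EEG spectrum
#'
#' Mean per-epoch PSD over all epochs scored as `state`, normalized so its
#' integral over 0-25 Hz is 1.
#'
#' @param rec a [recording()].
#' @param h the recording's [hypnogram()].
#' @param state `"W"`, `"N"` or `"R"`.
#' @param epoch_s epoch length; must match `h`.
#' @return data frame `freq_hz`, `density` restricted to 0-25 Hz.
#' @export
normalized_spectrum <- function(rec, h, state, epoch_s = h$epoch_s) {
  stopifnot(inherits(rec, "recording"), inherits(h, "hypnogram"))
  assert_state(state)
  psd <- epoch_spectrogram(rec, epoch_s)
  n <- min(nrow(psd$psd), length(h$states))
  sel <- which(h$states[seq_len(n)] == state)
  if (!length(sel))
    stop("state ", state, " absent from the hypnogram")
  m <- colMeans(psd$psd[sel, , drop = FALSE])
  keep <- psd$freq <= 25
  total <- band_integral(psd$freq, m, 0, 25)
  data.frame(freq_hz = psd$freq[keep], density = m[keep] / total)
}
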