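# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most direct route available (brute force, closed form)
# rather than calling the implementation under test.

# Greedy one-to-one matching of detected to true event onsets within a
# frame tolerance; returns true/false positive/negative counts.
match_events <- function(events, truth, frame_rate, tol_frames = 2) {
  if (nrow(events) == 0)
    return(c(tp = 0, fp = 0, fn = nrow(truth)))
  used <- rep(FALSE, nrow(truth))
  tp <- 0
  for (i in seq_len(nrow(events))) {
    d <- abs(events$onset_s[i] - truth$onset_s) * frame_rate
    j <- which(!used & d <= tol_frames)
    if (length(j)) {
      used[j[which.min(d[j])]] <- TRUE
      tp <- tp + 1
    }
  }
  c(tp = tp, fp = nrow(events) - tp, fn = sum(!used))
}

# Detection precision/recall of the full calcium path on one generated set.
benchmark_detection <- function(ca, n_sd = 3, min_frames = 3) {
  tot <- c(tp = 0, fp = 0, fn = 0)
  fr <- ca$traces$frame_rate
  for (r in seq_len(ncol(ca$traces$traces))) {
    tr <- ca$traces$traces[, r]
    f0 <- sliding_baseline(tr, frame_rate = fr)
    ev <- detect_events(compute_dff(tr, f0, frame_rate = fr),
                        n_sd = n_sd, min_frames = min_frames)
    tru <- ca$truth$events_true[ca$truth$events_true$roi == r, , drop = FALSE]
    tot <- tot + match_events(ev, tru, fr)
  }
  c(precision = tot[["tp"]] / max(1, tot[["tp"]] + tot[["fp"]]),
    recall = tot[["tp"]] / max(1, tot[["tp"]] + tot[["fn"]]))
}

# Direct per-epoch band power from the raw signal (rectangle-rule
# periodogram), independent of the package's spectrogram path.
oracle_epoch_band_power <- function(x, fs, epoch_s, lo, hi) {
  spe <- round(epoch_s * fs)
  n_epochs <- floor(length(x) / spe)
  vapply(seq_len(n_epochs), function(e) {
    seg <- x[(e - 1) * spe + seq_len(spe)]
    p <- Mod(fft(seg))^2 / (fs * spe)
    f <- (seq_along(p) - 1) * fs / spe
    sel <- f >= lo & f <= hi
    2 * sum(p[sel]) * fs / spe
  }, 0)
}

# Brute-force minimal distance from each bouton's exact position to every
# foreground voxel centre; boutons whose containing voxel is foreground
# count as inside (0), matching the module's convention.
oracle_min_distances <- function(scene) {
  d <- dim(scene$mask)
  vs <- scene$voxel_size_um
  fg <- which(scene$mask, arr.ind = TRUE)  # 1-based (z, y, x)
  fg_phys <- sweep(fg - 1, 2, vs, `*`)
  vapply(seq_len(nrow(scene$boutons)), function(i) {
    p <- c(scene$boutons$z_um[i], scene$boutons$y_um[i],
           scene$boutons$x_um[i])
    vox <- pmin(pmax(round(p / vs), 0), d - 1)
    if (scene$mask[vox[1] + 1, vox[2] + 1, vox[3] + 1]) return(0)
    sqrt(min(colSums((t(fg_phys) - p)^2)))
  }, 0)
}

# Independent episode-boundary scan for transition finding.
oracle_transitions <- function(h, from, to, min_flank_s) {
  s <- h$states
  out <- numeric()
  n <- length(s)
  run_len <- function(i, dir) {
    # length of the run of identical labels containing epoch i
    j <- i
    while (j + dir >= 1 && j + dir <= n && s[j + dir] == s[i]) j <- j + dir
    abs(j - i) + 1
  }
  for (i in seq_len(n - 1)) {
    if (s[i] == from && s[i + 1] == to &&
        run_len(i, -1L) * h$epoch_s >= min_flank_s &&
        run_len(i + 1, 1L) * h$epoch_s >= min_flank_s)
      out <- c(out, i * h$epoch_s)
  }
  out
}

# Small helper: a hypnogram built from a run-length description like
# list(c("N", 12), c("W", 6)).
hyp_from_runs <- function(runs, epoch_s = 5) {
  hypnogram(unlist(lapply(runs, function(r) rep(r[[1]], as.integer(r[[2]])))),
            epoch_s)
}
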