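#' Calcium trace normalization and transient detection
#'
#' ROI fluorescence is normalized to dF/F against a sliding lower-quartile
#' baseline (F0 = 0.25-quantile in a +/-600-s window), z-scored against a
#' designated baseline period, and scanned for transients crossing a
#' threshold of 3 SD above the mean dF/F sustained over three frames.
#'
#' @name calcium
NULL

#' Sliding-quantile baseline (F0)
#'
#' For every frame, F0 is the `quantile` (linear-interpolation definition)
#' of the fluorescence within a window of `half_window_s` seconds on each
#' side; windows are truncated (not reflected) at the trace edges.
#'
#' @param trace a [roi_trace()] or numeric vector.
#' @param half_window_s half window width in seconds (default 600).
#' @param quantile baseline quantile (default 0.25, the lower quartile).
#' @param frame_rate required when `trace` is a bare numeric.
#' @return numeric F0 series, one value per frame.
#' @export
sliding_baseline <- function(trace, half_window_s = 600, quantile = 0.25,
                             frame_rate = NULL) {
  x <- trace_values(trace)
  fr <- trace_rate(trace, frame_rate)
  if (length(x) < 2L) stop("trace must have at least 2 frames")
  if (all(x <= 0))
    stop("fluorescence is non-positive everywhere; dF/F undefined")
  w <- as.integer(round(half_window_s * fr))
  .sliding_quantile_cpp(x, w, quantile)
}

#' Compute dF/F from fluorescence and baseline
#'
#' @param trace a [roi_trace()] or numeric vector.
#' @param f0 baseline series from [sliding_baseline()]; must be positive.
#' @param frame_rate required when `trace` is a bare numeric.
#' @return list of class `dff_trace`: `dff`, `f0`, `frame_rate`.
#' @export
compute_dff <- function(trace, f0, frame_rate = NULL) {
  x <- trace_values(trace)
  fr <- trace_rate(trace, frame_rate)
  if (length(f0) != length(x)) stop("f0 and trace lengths differ")
  if (any(f0 <= 0)) stop("f0 must be positive everywhere")
  structure(list(dff = (x - f0) / f0, f0 = f0, frame_rate = fr),
            class = "dff_trace")
}

#' Z-score a trace against a baseline period
#'
#' `z = (x - mean) / sd`, with mean and SD (n-1 denominator) taken over the
#' frames inside `baseline_window`.
#'
#' @param trace a [roi_trace()] or numeric vector.
#' @param baseline_window `(start_s, end_s)` of the baseline period.
#' @param frame_rate required when `trace` is a bare numeric.
#' @return numeric z-score series.
#' @export
zscore_trace <- function(trace, baseline_window, frame_rate = NULL) {
  x <- trace_values(trace)
  fr <- trace_rate(trace, frame_rate)
  t <- (seq_along(x) - 1) / fr
  sel <- t >= baseline_window[1] & t < baseline_window[2]
  if (sum(sel) < 2L) stop("baseline window must contain at least 2 frames")
  m <- mean(x[sel]); s <- sd(x[sel])
  if (s == 0) stop("zero variance in the baseline window")
  (x - m) / s
}

#' Detect calcium transients by sustained threshold crossing
#'
#' The detection threshold sits `n_sd` standard deviations above the centre
#' of the whole dF/F trace. By default (`scale = "robust"`) the centre is
#' the trace median and the SD is the noise SD estimated from the median
#' absolute deviation of the first differences
#' (`1.4826 * MAD(diff(dff)) / sqrt(2)`); on an event-free trace these
#' coincide with the mean and SD, while on active traces they keep the
#' transients themselves from inflating the threshold. `scale = "moment"`
#' uses the plain whole-trace mean and SD instead.
#'
#' An event is a maximal run of at least `min_frames` consecutive frames
#' above threshold; runs separated by one or more subthreshold frames are
#' distinct events. With `variant = "moving_average"` the run criterion is
#' applied to the `min_frames`-frame moving average of dF/F instead.
#'
#' @param d a `dff_trace` from [compute_dff()].
#' @param n_sd threshold in SD units (default 3).
#' @param min_frames minimum run length in frames (default 3).
#' @param variant `"run"` (default) or `"moving_average"`.
#' @param scale `"robust"` (default) or `"moment"` threshold estimation.
#' @return data frame of class `ca_events`: `onset_frame`, `peak_frame`
#'   (1-based), `onset_s`, `peak_s`, `amplitude` (peak dF/F),
#'   `duration_s`. Zero-variance dF/F yields zero events with a warning.
#' @export
detect_events <- function(d, n_sd = 3, min_frames = 3L,
                          variant = c("run", "moving_average"),
                          scale = c("robust", "moment")) {
  stopifnot(inherits(d, "dff_trace"))
  variant <- match.arg(variant)
  scale <- match.arg(scale)
  dff <- d$dff
  if (length(dff) < min_frames) stop("trace shorter than min_frames")
  if (scale == "robust") {
    centre <- median(dff)
    s <- 1.4826 * median(abs(diff(dff) - median(diff(dff)))) / sqrt(2)
  } else {
    centre <- mean(dff)
    s <- sd(dff)
  }
  empty <- data.frame(onset_frame = integer(), peak_frame = integer(),
                      onset_s = numeric(), peak_s = numeric(),
                      amplitude = numeric(), duration_s = numeric())
  class(empty) <- c("ca_events", "data.frame")
  if (s == 0) {
    warning("zero-variance dF/F; no events detected")
    return(empty)
  }
  theta <- centre + n_sd * s
  crit <- if (variant == "run") dff else
    as.numeric(stats::filter(dff, rep(1 / min_frames, min_frames),
                             sides = 1))
  above <- !is.na(crit) & crit > theta
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_frames)
  if (variant == "moving_average")
    keep <- which(r$values)  # the averaging already spans min_frames
  if (!length(keep)) return(empty)
  out <- do.call(rbind, lapply(keep, function(i) {
    a <- starts[i]; b <- ends[i]
    pk <- a - 1L + which.max(dff[a:b])
    data.frame(onset_frame = a, peak_frame = pk,
               onset_s = (a - 1L) / d$frame_rate,
               peak_s = (pk - 1L) / d$frame_rate,
               amplitude = dff[pk],
               duration_s = (b - a + 1L) / d$frame_rate)
  }))
  class(out) <- c("ca_events", "data.frame")
  out
}

#' Windowed event statistics
#'
#' @param events a `ca_events` data frame from [detect_events()].
#' @param z z-scored trace (same frame base as the events).
#' @param frame_rate frames per second.
#' @param window `(start_s, end_s)` analysis window (half-open).
#' @return list of class `event_stats`: `mean_level_z`, `amp_mean` (`NA` if
#'   no event peaks in the window), `freq_per_min`, `window`. Events are
#'   assigned to the window by peak time.
#' @export
event_stats <- function(events, z, frame_rate, window) {
  if (window[2] <= window[1]) stop("empty analysis window")
  t <- (seq_along(z) - 1) / frame_rate
  if (window[1] < 0 || window[2] > t[length(t)] + 1 / frame_rate)
    stop("window outside the trace span")
  inwin <- t >= window[1] & t < window[2]
  pk <- events$peak_s >= window[1] & events$peak_s < window[2]
  minutes <- (window[2] - window[1]) / 60
  structure(list(
    mean_level_z = mean(z[inwin]),
    amp_mean = if (any(pk)) mean(events$amplitude[pk]) else NA_real_,
    freq_per_min = sum(pk) / minutes,
    window = window), class = "event_stats")
}

#' Before/after differences of event statistics
#'
#' @param before,after `event_stats` for the pre- and post-treatment
#'   windows of the same ROI.
#' @return list: `d_mean_level_z`, `d_amp_mean` (NA-propagating),
#'   `d_freq_per_min`, each `after - before`.
#' @export
pre_post_change <- function(before, after) {
  stopifnot(inherits(before, "event_stats"), inherits(after, "event_stats"))
  list(d_mean_level_z = after$mean_level_z - before$mean_level_z,
       d_amp_mean = after$amp_mean - before$amp_mean,
       d_freq_per_min = after$freq_per_min - before$freq_per_min)
}
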