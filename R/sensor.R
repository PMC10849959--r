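#' GRAB-sensor pharmacology quantification
#'
#' Sensor sessions are z-scored per ROI against the pre-treatment baseline,
#' averaged into a session trace, and quantified by window contrasts: the
#' local-drug rule compares [-20, 0] vs [40, 60] min around the treatment;
#' the systemic-injection rule compares the 20-120 min post window against
#' the z-scoring baseline itself.
#'
#' @name sensor
NULL

#' Z-score raw sensor ROIs into a session
#'
#' Each ROI is z-scored against its own mean and SD over `baseline_window`;
#' zero-variance ROIs are dropped with a warning (an error if none remain).
#' The session trace is the unweighted mean of ROI z-scores.
#'
#' @param raw a [roi_trace_set()] of raw fluorescence.
#' @param treatment_time_s treatment timestamp (seconds).
#' @param baseline_window `(start_s, end_s)`; default `(0, treatment)`.
#' @param treatment_label free-text label.
#' @return a [sensor_session()].
#' @export
session_zscore <- function(raw, treatment_time_s,
                           baseline_window = c(0, treatment_time_s),
                           treatment_label = "") {
  stopifnot(inherits(raw, "roi_trace_set"))
  t <- raw$time_s
  sel <- t >= baseline_window[1] & t < baseline_window[2]
  if (sum(sel) < 2L) stop("baseline window must contain at least 2 frames")
  keep <- logical(ncol(raw$traces))
  z <- matrix(0, nrow(raw$traces), ncol(raw$traces))
  for (r in seq_len(ncol(raw$traces))) {
    m <- mean(raw$traces[sel, r]); s <- sd(raw$traces[sel, r])
    if (s == 0) {
      warning("dropping zero-variance ROI ", raw$roi_ids[r])
      next
    }
    keep[r] <- TRUE
    z[, r] <- (raw$traces[, r] - m) / s
  }
  if (!any(keep)) stop("all ROIs have zero baseline variance")
  sensor_session(z[, keep, drop = FALSE], raw$frame_rate, treatment_time_s,
                 treatment_label, baseline_window)
}

window_mean <- function(s, win_s) {
  t <- s$time_s
  sel <- t >= win_s[1] & t < win_s[2]
  if (!any(sel))
    stop("window [", win_s[1], ", ", win_s[2], "] s outside the recording")
  if (win_s[1] < 0 || win_s[2] > t[length(t)] + 1 / s$frame_rate)
    stop("window [", win_s[1], ", ", win_s[2],
         "] s not covered by the recording")
  mean(s$session_z[sel])
}

#' Window-contrast delta z-score
#'
#' `delta_z = mean(session z in post) - mean(session z in pre)`, with
#' windows in minutes relative to the treatment time. Defaults follow the
#' local-drug rule: pre [-20, 0], post [40, 60] min.
#'
#' @param s a [sensor_session()].
#' @param pre_min,post_min `(start, end)` in minutes relative to treatment.
#' @return list of class `window_contrast`: `delta_z`, `pre_window_min`,
#'   `post_window_min`, `treatment_label`.
#' @export
delta_z <- function(s, pre_min = c(-20, 0), post_min = c(40, 60)) {
  stopifnot(inherits(s, "sensor_session"))
  if (pre_min[2] > 0 || post_min[1] < 0 ||
      pre_min[1] >= pre_min[2] || post_min[1] >= post_min[2])
    stop("windows must be non-degenerate with pre end <= 0 <= post start")
  pre_s <- s$treatment_time_s + pre_min * 60
  post_s <- s$treatment_time_s + post_min * 60
  structure(list(delta_z = window_mean(s, post_s) - window_mean(s, pre_s),
                 pre_window_min = pre_min, post_window_min = post_min,
                 treatment_label = s$treatment_label),
            class = "window_contrast")
}

#' Injection-style delta z-score against the session baseline
#'
#' `delta_z = mean(session z in the post window) - mean(session z in the
#' z-scoring baseline window)`. Default post window 20-120 min after
#' treatment (systemic-injection rule).
#'
#' @param s a [sensor_session()] carrying its `baseline_window`.
#' @param post_min `(start, end)` in minutes relative to treatment.
#' @return a `window_contrast` (pre window reported in minutes relative to
#'   treatment).
#' @export
delta_z_injection <- function(s, post_min = c(20, 120)) {
  stopifnot(inherits(s, "sensor_session"))
  if (is.null(s$baseline_window))
    stop("session does not carry a z-scoring baseline window")
  post_s <- s$treatment_time_s + post_min * 60
  pre_min <- (s$baseline_window - s$treatment_time_s) / 60
  structure(list(delta_z = window_mean(s, post_s) -
                   window_mean(s, s$baseline_window),
                 pre_window_min = pre_min, post_window_min = post_min,
                 treatment_label = s$treatment_label),
            class = "window_contrast")
}

#' @export
print.window_contrast <- function(x, ...) {
  cat(sprintf(
    "<window_contrast> delta z = %.3f (pre [%g, %g] min, post [%g, %g] min)%s\n",
    x$delta_z, x$pre_window_min[1], x$pre_window_min[2],
    x$post_window_min[1], x$post_window_min[2],
    if (nzchar(x$treatment_label)) paste0(" - ", x$treatment_label) else ""))
  invisible(x)
}
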