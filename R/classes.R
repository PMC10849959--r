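#' EEG/EMG recording
#'
#' @param eeg numeric EEG voltage series (uV).
#' @param emg numeric EMG voltage series (uV), same length as `eeg`.
#' @param fs sampling rate in Hz.
#' @param start_time_s recording start time in seconds.
#' @return a `recording` object.
#' @export
recording <- function(eeg, emg, fs, start_time_s = 0) {
  eeg <- as.numeric(eeg); emg <- as.numeric(emg)
  if (length(eeg) != length(emg))
    stop("eeg and emg must have the same length")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  structure(list(eeg = eeg, emg = emg, fs = fs,
                 start_time_s = start_time_s),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d samples @ %g Hz (%.1f min), start %g s\n",
              length(x$eeg), x$fs, length(x$eeg) / x$fs / 60,
              x$start_time_s))
  invisible(x)
}

#' Hypnogram: one brain-state label per scoring epoch
#'
#' @param states character vector over `c("W", "N", "R")`.
#' @param epoch_s epoch length in seconds (default 5).
#' @return a `hypnogram` object.
#' @export
hypnogram <- function(states, epoch_s = 5) {
  states <- as.character(states)
  if (length(states) < 1L) stop("hypnogram must be nonempty")
  if (!all(states %in% STATES))
    stop("states must be coded W, N or R")
  if (epoch_s <= 0) stop("epoch_s must be positive")
  structure(list(states = states, epoch_s = epoch_s), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$states, levels = STATES))
  cat(sprintf("<hypnogram> %d x %g-s epochs (W %d, N %d, R %d)\n",
              length(x$states), x$epoch_s, tab["W"], tab["N"], tab["R"]))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$states)

#' Set of ROI fluorescence traces on a common time base
#'
#' @param traces numeric matrix, one column per ROI, one row per frame.
#' @param frame_rate frames per second.
#' @param roi_ids optional ROI identifiers (default `roi1..roiK`).
#' @param compartment optional per-ROI compartment labels
#'   (`"soma"`/`"process"`).
#' @param cell_id optional per-ROI parent-cell identifiers.
#' @return a `roi_trace_set` object.
#' @export
roi_trace_set <- function(traces, frame_rate, roi_ids = NULL,
                          compartment = NULL, cell_id = NULL) {
  traces <- as.matrix(traces)
  if (!all(is.finite(traces))) stop("trace values must be finite")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  k <- ncol(traces)
  if (is.null(roi_ids)) roi_ids <- paste0("roi", seq_len(k))
  if (length(roi_ids) != k) stop("one roi_id per column required")
  if (!is.null(compartment) && length(compartment) != k)
    stop("one compartment label per ROI required")
  if (!is.null(cell_id) && length(cell_id) != k)
    stop("one cell_id per ROI required")
  colnames(traces) <- roi_ids
  structure(list(traces = traces, frame_rate = frame_rate,
                 time_s = (seq_len(nrow(traces)) - 1) / frame_rate,
                 roi_ids = roi_ids, compartment = compartment,
                 cell_id = cell_id),
            class = "roi_trace_set")
}

#' @export
print.roi_trace_set <- function(x, ...) {
  cat(sprintf("<roi_trace_set> %d ROIs x %d frames @ %g Hz (%.1f min)\n",
              ncol(x$traces), nrow(x$traces), x$frame_rate,
              nrow(x$traces) / x$frame_rate / 60))
  invisible(x)
}

#' Single-ROI fluorescence trace
#'
#' @param values fluorescence per frame (a.u.).
#' @param frame_rate frames per second.
#' @param roi_id identifier.
#' @param compartment `"soma"` or `"process"`.
#' @param cell_id parent cell identifier.
#' @return a `roi_trace` object.
#' @export
roi_trace <- function(values, frame_rate, roi_id = "roi1",
                      compartment = c("process", "soma"), cell_id = NA) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("trace values must be finite")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  compartment <- match.arg(compartment)
  structure(list(values = values, frame_rate = frame_rate, roi_id = roi_id,
                 compartment = compartment, cell_id = cell_id),
            class = "roi_trace")
}

# Accept either a roi_trace or a bare numeric + frame_rate.
trace_values <- function(trace) {
  if (inherits(trace, "roi_trace")) trace$values else as.numeric(trace)
}
trace_rate <- function(trace, frame_rate = NULL) {
  if (inherits(trace, "roi_trace")) trace$frame_rate
  else if (!is.null(frame_rate)) frame_rate
  else stop("frame_rate required for a bare numeric trace")
}

#' Z-scored GRAB-sensor session
#'
#' @param roi_z numeric matrix of per-ROI z-scored traces (frames x ROIs).
#' @param frame_rate frames per second.
#' @param treatment_time_s treatment timestamp, seconds from recording start.
#' @param treatment_label free-text treatment description.
#' @param baseline_window `(start_s, end_s)` of the z-scoring baseline.
#' @return a `sensor_session`; `$session_z` is the unweighted mean across
#'   ROIs.
#' @export
sensor_session <- function(roi_z, frame_rate, treatment_time_s,
                           treatment_label = "", baseline_window = NULL) {
  roi_z <- as.matrix(roi_z)
  if (ncol(roi_z) < 1L) stop("at least one ROI required")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  dur <- nrow(roi_z) / frame_rate
  if (!(treatment_time_s > 0 && treatment_time_s < dur))
    stop("treatment time must lie inside the recording")
  structure(list(roi_z = roi_z,
                 session_z = rowMeans(roi_z),
                 frame_rate = frame_rate,
                 time_s = (seq_len(nrow(roi_z)) - 1) / frame_rate,
                 treatment_time_s = treatment_time_s,
                 treatment_label = treatment_label,
                 baseline_window = baseline_window),
            class = "sensor_session")
}

#' @export
print.sensor_session <- function(x, ...) {
  cat(sprintf(
    "<sensor_session> %d ROIs x %d frames @ %g Hz; treatment '%s' at %g s\n",
    ncol(x$roi_z), nrow(x$roi_z), x$frame_rate, x$treatment_label,
    x$treatment_time_s))
  invisible(x)
}

#' 3D microglia mask plus bouton point set
#'
#' Axis order is `(z, y, x)` throughout; physical coordinates are in
#' micrometres with the origin at the centre of voxel `(0, 0, 0)`.
#'
#' @param mask 3D logical array `(z, y, x)`, `TRUE` = microglia.
#' @param voxel_size_um `(z, y, x)` voxel size in um.
#' @param boutons data frame with columns `x_um`, `y_um`, `z_um`.
#' @return a `volume_scene` object.
#' @export
volume_scene <- function(mask, voxel_size_um, boutons) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("voxel_size_um must be three positive values (z, y, x)")
  if (!all(c("x_um", "y_um", "z_um") %in% names(boutons)))
    stop("boutons must have columns x_um, y_um, z_um")
  structure(list(mask = mask, voxel_size_um = as.numeric(voxel_size_um),
                 boutons = as.data.frame(boutons)),
            class = "volume_scene")
}

#' @export
print.volume_scene <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<volume_scene> %d x %d x %d voxels (z,y,x) @ (%g, %g, %g) um; %d foreground voxels; %d boutons\n",
    d[1], d[2], d[3], x$voxel_size_um[1], x$voxel_size_um[2],
    x$voxel_size_um[3], sum(x$mask), nrow(x$boutons)))
  invisible(x)
}
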