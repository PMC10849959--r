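#' Readers and writers for the pipeline's plain-text formats
#'
#' CSV with JSON sidecars is the canonical interchange: recordings are
#' two-column CSVs (`eeg`, `emg`) with fs in the sidecar; trace tables are
#' `time_s` plus one column per ROI; hypnograms are
#' `epoch_index,start_s,state`; volumes are multi-page TIFF masks plus a
#' bouton CSV (`x_um,y_um,z_um`) and a voxel-size sidecar.
#'
#' @name io
NULL

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' @rdname io
#' @param rec a [recording()].
#' @param path CSV path; a `.json` sidecar is written next to it.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  write.csv(data.frame(eeg = rec$eeg, emg = rec$emg), path,
            row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, start_time_s = rec$start_time_s,
                            channels = c("eeg", "emg")),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  d <- read.csv(path)
  recording(d$eeg, d$emg, fs = meta$fs,
            start_time_s = if (is.null(meta$start_time_s)) 0
            else meta$start_time_s)
}

#' @rdname io
#' @param h a [hypnogram()].
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  n <- length(h$states)
  write.csv(data.frame(epoch_index = seq_len(n) - 1L,
                       start_s = (seq_len(n) - 1L) * h$epoch_s,
                       state = h$states),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_hypnogram <- function(path) {
  d <- read.csv(path, colClasses = c(state = "character"))
  epoch_s <- if (nrow(d) > 1L) d$start_s[2] - d$start_s[1] else 5
  hypnogram(d$state, epoch_s)
}

#' @rdname io
#' @param ts a [roi_trace_set()].
#' @export
write_traces <- function(ts, path) {
  stopifnot(inherits(ts, "roi_trace_set"))
  write.csv(cbind(data.frame(time_s = ts$time_s),
                  as.data.frame(ts$traces)),
            path, row.names = FALSE)
  jsonlite::write_json(
    list(frame_rate = ts$frame_rate, roi_ids = ts$roi_ids,
         compartment = ts$compartment, cell_id = ts$cell_id),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname io
#' @export
read_traces <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  d <- read.csv(path)
  roi_trace_set(as.matrix(d[, -1, drop = FALSE]), meta$frame_rate,
                roi_ids = meta$roi_ids, compartment = meta$compartment,
                cell_id = meta$cell_id)
}

#' @rdname io
#' @param scene a [volume_scene()].
#' @param mask_path multi-page TIFF path (8-bit, 0/255, one page per z).
#' @param boutons_path bouton CSV path (`x_um,y_um,z_um`); voxel sizes go
#'   in the mask's JSON sidecar.
#' @export
write_volume <- function(scene, mask_path, boutons_path) {
  stopifnot(inherits(scene, "volume_scene"))
  pages <- lapply(seq_len(dim(scene$mask)[1]), function(iz)
    matrix(as.numeric(scene$mask[iz, , ]), dim(scene$mask)[2],
           dim(scene$mask)[3]))
  tiff::writeTIFF(pages, mask_path, bits.per.sample = 8L)
  write.csv(scene$boutons[, c("x_um", "y_um", "z_um")], boutons_path,
            row.names = FALSE)
  jsonlite::write_json(list(voxel_size_um = scene$voxel_size_um,
                            axis_order = c("z", "y", "x")),
                       sidecar_path(mask_path), auto_unbox = TRUE,
                       digits = NA)
  invisible(mask_path)
}

#' @rdname io
#' @export
read_volume <- function(mask_path, boutons_path) {
  meta <- jsonlite::read_json(sidecar_path(mask_path),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(mask_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  mask <- array(FALSE, dim = d)
  for (iz in seq_along(pages)) mask[iz, , ] <- pages[[iz]] > 0.5
  volume_scene(mask, meta$voxel_size_um, read.csv(boutons_path))
}

#' @rdname io
#' @param truth a ground-truth list from a generator.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  if (!is.null(out$hypnogram_true))
    out$hypnogram_true <- list(states = out$hypnogram_true$states,
                               epoch_s = out$hypnogram_true$epoch_s)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
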