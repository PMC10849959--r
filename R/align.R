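#' State-conditioned and transition-triggered trace summaries
#'
#' Any z-scored trace can be summarized per brain state or averaged around
#' hypnogram state transitions. Frames map to epochs by
#' `floor(time / epoch_s)` under the half-open epoch convention.
#'
#' @name align
NULL

frame_states <- function(n_frames, frame_rate, h) {
  t <- (seq_len(n_frames) - 1) / frame_rate
  idx <- floor(t / h$epoch_s) + 1L
  if (max(idx) > length(h$states))
    stop("hypnogram does not cover the trace span")
  h$states[idx]
}

#' Mean of a trace within one brain state
#'
#' @param z numeric z-scored trace.
#' @param frame_rate frames per second.
#' @param h a [hypnogram()] covering the trace.
#' @param state target state (`"W"`, `"N"` or `"R"`).
#' @param exclude states whose frames are discarded before averaging
#'   (default `"R"`: REM is excluded from calcium comparisons).
#' @return mean of `z` over frames labeled `state`; `NA` if the state is
#'   absent (or excluded).
#' @export
state_mean <- function(z, frame_rate, h, state, exclude = "R") {
  assert_state(state)
  fs <- frame_states(length(z), frame_rate, h)
  keep <- !(fs %in% exclude) & fs == state
  if (!any(keep)) return(NA_real_)
  mean(z[keep])
}

#' Find qualifying state transitions in a hypnogram
#'
#' A transition qualifies when an episode of `from_state` lasting at least
#' `min_flank_s` is immediately followed by an episode of `to_state`
#' lasting at least `min_flank_s`.
#'
#' @param h a [hypnogram()].
#' @param from_state,to_state distinct states.
#' @param min_flank_s minimum flanking-episode duration (default 30 s).
#' @return data frame `time_s`, `from_state`, `to_state` (possibly empty).
#' @export
find_transitions <- function(h, from_state, to_state, min_flank_s = 30) {
  assert_state(from_state); assert_state(to_state)
  if (from_state == to_state) stop("from_state and to_state must differ")
  ep <- merge_episodes(h)
  out <- data.frame(time_s = numeric(), from_state = character(),
                    to_state = character())
  if (nrow(ep) < 2L) return(out)
  for (i in seq_len(nrow(ep) - 1L)) {
    if (ep$state[i] == from_state && ep$state[i + 1L] == to_state &&
        ep$duration_s[i] >= min_flank_s &&
        ep$duration_s[i + 1L] >= min_flank_s) {
      out <- rbind(out, data.frame(time_s = ep$start_s[i + 1L],
                                   from_state = from_state,
                                   to_state = to_state))
    }
  }
  out
}

#' Transition-triggered trace average
#'
#' Trace segments around each transition are placed on a common offset grid
#' at frame resolution (nearest frame); transitions whose window falls
#' outside the trace are dropped with a message.
#'
#' @param z numeric z-scored trace.
#' @param frame_rate frames per second.
#' @param transitions data frame from [find_transitions()].
#' @param window_s `(pre, post)` window half-widths in seconds
#'   (default 60 each side).
#' @return list of class `aligned_traces`: `matrix` (one row per usable
#'   transition), `offsets_s` (strictly increasing, includes 0), `mean`,
#'   `sem` (`NA` with a single row), `n`.
#' @export
align_traces <- function(z, frame_rate, transitions, window_s = c(60, 60)) {
  if (any(window_s <= 0)) stop("window must extend on both sides")
  n_pre <- as.integer(round(window_s[1] * frame_rate))
  n_post <- as.integer(round(window_s[2] * frame_rate))
  if (n_pre + n_post < 1L) stop("window shorter than one frame")
  offsets <- (-n_pre:n_post) / frame_rate
  rows <- list()
  for (i in seq_len(nrow(transitions))) {
    centre <- 1L + as.integer(round(transitions$time_s[i] * frame_rate))
    idx <- centre + (-n_pre:n_post)
    if (idx[1] < 1L || idx[length(idx)] > length(z)) {
      message("dropping transition at ", transitions$time_s[i],
              " s: window exceeds the trace")
      next
    }
    rows[[length(rows) + 1L]] <- z[idx]
  }
  if (!length(rows)) stop("no transition window fits inside the trace")
  m <- do.call(rbind, rows)
  mu <- colMeans(m)
  sem <- if (nrow(m) > 1L) apply(m, 2L, sd) / sqrt(nrow(m)) else
    rep(NA_real_, ncol(m))
  structure(list(matrix = m, offsets_s = offsets, mean = mu, sem = sem,
                 n = nrow(m)),
            class = "aligned_traces")
}

#' @export
print.aligned_traces <- function(x, ...) {
  cat(sprintf("<aligned_traces> %d transitions x %d offsets [%g, %g] s\n",
              x$n, length(x$offsets_s), min(x$offsets_s), max(x$offsets_s)))
  invisible(x)
}

#' Pre/post contrast of a transition-triggered average
#'
#' @param at an `aligned_traces` object.
#' @return `mean(z at offsets > 0) - mean(z at offsets < 0)`.
#' @export
transition_contrast <- function(at) {
  stopifnot(inherits(at, "aligned_traces"))
  mean(at$mean[at$offsets_s > 0]) - mean(at$mean[at$offsets_s < 0])
}
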