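#' Map event times to imaging frames
#'
#' Aligns behavior timestamps to the imaging clock by assigning each event
#' time to the nearest frame timestamp; an exact midpoint maps to the
#' earlier frame. Times farther than half a frame period outside the
#' recorded span raise an error naming the offending time.
#'
#' @param times Event times in seconds (common timebase with the frames).
#' @param frame_times Strictly increasing frame timestamps in seconds.
#' @return Integer vector of 1-based frame indices.
#' @export
align_to_frames <- function(times, frame_times) {
  if (any(diff(frame_times) <= 0)) {
    stop("`frame_times` must be strictly increasing", call. = FALSE)
  }
  period <- stats::median(diff(frame_times))
  lo <- frame_times[1] - period / 2
  hi <- frame_times[length(frame_times)] + period / 2
  bad <- times < lo | times > hi
  if (any(bad)) {
    stop("event time(s) outside the imaging span: ",
         paste(signif(times[bad], 6), collapse = ", "), " s", call. = FALSE)
  }
  mids <- utils::head(frame_times, -1) + diff(frame_times) / 2
  findInterval(times, mids, left.open = TRUE) + 1L
}

#' Build per-trial movement windows
#'
#' The movement window of a trial spans from `pad` seconds before reach
#' onset to `pad` seconds after retrieval end (default 100 ms on each side).
#' Windows are expressed as half-open 1-based frame intervals
#' `[start_frame, end_frame)`; a frame is "in-window" iff it falls in some
#' padded trial interval. Overlapping padded windows are flagged and merge
#' naturally in the in/out partition.
#'
#' @param trials Tibble with columns `trial_id`, `onset_s`, `end_s` (sorted
#'   by onset; sorted automatically with a warning otherwise).
#' @param frame_times Strictly increasing frame timestamps (s).
#' @param pad Padding in seconds on each side of the reach-to-retrieval
#'   span.
#' @return Tibble with columns `trial_id`, `start_frame`, `end_frame`
#'   (half-open), `start_s`, `end_s` (padded times) and `merged` (overlap
#'   flag).
#' @export
build_windows <- function(trials, frame_times, pad = 0.1) {
  stopifnot(pad >= 0)
  if (any(trials$onset_s >= trials$end_s)) {
    stop("each trial needs `onset_s < end_s`", call. = FALSE)
  }
  if (is.unsorted(trials$onset_s)) {
    warning("trials were not sorted by onset; sorting", call. = FALSE)
    trials <- trials[order(trials$onset_s), , drop = FALSE]
  }
  t0 <- trials$onset_s - pad
  t1 <- trials$end_s + pad
  if (min(t0) < frame_times[1] - 1e-9 ||
      max(t1) > frame_times[length(frame_times)] + 1e-9) {
    stop("padded window extends beyond the imaging session", call. = FALSE)
  }
  n <- length(t0)
  merged <- rep(FALSE, n)
  if (n > 1) {
    ov <- t0[-1] < t1[-n]
    merged[-1] <- merged[-1] | ov
    merged[-n] <- merged[-n] | ov
    if (any(ov)) {
      warning(sum(ov), " overlapping padded window pair(s) flagged as merged",
              call. = FALSE)
    }
  }
  tibble::tibble(
    trial_id = trials$trial_id,
    start_frame = vapply(t0, function(a) sum(frame_times < a) + 1L, 1L),
    end_frame = vapply(t1, function(b) sum(frame_times <= b) + 1L, 1L),
    start_s = t0,
    end_s = t1,
    merged = merged
  )
}

#' In-window frame mask
#'
#' Logical mask over frames: `TRUE` for frames inside any movement window.
#' The in-window set and its complement partition the session's frames.
#'
#' @param windows Window table from [build_windows()].
#' @param n_frames Total number of frames in the session.
#' @return Logical vector of length `n_frames`.
#' @export
window_mask <- function(windows, n_frames) {
  mask <- logical(n_frames)
  for (i in seq_len(nrow(windows))) {
    if (windows$end_frame[i] > windows$start_frame[i]) {
      mask[windows$start_frame[i]:(windows$end_frame[i] - 1L)] <- TRUE
    }
  }
  mask
}
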