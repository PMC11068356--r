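#' Scaled fluorescence trace container
#'
#' Holds a neurons x frames matrix of scaled fluorescence (the source
#' extraction tool's `C_raw`, unitless dF), the frame timestamps in seconds
#' and the frame rate. Rows are neurons, columns are frames.
#'
#' @param mat Numeric matrix, neurons x frames, finite entries.
#' @param frame_rate Frames per second, > 0.
#' @param time Optional frame timestamps (s), strictly increasing, length
#'   `ncol(mat)`; defaults to a regular grid starting at 0.
#' @param session Optional session identifier.
#' @return An object of class `calcium_traces`.
#' @export
calcium_traces <- function(mat, frame_rate, time = NULL, session = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (!all(is.finite(mat))) stop("trace matrix must be finite", call. = FALSE)
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("`frame_rate` must be > 0", call. = FALSE)
  }
  if (is.null(time)) time <- (seq_len(ncol(mat)) - 1) / frame_rate
  if (length(time) != ncol(mat) || any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing with one entry per frame",
         call. = FALSE)
  }
  if (is.null(rownames(mat))) rownames(mat) <- seq_len(nrow(mat))
  structure(
    list(mat = mat, time = as.numeric(time), frame_rate = frame_rate,
         session = session),
    class = "calcium_traces"
  )
}

#' @export
print.calcium_traces <- function(x, ...) {
  cat("<calcium_traces> ", nrow(x$mat), " neurons x ", ncol(x$mat),
      " frames at ", x$frame_rate, " Hz (",
      round(utils::tail(x$time, 1), 1), " s)\n", sep = "")
  invisible(x)
}

#' @export
dim.calcium_traces <- function(x) dim(x$mat)

#' @importFrom tibble as_tibble
#' @export
as_tibble.calcium_traces <- function(x, ...) {
  tibble::tibble(
    neuron_id = rep(rownames(x$mat), times = ncol(x$mat)),
    frame = rep(seq_len(ncol(x$mat)), each = nrow(x$mat)),
    time_s = rep(x$time, each = nrow(x$mat)),
    value = as.vector(x$mat)
  ) |> dplyr::arrange(.data$neuron_id, .data$frame)
}

#' Event-restricted activity container
#'
#' Same shape as [calcium_traces()] but holding the nonnegative
#' baseline-subtracted activity restricted to the rising phase of detected
#' calcium events (zero everywhere else). This is the matrix all downstream
#' population metrics operate on.
#'
#' @inheritParams calcium_traces
#' @return An object of class `event_activity`.
#' @export
event_activity <- function(mat, frame_rate, time = NULL, session = NULL) {
  out <- calcium_traces(mat, frame_rate, time, session)
  if (any(out$mat < 0)) stop("event activity must be nonnegative", call. = FALSE)
  class(out) <- c("event_activity", "calcium_traces")
  out
}

#' @export
print.event_activity <- function(x, ...) {
  cat("<event_activity> ", nrow(x$mat), " neurons x ", ncol(x$mat),
      " frames; ", round(100 * mean(x$mat > 0), 2),
      "% of frames inside event rising phases\n", sep = "")
  invisible(x)
}
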