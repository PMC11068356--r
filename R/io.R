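#' Read and write the pipeline's CSV formats
#'
#' Plain CSV readers/writers (comma separator, `.` decimal, mandatory
#' header) for every tabular artifact of the pipeline: trial tables
#' (`trial_id, onset_s, end_s, outcome`), trajectories
#' (`trial_id, t, x, y`; coordinates in cm, times in seconds), per-day
#' outcome counts, fEPSP series (`t_min, amplitude_mv`; times in minutes),
#' and trace matrices (one row per neuron, a `neuron_id` column followed by
#' one column per frame, with the frame timestamps in a companion file).
#' Every writer's output is readable by its reader with equal content.
#'
#' @param x Object to write.
#' @param path,traces_path,times_path File paths.
#' @param frame_rate Frame rate for [read_traces()]; inferred from the
#'   timestamps when omitted.
#' @name session_io
NULL

#' @rdname session_io
#' @export
write_trials <- function(x, path) {
  readr::write_csv(dplyr::mutate(x, outcome = as.character(.data$outcome)),
                   path)
  invisible(path)
}

#' @rdname session_io
#' @export
read_trials <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           trial_id = readr::col_integer(),
                           onset_s = readr::col_double(),
                           end_s = readr::col_double(),
                           outcome = readr::col_character()
                         ))
  bad <- setdiff(unique(out$outcome), outcome_levels)
  if (length(bad) > 0) {
    stop("unknown outcome label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(out, outcome = factor(.data$outcome, levels = outcome_levels))
}

#' @rdname session_io
#' @export
write_trajectories <- function(x, path) {
  readr::write_csv(x[, c("trial_id", "t", "x", "y")], path)
  invisible(path)
}

#' @rdname session_io
#' @export
read_trajectories <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    trial_id = readr::col_integer(),
                    t = readr::col_double(),
                    x = readr::col_double(),
                    y = readr::col_double()
                  ))
}

#' @rdname session_io
#' @export
write_outcomes <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname session_io
#' @export
read_outcomes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_integer()))
}

#' @rdname session_io
#' @export
write_fepsp <- function(x, path) {
  readr::write_csv(x[, c("t_min", "amplitude_mv")], path)
  invisible(path)
}

#' @rdname session_io
#' @export
read_fepsp <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    t_min = readr::col_double(),
                    amplitude_mv = readr::col_double()
                  ))
}

#' @rdname session_io
#' @export
write_traces <- function(x, traces_path, times_path) {
  stopifnot(inherits(x, "calcium_traces"))
  df <- tibble::as_tibble(x$mat, .name_repair = ~ sprintf("f%05d", seq_along(.x)))
  df <- dplyr::bind_cols(tibble::tibble(neuron_id = rownames(x$mat)), df)
  readr::write_csv(df, traces_path)
  readr::write_csv(tibble::tibble(frame = seq_along(x$time), time_s = x$time),
                   times_path)
  invisible(traces_path)
}

#' @rdname session_io
#' @export
read_traces <- function(traces_path, times_path, frame_rate = NULL) {
  df <- readr::read_csv(traces_path, show_col_types = FALSE)
  times <- readr::read_csv(times_path, show_col_types = FALSE)
  mat <- as.matrix(df[, -1])
  dimnames(mat) <- list(as.character(df$neuron_id), NULL)
  if (is.null(frame_rate)) frame_rate <- 1 / stats::median(diff(times$time_s))
  calcium_traces(mat, frame_rate = frame_rate, time = times$time_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
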