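#' Robust per-neuron baseline statistics
#'
#' Estimates the baseline mean and the SD of baseline fluctuation of each
#' trace. Because active neurons carry sparse large transients, the
#' estimator is robust by default: median for the mean and `1.4826 * MAD`
#' for the SD. An optional second pass re-estimates both after masking the
#' supra-threshold excursions found with the first-pass statistics.
#'
#' @param traces A [calcium_traces()] object with at least 100 frames.
#' @param refine If `TRUE`, run the two-pass refinement (mask detected
#'   excursions, then re-estimate).
#' @param k Threshold multiplier used only for the refinement mask.
#' @return Tibble with columns `neuron_id`, `baseline_mean`, `baseline_sd`,
#'   `constant` (flag for degenerate constant traces, which are excluded
#'   downstream), plus an `estimator` attribute.
#' @export
estimate_baseline <- function(traces, refine = FALSE, k = 3) {
  stopifnot(inherits(traces, "calcium_traces"))
  if (ncol(traces$mat) < 100) {
    stop("need at least 100 frames per neuron to estimate a baseline",
         call. = FALSE)
  }
  est_one <- function(x) c(stats::median(x), stats::mad(x))
  st <- t(apply(traces$mat, 1, est_one))
  if (refine) {
    for (j in seq_len(nrow(st))) {
      if (st[j, 2] == 0) next
      x <- traces$mat[j, ]
      keep <- x - st[j, 1] <= k * st[j, 2]
      if (sum(keep) >= 100) st[j, ] <- est_one(x[keep])
    }
  }
  constant <- st[, 2] == 0
  if (any(constant)) {
    warning(sum(constant), " constant trace(s) flagged; excluded downstream",
            call. = FALSE)
  }
  out <- tibble::tibble(
    neuron_id = rownames(traces$mat),
    baseline_mean = st[, 1],
    baseline_sd = st[, 2],
    constant = constant
  )
  attr(out, "estimator") <- if (refine) "median/MAD, event-masked refit" else
    "median/MAD"
  out
}

#' Detect calcium events by the k x SD rule
#'
#' A calcium event is a maximal contiguous excursion of the
#' baseline-subtracted trace above `k` times the SD of baseline fluctuation
#' (default `k = 3`) lasting at least `min_duration` frames. The event peak
#' is the frame of the excursion maximum; the onset is found by walking back
#' from the excursion start to the preceding local minimum, so that the
#' `[onset, peak]` span covers the full rising phase.
#'
#' @param traces A [calcium_traces()] object.
#' @param stats Baseline statistics from [estimate_baseline()] on the same
#'   traces (computed on the fly if omitted).
#' @param k Positive threshold multiplier.
#' @param min_duration Minimum supra-threshold run length in frames needed
#'   to trigger an event (default 3, i.e. 150 ms at 20 Hz -- well under a
#'   slow indicator's rise time but enough to suppress paired-noise
#'   triggers).
#' @param k_end Lower (hysteresis) multiplier at which an event ends: once
#'   triggered at `k` sigma, an excursion extends until the activity falls
#'   back below `k_end` sigma, so noise wiggles around the high threshold
#'   during a slow transient's decay do not fragment one event into many.
#'   `k_end = k` recovers plain maximal supra-threshold excursions.
#' @return Tibble with one row per event: `neuron_id`, `onset_frame`,
#'   `peak_frame`, `onset_s`, `peak_s`, `amplitude` (dF above baseline mean
#'   at the peak).
#' @export
detect_events <- function(traces, stats = estimate_baseline(traces), k = 3,
                          min_duration = 3, k_end = 1) {
  stopifnot(inherits(traces, "calcium_traces"))
  if (!is.numeric(k) || k <= 0) stop("`k` must be > 0", call. = FALSE)
  k_end <- min(k_end, k)
  per_neuron <- purrr::map(seq_len(nrow(traces$mat)), function(j) {
    if (stats$constant[j]) return(NULL)
    z <- traces$mat[j, ] - stats$baseline_mean[j]
    high <- z > k * stats$baseline_sd[j]
    low <- z > k_end * stats$baseline_sd[j]
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    # a low-envelope run is an event iff it contains a sustained high run
    keep <- which(r$values)
    if (length(keep) > 0) {
      has_high <- vapply(keep, function(i) {
        h <- rle(high[starts[i]:ends[i]])
        any(h$values & h$lengths >= min_duration)
      }, TRUE)
      keep <- keep[has_high]
    }
    if (length(keep) == 0) return(NULL)
    onset <- peak <- integer(length(keep))
    for (ii in seq_along(keep)) {
      s <- starts[keep[ii]]; e <- ends[keep[ii]]
      peak[ii] <- s - 1L + which.max(z[s:e])
      # walk back from the first high crossing inside the envelope
      o <- s - 1L + which(high[s:e])[1]
      while (o > 1 && z[o - 1] < z[o]) o <- o - 1L
      onset[ii] <- o
    }
    list(neuron_id = rep(stats$neuron_id[j], length(keep)),
         onset_frame = onset, peak_frame = peak, amplitude = z[peak])
  })
  per_neuron <- per_neuron[!vapply(per_neuron, is.null, TRUE)]
  res <- if (length(per_neuron) == 0) {
    tibble::tibble(neuron_id = character(), onset_frame = integer(),
                   peak_frame = integer(), amplitude = numeric())
  } else {
    tibble::tibble(
      neuron_id = unlist(purrr::map(per_neuron, "neuron_id")),
      onset_frame = unlist(purrr::map(per_neuron, "onset_frame")),
      peak_frame = unlist(purrr::map(per_neuron, "peak_frame")),
      amplitude = unlist(purrr::map(per_neuron, "amplitude"))
    )
  }
  res |>
    dplyr::mutate(
      onset_s = traces$time[.data$onset_frame],
      peak_s = traces$time[.data$peak_frame],
      .after = "peak_frame"
    )
}

#' Restrict activity to event rising phases
#'
#' Builds the activity matrix fed to all population metrics: the positive
#' part of the baseline-subtracted trace on the frames between each detected
#' event's onset and peak, and exactly zero everywhere else.
#'
#' @param traces A [calcium_traces()] object.
#' @param events Event table from [detect_events()] on the same traces.
#' @param stats Baseline statistics used for the detection.
#' @return An [event_activity()] object of the same dimensions as `traces`.
#' @export
rising_phase_activity <- function(traces, events,
                                  stats = estimate_baseline(traces)) {
  stopifnot(inherits(traces, "calcium_traces"))
  n_frames <- ncol(traces$mat)
  if (nrow(events) > 0 &&
      (min(events$onset_frame) < 1 || max(events$peak_frame) > n_frames)) {
    stop("event span outside trace bounds", call. = FALSE)
  }
  A <- matrix(0, nrow(traces$mat), n_frames,
              dimnames = dimnames(traces$mat))
  row_of <- stats::setNames(seq_len(nrow(traces$mat)), rownames(traces$mat))
  mu <- stats::setNames(stats$baseline_mean, stats$neuron_id)
  for (i in seq_len(nrow(events))) {
    j <- row_of[[as.character(events$neuron_id[i])]]
    idx <- events$onset_frame[i]:events$peak_frame[i]
    A[j, idx] <- pmax(traces$mat[j, idx] - mu[[as.character(events$neuron_id[i])]], 0)
  }
  event_activity(A, frame_rate = traces$frame_rate, time = traces$time,
                 session = traces$session)
}

#' Simple AR(1) inverse-filter deconvolution
#'
#' Optional nonnegative deconvolution `s[t] = max(c[t] - gamma * c[t-1], 0)`
#' of each trace under an AR(1) transient model. Exactly inverts noiseless
#' AR(1) dynamics; it is OFF by default in the pipeline, whose event rule
#' operates on the raw scaled traces.
#'
#' @param traces A [calcium_traces()] object.
#' @param gamma AR(1) coefficient in (0, 1).
#' @return A [calcium_traces()] object holding the nonnegative deconvolved
#'   activity, with attribute `deconvolved = TRUE`.
#' @export
deconvolve_ar1 <- function(traces, gamma) {
  stopifnot(inherits(traces, "calcium_traces"))
  if (!is.numeric(gamma) || gamma <= 0 || gamma >= 1) {
    stop("`gamma` must lie strictly between 0 and 1", call. = FALSE)
  }
  m <- traces$mat
  s <- cbind(pmax(m[, 1, drop = FALSE], 0),
             pmax(m[, -1, drop = FALSE] - gamma * m[, -ncol(m), drop = FALSE], 0))
  dimnames(s) <- dimnames(m)
  out <- calcium_traces(s, frame_rate = traces$frame_rate, time = traces$time,
                        session = traces$session)
  attr(out, "deconvolved") <- TRUE
  attr(out, "gamma") <- gamma
  out
}
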