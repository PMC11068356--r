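#' Run the full session analysis
#'
#' Chains the analysis stages on one session: baseline estimation, calcium
#' event detection (k x SD rule) and rising-phase extraction, movement
#' windows, movement-related neuron classification, peri-onset population
#' trace with the activated statistic, trial-to-trial population
#' correlation, pairwise trajectory Hausdorff distances and (when outcome
#' counts are supplied) per-day outcome rates. Deterministic given the
#' inputs and parameters.
#'
#' @param traces A [calcium_traces()] object.
#' @param trials Trial table (`trial_id`, `onset_s`, `end_s`, `outcome`).
#' @param trajectories Optional trajectory tibble (`trial_id`, `t`, `x`,
#'   `y`).
#' @param outcomes Optional per-day outcome count table.
#' @param k Event threshold multiplier (default 3).
#' @param alpha Classification significance level (default 0.05).
#' @param pad Movement-window padding in seconds (default 0.1).
#' @param range,baseline_window,peak_window Peri-onset windows passed to
#'   [population_trace()].
#' @param resample Optional resampling count for [pairwise_hausdorff()].
#' @param vector_mode Population-vector mode for [trial_correlation()].
#' @param deconvolve Optional AR(1) coefficient; when set, events are
#'   detected on the deconvolved signal instead of the raw traces (recorded
#'   in the summary).
#' @return Object of class `session_summary` holding every stage result
#'   plus a one-row `summary` tibble (`n_neurons`, `n_events`,
#'   `n_movement_related`, `activated`, `mean_r`, `mean_hausdorff`, ...).
#'   Supports `glance()` and is serializable with
#'   [write_session_summary()].
#' @examples
#' ses <- sim_session(sim_config(n_neurons = 20, n_trials = 8,
#'                               session_duration = 120, seed = 7))
#' res <- analyze_session(ses$traces, ses$trials, ses$trajectories,
#'                        ses$outcomes)
#' glance(res)
#' @export
analyze_session <- function(traces, trials, trajectories = NULL,
                            outcomes = NULL, k = 3, alpha = 0.05, pad = 0.1,
                            range = c(-2, 3), baseline_window = c(-2, -0.5),
                            peak_window = c(-0.5, 1.5), resample = NULL,
                            vector_mode = "sum", deconvolve = NULL) {
  detect_on <- traces
  if (!is.null(deconvolve)) detect_on <- deconvolve_ar1(traces, deconvolve)
  stats <- estimate_baseline(detect_on)
  events <- detect_events(detect_on, stats, k = k)
  activity <- rising_phase_activity(detect_on, events, stats)
  windows <- build_windows(trials, traces$time, pad = pad)
  classification <- classify_neurons(activity, windows, alpha = alpha)
  n_rel <- sum(classification$label == "movement_related")
  pop <- NULL
  corr <- NULL
  if (n_rel >= 1) {
    pop <- population_trace(activity, trials, classification, range = range,
                            baseline_window = baseline_window,
                            peak_window = peak_window)
  }
  if (n_rel >= 2) {
    corr <- trial_correlation(activity, windows, classification,
                              vector_mode = vector_mode)
  }
  haus <- if (!is.null(trajectories)) pairwise_hausdorff(trajectories,
                                                         resample = resample)
  rates <- if (!is.null(outcomes)) outcome_rates(outcomes)
  summary <- tibble::tibble(
    n_neurons = nrow(traces$mat),
    n_frames = ncol(traces$mat),
    n_trials = nrow(trials),
    n_events = nrow(events),
    n_movement_related = n_rel,
    activated = if (is.null(pop)) NA_real_ else pop$activated,
    mean_r = if (is.null(corr)) NA_real_ else corr$mean_r,
    mean_hausdorff_cm = if (is.null(haus)) NA_real_ else haus$mean
  )
  structure(
    list(summary = summary, events = events, windows = windows,
         classification = classification, population = pop,
         correlation = corr, hausdorff = haus, rates = rates,
         params = list(k = k, alpha = alpha, pad = pad, range = range,
                       baseline_window = baseline_window,
                       peak_window = peak_window,
                       resample = resample, vector_mode = vector_mode,
                       deconvolve = deconvolve)),
    class = "session_summary"
  )
}

#' @export
print.session_summary <- function(x, ...) {
  cat("<session_summary>\n")
  s <- x$summary
  cat("  ", s$n_neurons, " neurons, ", s$n_trials, " trials, ", s$n_events,
      " calcium events\n", sep = "")
  cat("  movement-related neurons:", s$n_movement_related, "\n")
  cat("  activated population activity:", signif(s$activated, 4), "\n")
  cat("  mean trial-to-trial r:", signif(s$mean_r, 4), "\n")
  if (!is.na(s$mean_hausdorff_cm)) {
    cat("  mean pairwise Hausdorff:", signif(s$mean_hausdorff_cm, 4), "cm\n")
  }
  invisible(x)
}

#' @export
glance.session_summary <- function(x, ...) x$summary

#' Write a session summary as JSON
#'
#' Serializes the scalar session summary together with the analysis
#' parameters. Output is deterministic: the same summary always produces
#' byte-identical JSON.
#'
#' @param x A `session_summary` from [analyze_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_summary <- function(x, path) {
  stopifnot(inherits(x, "session_summary"))
  payload <- list(
    summary = as.list(x$summary),
    params = x$params,
    rates = if (is.null(x$rates)) NULL else
      lapply(split(x$rates, x$rates$day), function(d) {
        stats::setNames(as.list(d$rate), as.character(d$outcome))
      })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
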