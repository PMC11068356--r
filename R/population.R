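#' Classify movement-related neurons
#'
#' Two-sided Wilcoxon rank-sum test per neuron between its event-restricted
#' activity inside vs outside the movement windows. A neuron is labelled
#' `movement_related` iff `p < alpha` **and** its mean in-window activity
#' exceeds its mean out-of-window activity; everything else (including
#' indiscriminately active and movement-suppressed neurons) is `excluded`.
#' All-zero neurons get `p = 1` by convention.
#'
#' @param activity An [event_activity()] object.
#' @param windows Window table from [build_windows()].
#' @param alpha Two-sided significance level (default 0.05; no
#'   multiple-testing correction, by design).
#' @return Tibble with columns `neuron_id`, `p_value`, `mean_in`,
#'   `mean_out`, `label` (`"movement_related"` or `"excluded"`).
#' @export
classify_neurons <- function(activity, windows, alpha = 0.05) {
  stopifnot(inherits(activity, "event_activity"))
  mask <- window_mask(windows, ncol(activity$mat))
  if (sum(mask) < 20 || sum(!mask) < 20) {
    stop("need at least 20 frames both inside and outside the windows",
         call. = FALSE)
  }
  res <- purrr::map_dfr(seq_len(nrow(activity$mat)), function(j) {
    a <- activity$mat[j, ]
    x <- a[mask]
    y <- a[!mask]
    if (all(a == a[1])) {
      p <- 1
    } else {
      p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
      if (is.na(p)) p <- 1
    }
    tibble::tibble(
      neuron_id = rownames(activity$mat)[j],
      p_value = p,
      mean_in = mean(x),
      mean_out = mean(y)
    )
  })
  res |>
    dplyr::mutate(label = ifelse(
      .data$p_value < alpha & .data$mean_in > .data$mean_out,
      "movement_related", "excluded"
    ))
}

# trial-averaged peri-onset activity matrix: rows = selected neurons,
# columns = relative frame offsets; trials lacking full coverage are dropped
# with a warning
peri_onset_average <- function(mat, time, frame_rate, onsets, range) {
  onset_frames <- align_to_frames(onsets, time)
  offs <- seq(round(range[1] * frame_rate), round(range[2] * frame_rate))
  ok <- onset_frames + min(offs) >= 1 & onset_frames + max(offs) <= length(time)
  if (!all(ok)) {
    warning(sum(!ok), " trial(s) too close to the session edge dropped",
            call. = FALSE)
  }
  if (!any(ok)) stop("no trial has full peri-onset coverage", call. = FALSE)
  acc <- matrix(0, nrow(mat), length(offs))
  for (f in onset_frames[ok]) acc <- acc + mat[, f + offs, drop = FALSE]
  list(mean = acc / sum(ok), t_rel = offs / frame_rate, n_trials = sum(ok))
}

#' Order neurons by peri-onset peak time
#'
#' For each movement-related neuron the peak time is the relative time of
#' the maximum of its trial-averaged peri-onset activity; neurons are
#' ordered by ascending peak time, ties broken by neuron id. This ordering
#' reproduces the sorted activity-pattern rasters used to visualize
#' refinement.
#'
#' @param activity An [event_activity()] object.
#' @param trials Trial table with `onset_s`.
#' @param classified Classification from [classify_neurons()].
#' @param range Peri-onset range in seconds.
#' @return Tibble `neuron_id`, `peak_time_s`, `rank`, sorted by rank.
#' @export
sort_by_peak_time <- function(activity, trials, classified,
                              range = c(-2, 3)) {
  sel <- classified$neuron_id[classified$label == "movement_related"]
  if (length(sel) < 1) stop("no movement-related neurons", call. = FALSE)
  rows <- match(sel, rownames(activity$mat))
  pa <- peri_onset_average(activity$mat[rows, , drop = FALSE], activity$time,
                           activity$frame_rate, trials$onset_s, range)
  peak_t <- pa$t_rel[apply(pa$mean, 1, which.max)]
  ord <- order(peak_t, sel)
  tibble::tibble(
    neuron_id = sel[ord],
    peak_time_s = peak_t[ord],
    rank = seq_along(ord)
  )
}

#' Peri-onset population activity trace
#'
#' Averages the event-restricted activity over movement-related neurons and
#' then over trials on reach-onset-aligned bins, and summarizes it by the
#' baseline level (mean over `baseline_window`), the peak level (max over
#' `peak_window`) and the **activated population activity**
#' `activated = peak - baseline`, the refinement statistic that grows with
#' training.
#'
#' @param activity An [event_activity()] object.
#' @param trials Trial table with `onset_s`.
#' @param classified Classification from [classify_neurons()]; only
#'   movement-related neurons enter (pass `all_neurons = TRUE` for a
#'   sensitivity variant).
#' @param range Peri-onset range (s) of the trace.
#' @param baseline_window,peak_window Intervals (s, relative to onset) for
#'   the baseline mean and the peak maximum; the defaults bracket the
#'   observed rise at -0.2 s and peak at +0.33 s.
#' @param all_neurons Use every neuron instead of the movement-related set.
#' @return Object of class `population_trace`: the onset-aligned `trace`
#'   tibble (`t_rel`, `activity`) plus scalars `baseline`, `peak`,
#'   `activated`, `n_neurons`, `n_trials`. Supports `tidy()`, `glance()`
#'   and `autoplot()`.
#' @export
population_trace <- function(activity, trials, classified,
                             range = c(-2, 3),
                             baseline_window = c(-2, -0.5),
                             peak_window = c(-0.5, 1.5),
                             all_neurons = FALSE) {
  stopifnot(inherits(activity, "event_activity"))
  sel <- if (all_neurons) rownames(activity$mat) else
    classified$neuron_id[classified$label == "movement_related"]
  if (length(sel) < 1) stop("no neurons selected", call. = FALSE)
  rows <- match(sel, rownames(activity$mat))
  pop <- colMeans(activity$mat[rows, , drop = FALSE])
  pa <- peri_onset_average(matrix(pop, 1), activity$time, activity$frame_rate,
                           trials$onset_s, range)
  trace <- tibble::tibble(t_rel = pa$t_rel, activity = pa$mean[1, ])
  in_b <- trace$t_rel >= baseline_window[1] & trace$t_rel < baseline_window[2]
  in_p <- trace$t_rel >= peak_window[1] & trace$t_rel < peak_window[2]
  baseline <- mean(trace$activity[in_b])
  peak <- max(trace$activity[in_p])
  structure(
    list(trace = trace, baseline = baseline, peak = peak,
         activated = peak - baseline,
         n_neurons = length(sel), n_trials = pa$n_trials,
         baseline_window = baseline_window, peak_window = peak_window),
    class = "population_trace"
  )
}

#' @export
print.population_trace <- function(x, ...) {
  cat("<population_trace> ", x$n_neurons, " neurons x ", x$n_trials,
      " trials; activated = ", signif(x$activated, 4),
      " (peak ", signif(x$peak, 4), " - baseline ", signif(x$baseline, 4),
      ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.population_trace <- function(x, ...) x$trace

#' @export
glance.population_trace <- function(x, ...) {
  tibble::tibble(
    baseline = x$baseline, peak = x$peak, activated = x$activated,
    n_neurons = x$n_neurons, n_trials = x$n_trials
  )
}

#' @export
autoplot.population_trace <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$t_rel, .data$activity)) +
    ggplot2::annotate("rect", xmin = object$baseline_window[1],
                      xmax = object$baseline_window[2], ymin = -Inf,
                      ymax = Inf, alpha = 0.08) +
    ggplot2::geom_hline(yintercept = object$baseline, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from movement onset (s)",
                  y = "population activity (dF)",
                  title = sprintf("Activated population activity: %.4f",
                                  object$activated)) +
    ggplot2::theme_minimal()
}

#' Trial-to-trial population activity correlation
#'
#' Per trial, the population activity vector holds each movement-related
#' neuron's summed event-restricted activity inside that trial's movement
#' window (or, with `vector_mode = "timebin"`, the neuron x 100-ms-bin
#' activity flattened). Pearson correlations between all trial pairs
#' quantify the recurrence of the activity pattern; the summary is the mean
#' over unordered pairs. Pairs with a constant vector are undefined and
#' excluded from the mean.
#'
#' @param activity An [event_activity()] object.
#' @param windows Window table from [build_windows()] (per trial).
#' @param classified Classification from [classify_neurons()].
#' @param vector_mode `"sum"` (default) or `"timebin"`.
#' @param bin_s Bin width for `"timebin"` mode, seconds.
#' @param all_neurons Use every neuron instead of the movement-related set.
#' @return Object of class `trial_correlation`: correlation `matrix`,
#'   `mean_r` over the strict upper triangle (undefined pairs dropped),
#'   `trial_ids`, `n_undefined`, `vector_mode`. Supports `tidy()`,
#'   `glance()` and `autoplot()`.
#' @export
trial_correlation <- function(activity, windows, classified,
                              vector_mode = c("sum", "timebin"),
                              bin_s = 0.1, all_neurons = FALSE) {
  stopifnot(inherits(activity, "event_activity"))
  vector_mode <- match.arg(vector_mode)
  sel <- if (all_neurons) rownames(activity$mat) else
    classified$neuron_id[classified$label == "movement_related"]
  if (length(sel) < 2) {
    stop("need at least two movement-related neurons", call. = FALSE)
  }
  if (nrow(windows) < 2) stop("need at least two trials", call. = FALSE)
  rows <- match(sel, rownames(activity$mat))
  vecs <- purrr::map(seq_len(nrow(windows)), function(i) {
    idx <- windows$start_frame[i]:(windows$end_frame[i] - 1L)
    sub <- activity$mat[rows, idx, drop = FALSE]
    if (vector_mode == "sum") {
      rowSums(sub)
    } else {
      bins <- floor((seq_along(idx) - 1) * (1 / (bin_s * activity$frame_rate)))
      as.vector(t(rowsum(t(sub), bins)))
    }
  })
  V <- do.call(cbind, vecs)
  colnames(V) <- windows$trial_id
  C <- suppressWarnings(stats::cor(V))
  ok <- apply(V, 2, function(v) stats::sd(v) > 0)
  diag(C)[ok] <- 1
  up <- C[upper.tri(C)]
  structure(
    list(matrix = C, mean_r = mean(up, na.rm = TRUE),
         trial_ids = windows$trial_id, n_undefined = sum(is.na(up)),
         vector_mode = vector_mode),
    class = "trial_correlation"
  )
}

#' @export
print.trial_correlation <- function(x, ...) {
  cat("<trial_correlation> ", length(x$trial_ids), " trials (",
      x$vector_mode, " vectors); mean pairwise r = ", signif(x$mean_r, 4),
      if (x$n_undefined > 0) paste0(" (", x$n_undefined,
                                    " undefined pair(s) excluded)") else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.trial_correlation <- function(x, ...) {
  C <- x$matrix
  idx <- which(upper.tri(C), arr.ind = TRUE)
  tibble::tibble(
    trial_a = x$trial_ids[idx[, 1]],
    trial_b = x$trial_ids[idx[, 2]],
    r = C[idx]
  )
}

#' @export
glance.trial_correlation <- function(x, ...) {
  tibble::tibble(
    n_trials = length(x$trial_ids),
    mean_r = x$mean_r,
    n_undefined_pairs = x$n_undefined,
    vector_mode = x$vector_mode
  )
}

#' @export
autoplot.trial_correlation <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(
      x = factor(.data$trial_a, levels = object$trial_ids),
      y = factor(.data$trial_b, levels = object$trial_ids),
      fill = .data$r
    )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Pearson r") +
    ggplot2::labs(x = "trial", y = "trial",
                  title = sprintf("Mean trial-to-trial correlation: %.3f",
                                  object$mean_r)) +
    ggplot2::theme_minimal()
}
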