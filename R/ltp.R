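#' Normalize an fEPSP series to percentage of baseline
#'
#' Expresses each fEPSP amplitude as a percentage of the mean amplitude
#' over the pre-HFS baseline interval (default the 15 min before HFS, i.e.
#' `[-15, 0)` min). By construction the baseline-interval mean of the
#' normalized series is exactly 100, and normalizing an already-normalized
#' series returns it unchanged.
#'
#' @param series Tibble with columns `t_min` (minutes relative to HFS at 0)
#'   and `amplitude_mv`.
#' @param baseline Half-open baseline interval `[a, b)` in minutes; must
#'   end at 0 and contain at least 3 samples with nonzero mean.
#' @return The input tibble with an added `normalized` column (%), plus
#'   attributes `baseline_interval` and `baseline_mean_mv`.
#' @export
normalize_fepsp <- function(series, baseline = c(-15, 0)) {
  stopifnot(all(c("t_min", "amplitude_mv") %in% names(series)))
  if (baseline[2] != 0) stop("baseline interval must end at 0 (HFS)",
                             call. = FALSE)
  in_b <- series$t_min >= baseline[1] & series$t_min < baseline[2]
  if (sum(in_b) < 3) stop("need at least 3 baseline samples", call. = FALSE)
  bm <- mean(series$amplitude_mv[in_b])
  if (bm == 0) stop("baseline mean amplitude is zero", call. = FALSE)
  out <- dplyr::mutate(series, normalized = 100 * .data$amplitude_mv / bm)
  attr(out, "baseline_interval") <- baseline
  attr(out, "baseline_mean_mv") <- bm
  out
}

#' Before/after-HFS means of the normalized fEPSP
#'
#' Arithmetic means of the normalized fEPSP over the canonical comparison
#' windows: 10 min before HFS (`[-10, 0)` min) and the 50-60 min post-HFS
#' window. `after - before` is the LTP magnitude in percentage points.
#'
#' @param series Normalized series from [normalize_fepsp()] (normalized on
#'   the fly from the amplitudes if the `normalized` column is absent).
#' @param before,after Half-open intervals `[a, b)` in minutes; each must
#'   contain at least 3 samples.
#' @return One-row tibble with `before_pct`, `after_pct`, `ltp_pct`
#'   (= after - before) and the sample counts.
#' @export
fepsp_before_after <- function(series, before = c(-10, 0),
                               after = c(50, 60)) {
  if (!"normalized" %in% names(series)) series <- normalize_fepsp(series)
  pick <- function(iv) {
    v <- series$normalized[series$t_min >= iv[1] & series$t_min < iv[2]]
    if (length(v) < 3) {
      stop("interval [", iv[1], ", ", iv[2], ") contains fewer than 3 samples",
           call. = FALSE)
    }
    v
  }
  b <- pick(before)
  a <- pick(after)
  tibble::tibble(
    before_pct = mean(b), after_pct = mean(a),
    ltp_pct = mean(a) - mean(b),
    n_before = length(b), n_after = length(a)
  )
}

#' Plot a normalized fEPSP time course
#'
#' @param series Normalized series from [normalize_fepsp()].
#' @param bin_min Optional bin width in minutes for display averaging
#'   (`NULL` = plot raw samples).
#' @return A ggplot object.
#' @export
plot_fepsp <- function(series, bin_min = NULL) {
  if (!"normalized" %in% names(series)) series <- normalize_fepsp(series)
  df <- series
  if (!is.null(bin_min)) {
    df <- df |>
      dplyr::mutate(t_min = floor(.data$t_min / bin_min) * bin_min +
                      bin_min / 2) |>
      dplyr::summarise(normalized = mean(.data$normalized),
                       .by = "t_min")
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$t_min, .data$normalized)) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time from HFS (min)", y = "fEPSP (% of baseline)") +
    ggplot2::theme_minimal()
}
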