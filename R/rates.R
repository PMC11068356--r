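#' Count outcomes from a trial table
#'
#' Tabulates a per-trial table (with an `outcome` column and optionally a
#' `day` column) into the wide per-day outcome-count format used by
#' [outcome_rates()].
#'
#' @param trials Tibble with column `outcome` (levels
#'   `miss, no_grasp, drop, success`) and optionally `day`.
#' @return Tibble with columns `day`, the four outcome counts and
#'   `attempts`.
#' @export
outcome_counts <- function(trials) {
  if (!"day" %in% names(trials)) trials$day <- 1L
  trials |>
    dplyr::mutate(outcome = factor(.data$outcome, levels = outcome_levels)) |>
    dplyr::count(.data$day, .data$outcome, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "n",
                       values_fill = 0L) |>
    dplyr::mutate(attempts = .data$miss + .data$no_grasp + .data$drop +
                    .data$success)
}

#' Per-day behavioral outcome rates
#'
#' Converts per-day outcome counts into rates: for each category,
#' `rate = count / attempts` (the success rate is successful attempts over
#' total attempts). Per-day rates sum to 1 exactly.
#'
#' @param counts Tibble with columns `day`, `miss`, `no_grasp`, `drop`,
#'   `success` and optionally `attempts` (recomputed from the counts if
#'   absent or inconsistent).
#' @return Long tibble with columns `day`, `outcome`, `n`, `attempts`,
#'   `rate`.
#' @export
outcome_rates <- function(counts) {
  need <- c("day", outcome_levels)
  if (!all(need %in% names(counts))) {
    stop("`counts` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(as.matrix(counts[outcome_levels]) < 0)) {
    stop("outcome counts must be nonnegative", call. = FALSE)
  }
  totals <- rowSums(counts[outcome_levels])
  if ("attempts" %in% names(counts) && any(counts$attempts != totals)) {
    stop("per-day counts must sum to `attempts`", call. = FALSE)
  }
  if (any(totals == 0)) stop("zero attempts on some day", call. = FALSE)
  counts |>
    dplyr::select(dplyr::all_of(need)) |>
    dplyr::mutate(attempts = totals) |>
    tidyr::pivot_longer(dplyr::all_of(outcome_levels), names_to = "outcome",
                        values_to = "n") |>
    dplyr::mutate(
      outcome = factor(.data$outcome, levels = outcome_levels),
      rate = .data$n / .data$attempts
    ) |>
    dplyr::relocate("day", "outcome", "n", "attempts", "rate")
}

#' Per-category rate change between two days
#'
#' Tabulates the learning contrast `rate(day_b) - rate(day_a)` for every
#' outcome category (e.g. the Day-1 vs Day-6 success and miss contrasts of
#' a learning curve). Because per-day rates sum to 1, the deltas sum to 0.
#'
#' @param rates Long rate table from [outcome_rates()].
#' @param day_a,day_b Reference and comparison days (both must be present).
#' @return Tibble with columns `outcome`, `rate_a`, `rate_b`, `delta`.
#' @export
learning_delta <- function(rates, day_a, day_b) {
  for (d in c(day_a, day_b)) {
    if (!d %in% rates$day) stop("day ", d, " missing from `rates`",
                                call. = FALSE)
  }
  wide <- rates |>
    dplyr::filter(.data$day %in% c(day_a, day_b)) |>
    dplyr::select("day", "outcome", "rate") |>
    tidyr::pivot_wider(names_from = "day", values_from = "rate")
  tibble::tibble(
    outcome = wide$outcome,
    rate_a = wide[[as.character(day_a)]],
    rate_b = wide[[as.character(day_b)]],
    delta = wide[[as.character(day_b)]] - wide[[as.character(day_a)]]
  )
}

#' Learning-curve plot
#'
#' Per-day outcome rates as lines, the success rate emphasized.
#'
#' @param rates Long rate table from [outcome_rates()].
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(.data$day, .data$rate,
                                      colour = .data$outcome)) +
    ggplot2::geom_line(ggplot2::aes(linewidth = .data$outcome == "success"),
                       show.legend = c(linewidth = FALSE)) +
    ggplot2::geom_point() +
    ggplot2::scale_linewidth_manual(values = c(`TRUE` = 1.2, `FALSE` = 0.4)) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "training day", y = "rate", colour = "outcome") +
    ggplot2::theme_minimal()
}
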