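as_point_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  p <- as.matrix(p)
  if (nrow(p) == 0) stop("point set must be non-empty", call. = FALSE)
  if (ncol(p) != 2 || !all(is.finite(p))) {
    stop("points must be a finite n x 2 set of (x, y) coordinates",
         call. = FALSE)
  }
  unname(p)
}

#' Directed and symmetric Hausdorff distance between point sets
#'
#' `hausdorff_directed(a, b)` is the greatest of the distances from a point
#' in `a` to its closest point in `b`;
#' `hausdorff_dist(a, b) = max(hausdorff_directed(a, b), hausdorff_directed(b, a))`
#' is the symmetric Hausdorff distance used to compare reach trajectories,
#' treated as unordered planar point sets in cm.
#'
#' @param a,b Point sets: numeric `n x 2` matrices or data frames with
#'   columns `x` and `y`; both non-empty.
#' @return A single nonnegative distance in the units of the coordinates.
#' @examples
#' hausdorff_dist(cbind(0, 0), cbind(3, 4)) # 5
#' @export
hausdorff_directed <- function(a, b) {
  a <- as_point_matrix(a)
  b <- as_point_matrix(b)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(max(apply(d2, 1, min)))
}

#' @rdname hausdorff_directed
#' @export
hausdorff_dist <- function(a, b) {
  max(hausdorff_directed(a, b), hausdorff_directed(b, a))
}

#' Resample a trajectory uniformly along its arc length
#'
#' Linear interpolation of the path at `n` equally spaced arc-length
#' positions. Raw reach trajectories have heterogeneous point counts; the
#' Hausdorff distance is defined on point sets and needs no resampling, but
#' a uniform resampling is offered so every trajectory contributes equally
#' many points.
#'
#' @param trajectory Tibble with columns `x`, `y` (and optionally `t`).
#' @param n Number of output points.
#' @return Tibble with columns `x`, `y` of `n` rows.
#' @export
resample_trajectory <- function(trajectory, n = 100) {
  stopifnot(n >= 2)
  x <- trajectory$x
  y <- trajectory$y
  arc <- cumsum(c(0, sqrt(diff(x)^2 + diff(y)^2)))
  if (arc[length(arc)] == 0) {
    return(tibble::tibble(x = rep(x[1], n), y = rep(y[1], n)))
  }
  keep <- !duplicated(arc)
  target <- seq(0, arc[length(arc)], length.out = n)
  tibble::tibble(
    x = stats::approx(arc[keep], x[keep], xout = target)$y,
    y = stats::approx(arc[keep], y[keep], xout = target)$y
  )
}

#' Pairwise Hausdorff distances across trial trajectories
#'
#' Computes the full symmetric matrix of Hausdorff distances between all
#' trial trajectories of a session and summarizes trajectory variability as
#' the mean over unordered pairs (the strict upper triangle). Smaller means
#' indicate more stereotyped reaching.
#'
#' @param trajectories Tibble with columns `trial_id`, `x`, `y` holding at
#'   least two trajectories.
#' @param resample Optional point count for uniform arc-length resampling of
#'   every trajectory before the distance computation (`NULL` = use raw
#'   points, the default).
#' @return An object of class `hausdorff_result`: list with the distance
#'   `matrix` (cm), `mean` pairwise distance and `trial_ids`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
pairwise_hausdorff <- function(trajectories, resample = NULL) {
  ids <- unique(trajectories$trial_id)
  if (length(ids) < 2) {
    stop("need at least two trajectories", call. = FALSE)
  }
  paths <- purrr::map(ids, function(id) {
    p <- trajectories[trajectories$trial_id == id, , drop = FALSE]
    if (!is.null(resample)) p <- resample_trajectory(p, n = resample)
    as_point_matrix(p)
  })
  m <- length(paths)
  D <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      D[i, j] <- D[j, i] <- hausdorff_dist(paths[[i]], paths[[j]])
    }
  }
  structure(
    list(matrix = D, mean = mean(D[upper.tri(D)]), trial_ids = ids,
         resample = resample),
    class = "hausdorff_result"
  )
}

#' @export
print.hausdorff_result <- function(x, ...) {
  cat("<hausdorff_result> ", length(x$trial_ids), " trajectories, mean pairwise distance ",
      signif(x$mean, 4), " cm\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.hausdorff_result <- function(x, ...) {
  D <- x$matrix
  idx <- which(upper.tri(D), arr.ind = TRUE)
  tibble::tibble(
    trial_a = x$trial_ids[idx[, 1]],
    trial_b = x$trial_ids[idx[, 2]],
    distance = D[idx]
  )
}

#' @importFrom generics glance
#' @export
glance.hausdorff_result <- function(x, ...) {
  tibble::tibble(
    n_trajectories = length(x$trial_ids),
    n_pairs = choose(length(x$trial_ids), 2),
    mean_distance = x$mean,
    max_distance = max(x$matrix)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.hausdorff_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(
      x = factor(.data$trial_a, levels = object$trial_ids),
      y = factor(.data$trial_b, levels = object$trial_ids),
      fill = .data$distance
    )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Hausdorff (cm)") +
    ggplot2::labs(x = "trial", y = "trial",
                  title = sprintf("Mean pairwise Hausdorff distance: %.3f cm",
                                  object$mean)) +
    ggplot2::theme_minimal()
}
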