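# shared fixtures and independent oracles

small_cfg <- function(...) {
  sim_config(n_neurons = 20, n_trials = 10, session_duration = 170,
             seed = 42, ...)
}

# one small analyzed session, built once per test run
cached <- local({
  store <- new.env(parent = emptyenv())
  function(name, build) {
    if (is.null(store[[name]])) store[[name]] <- build()
    store[[name]]
  }
})

small_session <- function() {
  cached("small_session", function() {
    suppressWarnings(sim_session(small_cfg()))
  })
}

# quadratic brute-force Hausdorff oracle, straight from the definition
bf_directed <- function(A, B) {
  worst <- -Inf
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      d <- sqrt((A[i, 1] - B[j, 1])^2 + (A[i, 2] - B[j, 2])^2)
      if (d < best) best <- d
    }
    if (best > worst) worst <- best
  }
  unname(worst)
}

bf_hausdorff <- function(A, B) max(bf_directed(A, B), bf_directed(B, A))

rand_points <- function(n) cbind(x = stats::runif(n, -2, 2),
                                 y = stats::runif(n, -2, 2))

# definitional Pearson correlation (sum formula), independent of stats::cor
pearson_sum_formula <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# chi-square goodness of fit of counts against Poisson(lambda) with known
# lambda, pooling bins to expected counts >= 5
poisson_gof_p <- function(counts, lambda) {
  kmax <- max(counts)
  probs <- stats::dpois(0:kmax, lambda)
  probs <- c(probs, 1 - sum(probs))
  obs <- tabulate(counts + 1, nbins = kmax + 2)
  # pool from the right until every expected count is >= 5
  n <- length(counts)
  exp_counts <- probs * n
  while (length(exp_counts) > 2 && exp_counts[length(exp_counts)] < 5) {
    k <- length(exp_counts)
    exp_counts[k - 1] <- exp_counts[k - 1] + exp_counts[k]
    obs[k - 1] <- obs[k - 1] + obs[k]
    exp_counts <- exp_counts[-k]
    obs <- obs[-k]
  }
  while (length(exp_counts) > 2 && exp_counts[1] < 5) {
    exp_counts[2] <- exp_counts[2] + exp_counts[1]
    obs[2] <- obs[2] + obs[1]
    exp_counts <- exp_counts[-1]
    obs <- obs[-1]
  }
  stat <- sum((obs - exp_counts)^2 / exp_counts)
  stats::pchisq(stat, df = length(exp_counts) - 1, lower.tail = FALSE)
}

# event-activity container built directly from a matrix at 20 Hz
manual_activity <- function(mat) {
  event_activity(mat, frame_rate = 20)
}
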