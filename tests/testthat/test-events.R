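test_that("robust baseline estimator recovers known noise statistics", {
  withr::with_seed(31, {
    x <- matrix(stats::rnorm(2 * 1e4), nrow = 2)
    st <- estimate_baseline(calcium_traces(x, frame_rate = 20))
    expect_true(all(abs(st$baseline_sd - 1) < 0.05))
    expect_true(all(abs(st$baseline_mean) < 0.05))

    # sparse large transients (5% of frames) barely move the estimate
    y <- stats::rnorm(1e4)
    y[sample(1e4, 500)] <- y[sample(1e4, 500)] + 8
    st2 <- estimate_baseline(calcium_traces(matrix(y, 1), frame_rate = 20))
    expect_lt(abs(st2$baseline_sd - 1), 0.1)
  })
  const <- calcium_traces(matrix(1, 1, 200), frame_rate = 20)
  expect_warning(stc <- estimate_baseline(const), "constant")
  expect_true(stc$constant[1])
  expect_error(estimate_baseline(calcium_traces(matrix(0, 1, 50), 20)),
               "100 frames")
})

test_that("k x SD rule finds isolated excursions with their amplitude", {
  z <- numeric(300)
  z[150] <- 10
  tr <- calcium_traces(matrix(z, 1), frame_rate = 20)
  st <- tibble::tibble(neuron_id = "1", baseline_mean = 0, baseline_sd = 1,
                       constant = FALSE)
  ev <- detect_events(tr, st, k = 3, min_duration = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude, 10)
  expect_equal(ev$peak_frame, 150)
  # the default 2-frame minimum suppresses the single-frame spike
  expect_equal(nrow(detect_events(tr, st, k = 3, min_duration = 2)), 0)
  expect_error(detect_events(tr, st, k = 0), "`k` must be > 0")
})

test_that("event count is non-increasing in k and frames scale-equivariant", {
  withr::with_seed(32, {
    x <- stats::rnorm(5000) + 3 * calcium_kernel(rep(seq(0, 4.95, 0.05), 50))
  })
  tr <- calcium_traces(matrix(x, 1), frame_rate = 20)
  st <- estimate_baseline(tr)
  n_prev <- Inf
  for (k in c(1, 2, 3, 4, 5)) {
    n_k <- nrow(detect_events(tr, st, k = k))
    expect_lte(n_k, n_prev)
    n_prev <- n_k
  }
  ev <- detect_events(tr, st, k = 3)
  c0 <- 7.3
  st_c <- dplyr::mutate(st, baseline_mean = baseline_mean * c0,
                        baseline_sd = baseline_sd * c0)
  ev_c <- detect_events(calcium_traces(c0 * tr$mat, 20), st_c, k = 3)
  expect_identical(ev_c$onset_frame, ev$onset_frame)
  expect_identical(ev_c$peak_frame, ev$peak_frame)
  expect_equal(ev_c$amplitude, c0 * ev$amplitude, tolerance = 1e-12)
})

test_that("rising-phase activity is the masked positive excursion", {
  cfg <- sim_config(n_neurons = 1, noise_sd = 0, baseline_event_rate = 0,
                    n_trials = 1, session_duration = 30, seed = 2)
  gt <- tibble::tibble(neuron_id = 1L, movement_related = FALSE,
                       spikes = list(10))
  tr <- sim_traces(gt, cfg)
  st <- tibble::tibble(neuron_id = "1", baseline_mean = 0,
                       baseline_sd = 0.05, constant = FALSE)
  ev <- detect_events(tr, st)
  expect_equal(nrow(ev), 1)
  act <- rising_phase_activity(tr, ev, st)
  nz <- which(act$mat[1, ] > 0)
  expect_equal(max(nz), ev$peak_frame) # support ends exactly at the peak
  expect_gte(min(nz), ev$onset_frame)
  expect_true(all(act$mat >= 0))
  expect_lte(sum(act$mat), sum(pmax(tr$mat - st$baseline_mean, 0)))

  no_ev <- detect_events(tr, st, k = 1e6)
  expect_true(all(rising_phase_activity(tr, no_ev, st)$mat == 0))
  bad <- dplyr::mutate(ev, peak_frame = ncol(tr$mat) + 5L)
  expect_error(rising_phase_activity(tr, bad, st), "outside trace bounds")
})

test_that("AR(1) deconvolution exactly inverts noiseless AR(1) dynamics", {
  gamma <- 0.9
  n <- 400
  expect_error(deconvolve_ar1(calcium_traces(matrix(0, 1, n), 20), 1.2),
               "between 0 and 1")
  expect_true(all(deconvolve_ar1(calcium_traces(matrix(0, 1, n), 20),
                                 gamma)$mat == 0))
  # single unit spike
  c_tr <- numeric(n)
  c_tr[50] <- 1
  for (t in 51:n) c_tr[t] <- gamma * c_tr[t - 1]
  s <- deconvolve_ar1(calcium_traces(matrix(c_tr, 1), 20), gamma)$mat[1, ]
  expect_equal(which(s > 1e-12), 50)
  expect_equal(s[50], 1)
  # Poisson spikes, forward-backward round trip recovers the spike set
  withr::with_seed(33, spikes <- which(stats::runif(n) < 0.02))
  c2 <- numeric(n)
  for (t in seq_len(n)) {
    c2[t] <- (if (t > 1) gamma * c2[t - 1] else 0) + (t %in% spikes)
  }
  s2 <- deconvolve_ar1(calcium_traces(matrix(c2, 1), 20), gamma)$mat[1, ]
  expect_setequal(which(s2 > 1e-9), spikes)
})
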