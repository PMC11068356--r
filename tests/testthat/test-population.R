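# 200 frames at 20 Hz, one trial window over frames 81:120
toy_windows <- function() {
  tibble::tibble(trial_id = 1L, start_frame = 81L, end_frame = 121L,
                 start_s = 4.0, end_s = 6.0, merged = FALSE)
}

test_that("classification follows the p < alpha AND mean-in > mean-out rule", {
  w <- toy_windows()
  mask <- window_mask(w, 200)
  withr::with_seed(51, {
    up <- ifelse(mask, 5 + stats::runif(200), 0) # strongly movement-driven
    down <- ifelse(mask, 0, 5 + stats::runif(200)) # movement-suppressed
    zero <- numeric(200)
  })
  act <- manual_activity(rbind(up = up, down = down, zero = zero))
  cl <- classify_neurons(act, w)
  expect_equal(cl$label[cl$neuron_id == "up"], "movement_related")
  expect_equal(cl$label[cl$neuron_id == "down"], "excluded")
  expect_lt(cl$p_value[cl$neuron_id == "down"], 0.05) # excluded by direction
  expect_equal(cl$p_value[cl$neuron_id == "zero"], 1)
  expect_equal(cl$label[cl$neuron_id == "zero"], "excluded")
  expect_true(all(cl$p_value >= 0 & cl$p_value <= 1))
})

test_that("null neurons are flagged at no more than the directional rate", {
  w <- toy_windows()
  withr::with_seed(52, {
    m <- matrix(stats::rexp(400 * 200), nrow = 400) # same law in and out
  })
  cl <- classify_neurons(manual_activity(m), w)
  rate <- mean(cl$label == "movement_related")
  # two-sided alpha = 0.05 halved by the direction rule, + MC slack
  expect_lte(rate, 0.025 + 2 * sqrt(0.025 * 0.975 / 400))
})

test_that("neurons sort by peri-onset peak time with id tie-break", {
  fr <- 20
  n_fr <- 400
  trials <- tibble::tibble(trial_id = 1L, onset_s = 10, end_s = 11)
  m <- matrix(0, 3, n_fr, dimnames = list(c("a", "b", "c"), NULL))
  m[1, 10 * fr + 1 + 0.4 * fr] <- 1 # peak +0.4 s
  m[2, 10 * fr + 1 + 0.1 * fr] <- 1 # peak +0.1 s
  m[3, 10 * fr + 1 + 0.1 * fr] <- 1 # tie with b -> id order
  act <- manual_activity(m)
  cl <- tibble::tibble(neuron_id = c("a", "b", "c"), p_value = 0,
                       mean_in = 1, mean_out = 0,
                       label = "movement_related")
  ord <- sort_by_peak_time(act, trials, cl)
  expect_equal(ord$neuron_id, c("b", "c", "a"))
  expect_equal(ord$peak_time_s, c(0.1, 0.1, 0.4))
})

test_that("population trace summarizes peak minus baseline", {
  trials <- tibble::tibble(trial_id = 1L, onset_s = 10, end_s = 11)
  flat <- manual_activity(matrix(0, 2, 400,
                                 dimnames = list(c("a", "b"), NULL)))
  cl <- tibble::tibble(neuron_id = c("a", "b"), p_value = 1, mean_in = 0,
                       mean_out = 0, label = "excluded")
  pt <- population_trace(flat, trials, cl, all_neurons = TRUE)
  expect_equal(pt$activated, 0)
  expect_equal(glance(pt)$peak, 0)
  expect_equal(nrow(tidy(pt)), length(seq(-2 * 20, 3 * 20)))

  # a trial too close to the session edge is dropped with a warning
  trials2 <- tibble::tibble(trial_id = 1:2, onset_s = c(1, 10),
                            end_s = c(1.5, 11))
  expect_warning(population_trace(flat, trials2, cl, all_neurons = TRUE),
                 "session edge")
})

test_that("population rise onset lands near -0.2 s at high SNR", {
  # event-free background isolates the peri-reach kernel's timing
  ses <- cached("rise_session", function() {
    cfg <- sim_config(n_neurons = 40, frac_movement_related = 0.5,
                      reliability = 1, modulation_amplitude = 1.5,
                      baseline_event_rate = 0, noise_sd = 0.05,
                      n_trials = 40, session_duration = 800, seed = 53)
    trials <- sim_trials(cfg)
    traces <- sim_traces(sim_spike_trains(cfg, trials), cfg)
    list(trials = trials,
         res = suppressWarnings(analyze_session(traces, trials)))
  })
  pt <- ses$res$population
  tr <- pt$trace
  base_bins <- tr$activity[tr$t_rel >= -2 & tr$t_rel < -0.5]
  thr <- pt$baseline + 2 * stats::sd(base_bins)
  first_up <- min(tr$t_rel[tr$t_rel >= -2 & tr$activity > thr])
  expect_gte(first_up, -0.3)
  expect_lte(first_up, -0.1)
  # rising-phase mass peaks after the event-rate peak (indicator lag)
  peak_t <- tr$t_rel[which.max(tr$activity)]
  expect_gte(peak_t, 0.1)
  expect_lte(peak_t, 1.2)
})

test_that("trial correlations match the definitional Pearson formula", {
  # two trials, identical vectors -> r = 1
  fr <- 20
  m <- matrix(0, 3, 400, dimnames = list(c("a", "b", "c"), NULL))
  w <- tibble::tibble(trial_id = 1:2, start_frame = c(41L, 201L),
                      end_frame = c(81L, 241L), start_s = c(2, 10),
                      end_s = c(4, 12), merged = FALSE)
  pat <- c(1, 2, 5)
  m[, 45] <- pat
  m[, 205] <- pat
  cl <- tibble::tibble(neuron_id = c("a", "b", "c"), p_value = 0,
                       mean_in = 1, mean_out = 0, label = "movement_related")
  tc <- trial_correlation(manual_activity(m), w, cl)
  expect_equal(tc$mean_r, 1)
  expect_true(isSymmetric(tc$matrix))
  expect_true(all(diag(tc$matrix) == 1))

  # anti-ordered pair checked against the sum-formula oracle
  m2 <- m
  m2[, 205] <- rev(pat)
  tc2 <- trial_correlation(manual_activity(m2), w, cl)
  expect_equal(tc2$mean_r, pearson_sum_formula(pat, rev(pat)))

  # constant vector yields an undefined, excluded pair
  m3 <- m
  m3[, 205] <- 0
  tc3 <- trial_correlation(manual_activity(m3), w, cl)
  expect_equal(tc3$n_undefined, 1)
  expect_true(is.nan(tc3$mean_r))
})

test_that("mean r is invariant to neuron order and trial relabeling", {
  ses <- small_session()
  res <- suppressWarnings(analyze_session(ses$traces, ses$trials))
  act <- rising_phase_activity(ses$traces, res$events,
                               estimate_baseline(ses$traces))
  w <- res$windows
  cl <- res$classification
  tc <- trial_correlation(act, w, cl)
  # permute neuron rows
  perm <- sample(nrow(act$mat))
  act_p <- event_activity(act$mat[perm, ], act$frame_rate, act$time)
  expect_equal(trial_correlation(act_p, w, cl)$mean_r, tc$mean_r)
  # permute trial order: multiset of pairwise r unchanged
  permw <- w[sample(nrow(w)), ]
  tc_p <- trial_correlation(act, permw, cl)
  expect_equal(sort(tidy(tc_p)$r), sort(tidy(tc)$r), tolerance = 1e-12)
})
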