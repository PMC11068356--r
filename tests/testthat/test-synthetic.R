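test_that("config validation rejects inconsistent worlds", {
  expect_error(sim_config(reliability = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(tau_rise = 2, tau_decay = 1), "tau_rise")
  expect_error(sim_config(frame_rate = 0), "frame_rate")
  expect_error(sim_config(baseline_event_rate = -1), "nonnegative")
  bad <- outcome_profile("learner")
  bad[1, 1] <- bad[1, 1] + 0.2
  expect_error(sim_config(outcome_probs = bad), "summing to 1")
  expect_error(sim_trials(sim_config(n_trials = 40, session_duration = 60)),
               "too short")
})

test_that("identical seeds give bit-identical sessions", {
  a <- suppressWarnings(sim_session(small_cfg()))
  b <- suppressWarnings(sim_session(small_cfg()))
  expect_identical(a$traces$mat, b$traces$mat)
  expect_identical(a$trials, b$trials)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$fepsp$amplitude_mv, b$fepsp$amplitude_mv)
})

test_that("peri-reach rate kernel rises at -0.2 s and peaks near +0.33 s", {
  grid <- seq(-1, 2, by = 0.001)
  k <- peri_reach_kernel(grid)
  expect_true(all(k[grid <= -0.2] == 0))
  peak_t <- grid[which.max(k)]
  expect_gte(peak_t, 0.28)
  expect_lte(peak_t, 0.38)
  expect_equal(max(k), 1, tolerance = 1e-9)
})

test_that("spike generator matches its stated Poisson structure", {
  # zero modulation: every neuron homogeneous Poisson at the baseline rate
  cfg <- sim_config(n_neurons = 200, modulation_amplitude = 0,
                    baseline_event_rate = 0.1, n_trials = 5,
                    session_duration = 300, seed = 11)
  trials <- sim_trials(cfg)
  gt <- sim_spike_trains(cfg, trials)
  counts <- lengths(gt$spikes)
  expect_equal(sum(gt$movement_related),
               round(cfg$frac_movement_related * cfg$n_neurons))
  expect_gt(poisson_gof_p(counts, 0.1 * 300), 0.01)

  # reliability 1 + high amplitude: every related neuron fires in every trial
  cfg2 <- sim_config(n_neurons = 30, reliability = 1,
                     modulation_amplitude = 20, n_trials = 8,
                     session_duration = 160, seed = 12)
  trials2 <- sim_trials(cfg2)
  gt2 <- sim_spike_trains(cfg2, trials2)
  rel <- which(gt2$movement_related)
  hits <- sapply(rel, function(j) {
    all(sapply(trials2$onset_s, function(on) {
      any(gt2$spikes[[j]] >= on - 0.2 & gt2$spikes[[j]] <= on + 2)
    }))
  })
  expect_true(all(hits))
})

test_that("trace synthesis reproduces the closed-form transient", {
  cfg <- sim_config(n_neurons = 1, noise_sd = 0, baseline_event_rate = 0,
                    n_trials = 1, session_duration = 30, frame_rate = 20)
  gt0 <- tibble::tibble(neuron_id = 1L, movement_related = FALSE,
                        spikes = list(numeric(0)))
  expect_true(all(sim_traces(gt0, cfg)$mat == 0))

  t_spike <- 5
  gt1 <- tibble::tibble(neuron_id = 1L, movement_related = FALSE,
                        spikes = list(t_spike))
  tr <- sim_traces(gt1, cfg)
  t_star <- calcium_peak_time(cfg$tau_rise, cfg$tau_decay)
  expect_equal(t_star, log(1.5 / 0.2) * 0.2 * 1.5 / (1.5 - 0.2))
  peak_frame <- which.max(tr$mat[1, ])
  expect_lte(abs(tr$time[peak_frame] - (t_spike + t_star)),
             0.5 / cfg$frame_rate)
  expect_equal(max(tr$mat[1, ]), cfg$event_amplitude, tolerance = 0.02)
})

test_that("trajectory generator: dispersion controls spread, seed controls identity", {
  cfg0 <- sim_config(trajectory_dispersion = 0, n_trials = 6)
  tr0 <- sim_trajectories(cfg0)
  expect_true(all(table(tr0$trial_id) >= 10))
  expect_equal(pairwise_hausdorff(tr0)$mean, 0)

  means <- sapply(1:20, function(s) {
    m1 <- pairwise_hausdorff(sim_trajectories(
      sim_config(trajectory_dispersion = 0.1, n_trials = 20, seed = s)))$mean
    m2 <- pairwise_hausdorff(sim_trajectories(
      sim_config(trajectory_dispersion = 0.2, n_trials = 20, seed = 1000 + s)))$mean
    c(m1, m2)
  })
  expect_gt(mean(means[2, ]), mean(means[1, ]))

  expect_identical(sim_trajectories(sim_config(seed = 9)),
                   sim_trajectories(sim_config(seed = 9)))
})

test_that("outcome generator respects per-day probabilities", {
  all_success <- matrix(rep(c(0, 0, 0, 1), each = 2), nrow = 2,
                        dimnames = list(NULL, outcome_levels))
  cfg <- sim_config(outcome_probs = all_success)
  out <- sim_outcomes(cfg, n_days = 2, attempts_per_day = 40)
  expect_true(all(out$success == 40))
  expect_true(all(out$miss + out$no_grasp + out$drop + out$success ==
                    out$attempts))

  nl <- sim_outcomes(sim_config(outcome_probs = outcome_profile("non_learner"),
                                seed = 5),
                     n_days = 6, attempts_per_day = 5000)
  expect_true(all(abs(nl$success / nl$attempts - 0.15) < 0.02))
})

test_that("fEPSP generator is a step gain at HFS", {
  cfg <- sim_config(fepsp_post_gain = 1, fepsp_noise_cv = 0)
  flat <- sim_fepsp(cfg)
  expect_true(all(flat$amplitude_mv == cfg$fepsp_baseline))

  cfg2 <- sim_config(fepsp_baseline = 0.5, fepsp_post_gain = 1.35,
                     fepsp_noise_cv = 0)
  s <- sim_fepsp(cfg2)
  expect_true(all(s$amplitude_mv[s$t_min < 0] == 0.5))
  expect_true(all(s$amplitude_mv[s$t_min >= 0] == 0.675))
  expect_error(sim_fepsp(cfg2, t_grid = seq(-5, 60, 1)), "span")
})
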