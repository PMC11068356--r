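#' Simulate a trial table for one training day
#'
#' Places `n_trials` reach attempts evenly (with jitter) across the session
#' so that padded movement windows plus 2 s flanks never overlap, making
#' in-window vs out-of-window frames unambiguous. Onset and retrieval-end
#' times are snapped to the 1/60 s behavior-camera grid. Outcomes are drawn
#' from the configured day profile.
#'
#' @param config A [sim_config()].
#' @param day Training day whose outcome probabilities to use.
#' @return Tibble with columns `trial_id`, `onset_s`, `end_s`, `outcome`.
#' @export
sim_trials <- function(config, day = 1) {
  stopifnot(inherits(config, "sim_config"))
  flank <- 2
  spacing <- config$session_duration / config$n_trials
  need <- max(config$trial_duration) + 2 * flank
  if (spacing < need) {
    stop("`session_duration` too short to contain ", config$n_trials,
         " non-overlapping trials (need >= ",
         round(need * config$n_trials, 1), " s)", call. = FALSE)
  }
  probs <- config$outcome_probs[min(day, nrow(config$outcome_probs)), ]
  withr::with_seed(sim_substream(config$seed, 1L), {
    jitter_max <- min(1, (spacing - need) / 2)
    onset <- spacing * (seq_len(config$n_trials) - 0.5) +
      stats::runif(config$n_trials, -jitter_max, jitter_max)
    dur <- stats::runif(config$n_trials, config$trial_duration[1],
                        config$trial_duration[2])
    onset <- round(onset * 60) / 60
    end <- round((onset + dur) * 60) / 60
    outcome <- sample(outcome_levels, config$n_trials, replace = TRUE,
                      prob = probs)
  })
  tibble::tibble(
    trial_id = seq_len(config$n_trials),
    onset_s = onset, end_s = end,
    outcome = factor(outcome, levels = outcome_levels)
  )
}

#' Simulate ground-truth calcium-event (spike) times
#'
#' Movement-related neurons fire an inhomogeneous Poisson process with rate
#' `baseline_event_rate + modulation_amplitude * peri_reach_kernel(t - onset)`
#' in each trial they participate in (participation is Bernoulli with
#' probability `reliability`); all other neurons are homogeneous Poisson at
#' the baseline rate. The kernel rises 0.2 s before onset and peaks 0.33 s
#' after it.
#'
#' @param config A [sim_config()].
#' @param trials Trial table from [sim_trials()].
#' @return Tibble with columns `neuron_id`, `movement_related` and the
#'   list-column `spikes` (event times in seconds), carrying the
#'   participation matrix and generating parameters as attributes.
#' @export
sim_spike_trains <- function(config, trials) {
  stopifnot(inherits(config, "sim_config"))
  if (max(trials$end_s) + 2 > config$session_duration) {
    stop("`session_duration` too short to contain all trials with flanks",
         call. = FALSE)
  }
  n <- config$n_neurons
  n_rel <- round(config$frac_movement_related * n)
  related <- seq_len(n) <= n_rel
  T_ses <- config$session_duration
  withr::with_seed(sim_substream(config$seed, 2L), {
    participation <- matrix(FALSE, n, nrow(trials))
    spikes <- vector("list", n)
    for (j in seq_len(n)) {
      n_bg <- stats::rpois(1, config$baseline_event_rate * T_ses)
      ts <- stats::runif(n_bg, 0, T_ses)
      if (related[j] && config$modulation_amplitude > 0) {
        part <- stats::runif(nrow(trials)) < config$reliability
        participation[j, ] <- part
        for (i in which(part)) {
          n_ev <- stats::rpois(1, config$modulation_amplitude * .kernel_integral)
          if (n_ev > 0) {
            extra <- trials$onset_s[i] - .kernel_onset_lead +
              stats::rgamma(n_ev, shape = .kernel_shape, scale = .kernel_scale)
            ts <- c(ts, extra[extra >= 0 & extra <= T_ses])
          }
        }
      }
      spikes[[j]] <- sort(ts)
    }
  })
  out <- tibble::tibble(
    neuron_id = seq_len(n),
    movement_related = related,
    spikes = spikes
  )
  attr(out, "participation") <- participation
  attr(out, "reliability") <- config$reliability
  attr(out, "dispersion") <- config$trajectory_dispersion
  out
}

#' Synthesize fluorescence traces from spike times
#'
#' Forward model standing in for slow-indicator fluorescence: each event
#' adds a unit-peak double-exponential transient scaled by
#' `event_amplitude`, and i.i.d. Gaussian noise of SD `noise_sd` is added to
#' every frame. Deterministic given the config seed.
#'
#' @param spikes Ground-truth tibble from [sim_spike_trains()].
#' @param config A [sim_config()].
#' @return A [calcium_traces()] object.
#' @export
sim_traces <- function(spikes, config) {
  stopifnot(inherits(config, "sim_config"))
  fr <- config$frame_rate
  L <- round(config$session_duration * fr)
  tgrid <- (seq_len(L) - 1) / fr
  Lk <- ceiling(8 * config$tau_decay * fr)
  mat <- matrix(0, nrow(spikes), L)
  for (j in seq_len(nrow(spikes))) {
    y <- numeric(L)
    for (ts in spikes$spikes[[j]]) {
      i0 <- floor(ts * fr) + 1
      if (i0 > L) next
      idx <- i0:min(L, i0 + Lk - 1)
      y[idx] <- y[idx] + config$event_amplitude *
        calcium_kernel(tgrid[idx] - ts, config$tau_rise, config$tau_decay)
    }
    mat[j, ] <- y
  }
  if (config$noise_sd > 0) {
    withr::with_seed(sim_substream(config$seed, 3L), {
      mat <- mat + matrix(stats::rnorm(length(mat), sd = config$noise_sd),
                          nrow(mat), ncol(mat))
    })
  }
  rownames(mat) <- spikes$neuron_id
  calcium_traces(mat, frame_rate = fr, time = tgrid)
}

# smooth template reach path: out along a curved arc and back, ~1 cm scale
reach_template <- function(s) {
  list(x = 1.0 * sin(pi * s), y = 0.6 * sin(pi * s)^2 + 0.15 * sin(2 * pi * s))
}

#' Simulate reach trajectories
#'
#' Each trajectory is a fixed smooth template (a ~1 cm reach-out-and-back
#' arc) plus an independent smooth deviation path per coordinate, built from
#' three random sine harmonics whose joint RMS amplitude equals
#' `trajectory_dispersion`. With dispersion 0 all trajectories coincide.
#'
#' @param config A [sim_config()].
#' @param n_trials Number of trajectories (defaults to `config$n_trials`).
#' @param n_points Samples per trajectory (>= 10).
#' @return Tibble with columns `trial_id`, `t` (s), `x`, `y` (cm).
#' @export
sim_trajectories <- function(config, n_trials = config$n_trials,
                             n_points = 60) {
  stopifnot(inherits(config, "sim_config"), n_points >= 10)
  s <- seq(0, 1, length.out = n_points)
  tmpl <- reach_template(s)
  K <- 3
  sd_k <- config$trajectory_dispersion * sqrt(2 / K)
  basis <- sapply(seq_len(K), function(k) sin(k * pi * s))
  withr::with_seed(sim_substream(config$seed, 4L), {
    out <- purrr::map_dfr(seq_len(n_trials), function(i) {
      nx <- as.vector(basis %*% stats::rnorm(K, sd = sd_k))
      ny <- as.vector(basis %*% stats::rnorm(K, sd = sd_k))
      tibble::tibble(trial_id = i, t = s, x = tmpl$x + nx, y = tmpl$y + ny)
    })
  })
  out
}

#' Simulate day-by-day outcome counts
#'
#' Draws per-day multinomial outcome counts over
#' `miss, no_grasp, drop, success` from the configured day profiles
#' (default: 40 attempts per day).
#'
#' @param config A [sim_config()].
#' @param n_days Number of training days.
#' @param attempts_per_day Attempts per day.
#' @return Tibble with columns `day`, the four outcome counts and `attempts`.
#' @export
sim_outcomes <- function(config, n_days = nrow(config$outcome_probs),
                         attempts_per_day = 40) {
  stopifnot(inherits(config, "sim_config"), attempts_per_day > 0)
  probs <- outcome_profile_rows(config$outcome_probs, n_days)
  withr::with_seed(sim_substream(config$seed, 5L), {
    counts <- t(sapply(seq_len(n_days), function(d) {
      as.vector(stats::rmultinom(1, attempts_per_day, probs[d, ]))
    }))
  })
  colnames(counts) <- outcome_levels
  dplyr::bind_cols(tibble::tibble(day = seq_len(n_days)),
                   tibble::as_tibble(counts)) |>
    dplyr::mutate(attempts = as.integer(attempts_per_day))
}

outcome_profile_rows <- function(op, n_days) {
  idx <- pmin(seq_len(n_days), nrow(op))
  op[idx, , drop = FALSE]
}

#' Simulate an fEPSP amplitude series around HFS
#'
#' Amplitude is `fepsp_baseline` before high-frequency stimulation (time 0)
#' and `fepsp_baseline * fepsp_post_gain` after it, with optional
#' multiplicative Gaussian noise of CV `fepsp_noise_cv`. The default time
#' grid matches 0.017 Hz test stimulation from -15 to +60 min.
#'
#' @param config A [sim_config()].
#' @param t_grid Sample times in minutes relative to HFS; must span at least
#'   `[-15, 60]` min.
#' @return Tibble with columns `t_min`, `amplitude_mv`; the HFS time (0) is
#'   attached as attribute `hfs_min`.
#' @export
sim_fepsp <- function(config,
                      t_grid = -15 + seq(0, ceiling(75 * 0.017 * 60)) /
                        (0.017 * 60)) {
  stopifnot(inherits(config, "sim_config"))
  if (min(t_grid) > -15 || max(t_grid) < 60) {
    stop("`t_grid` must span at least [-15, 60] min around HFS", call. = FALSE)
  }
  amp <- config$fepsp_baseline *
    ifelse(t_grid < 0, 1, config$fepsp_post_gain)
  if (config$fepsp_noise_cv > 0) {
    withr::with_seed(sim_substream(config$seed, 6L), {
      amp <- amp * (1 + stats::rnorm(length(amp), sd = config$fepsp_noise_cv))
    })
  }
  out <- tibble::tibble(t_min = t_grid, amplitude_mv = amp)
  attr(out, "hfs_min") <- 0
  out
}

#' Simulate a complete session
#'
#' Convenience wrapper generating, from one seeded config, everything a
#' session analysis consumes: trial table, ground-truth spike trains,
#' fluorescence traces, reach trajectories, a day-by-day outcome table and
#' an fEPSP series.
#'
#' @param config A [sim_config()].
#' @param day Training day used for the trial outcomes.
#' @return A list of class `sim_session` with elements `config`, `trials`,
#'   `ground_truth`, `traces`, `trajectories`, `outcomes`, `fepsp`.
#' @export
sim_session <- function(config = sim_config(), day = 1) {
  trials <- sim_trials(config, day = day)
  gt <- sim_spike_trains(config, trials)
  structure(
    list(
      config = config,
      trials = trials,
      ground_truth = gt,
      traces = sim_traces(gt, config),
      trajectories = sim_trajectories(config),
      outcomes = sim_outcomes(config),
      fepsp = sim_fepsp(config)
    ),
    class = "sim_session"
  )
}

#' @export
print.sim_session <- function(x, ...) {
  cat("<sim_session> seed", x$config$seed, "--",
      x$config$n_neurons, "neurons,", nrow(x$trials), "trials,",
      x$config$session_duration, "s\n")
  invisible(x)
}
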