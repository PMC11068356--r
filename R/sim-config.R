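#' Outcome taxonomy of the single-pellet reaching task
#'
#' Attempts are scored as `miss` (paw never touches the pellet), `no_grasp`
#' (touched but not grasped), `drop` (grasped but lost during retrieval) or
#' `success` (pellet retrieved to the mouth).
#'
#' @export
outcome_levels <- c("miss", "no_grasp", "drop", "success")

#' Per-day outcome probability profiles
#'
#' Built-in day-by-day multinomial outcome probabilities for the synthetic
#' session generator. The `"learner"` profile follows the wildtype learning
#' curve (success rising from ~14.6% on Day 1 to 30.94% on Day 3 and a
#' plateau of ~33% thereafter, with the miss rate falling as aiming
#' improves); `"non_learner"` stays at the ~15% baseline success level on
#' every day.
#'
#' @param profile `"learner"` or `"non_learner"`.
#' @param n_days Number of training days (rows); profiles are defined for 6
#'   days, longer requests repeat the final day.
#' @return Numeric matrix `n_days x 4` with columns
#'   `miss, no_grasp, drop, success`; rows sum to 1.
#' @export
outcome_profile <- function(profile = c("learner", "non_learner"), n_days = 6) {
  profile <- match.arg(profile)
  if (profile == "learner") {
    success <- c(0.1463, 0.2279, 0.3094, 0.2896, 0.3190, 0.3276)
    miss <- seq(0.3254, 0.1162, length.out = 6)
    drop <- seq(0.0852, 0.1145, length.out = 6)
  } else {
    success <- rep(0.15, 6)
    miss <- rep(0.30, 6)
    drop <- rep(0.08, 6)
  }
  no_grasp <- 1 - success - miss - drop
  m <- cbind(miss = miss, no_grasp = no_grasp, drop = drop, success = success)
  if (n_days > 6) m <- m[c(seq_len(6), rep(6, n_days - 6)), , drop = FALSE]
  m <- m[seq_len(min(n_days, nrow(m))), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Configuration of the synthetic session generator
#'
#' Collects and validates every tunable of the simulator in one object. The
#' defaults describe a single imaging session of the single-pellet reaching
#' task: 40 attempts in a ~10 min miniscope recording at 20 Hz, sparse
#' GCaMP6s-like calcium events (slow double-exponential transients), a
#' subpopulation of movement-related neurons whose event rate rises 0.2 s
#' before reach onset and peaks 0.33 s after it, trial participation drawn
#' per neuron as a Bernoulli(`reliability`), reach trajectories on a ~1 cm
#' arc with smooth per-trial deviations, learner-profile outcome
#' probabilities, and an fEPSP series that steps to `fepsp_post_gain` times
#' baseline after high-frequency stimulation.
#'
#' @param n_neurons Number of imaged neurons.
#' @param frac_movement_related Fraction of neurons that are genuinely
#'   movement-modulated.
#' @param reliability Per-trial Bernoulli participation probability of each
#'   movement-related neuron (trial-to-trial reproducibility).
#' @param modulation_amplitude Peak added event rate (events/s) during the
#'   peri-reach kernel for participated trials.
#' @param baseline_event_rate Homogeneous background event rate, events/s.
#' @param event_amplitude Peak fluorescence of one calcium transient, scaled
#'   dF units (SNR = `event_amplitude / noise_sd`).
#' @param tau_rise,tau_decay Calcium transient time constants in seconds
#'   (`tau_rise < tau_decay`).
#' @param noise_sd SD of additive Gaussian trace noise, scaled dF units.
#' @param frame_rate Imaging frame rate in Hz (not stated for the source
#'   recordings; configurable, default 20 Hz).
#' @param n_trials Reach attempts per session.
#' @param session_duration Session length in seconds.
#' @param trial_duration Length-2 range (s) for the reach-to-retrieval span,
#'   drawn uniformly per trial and snapped to the 1/60 s behavior-camera grid.
#' @param trajectory_dispersion RMS amplitude (cm) of smooth per-trial
#'   deviations from the template reach path.
#' @param outcome_probs Matrix of per-day outcome probabilities with columns
#'   `miss, no_grasp, drop, success`; rows must sum to 1. See
#'   [outcome_profile()].
#' @param fepsp_baseline Pre-HFS fEPSP amplitude, mV.
#' @param fepsp_post_gain Multiplicative post-HFS amplitude gain (1.34
#'   reproduces the ~134% wildtype potentiation).
#' @param fepsp_noise_cv Coefficient of variation of multiplicative fEPSP
#'   measurement noise.
#' @param seed Integer master seed; each generator draws from its own
#'   substream derived from it, so adding one generator never perturbs
#'   another's output.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_neurons = 20, n_trials = 10, session_duration = 200)
#' @export
sim_config <- function(n_neurons = 100,
                       frac_movement_related = 0.4,
                       reliability = 0.5,
                       modulation_amplitude = 2,
                       baseline_event_rate = 0.1,
                       event_amplitude = 1,
                       tau_rise = 0.2,
                       tau_decay = 1.5,
                       noise_sd = 0.1,
                       frame_rate = 20,
                       n_trials = 40,
                       session_duration = 600,
                       trial_duration = c(0.8, 1.5),
                       trajectory_dispersion = 0.2,
                       outcome_probs = outcome_profile("learner"),
                       fepsp_baseline = 0.5,
                       fepsp_post_gain = 1.34,
                       fepsp_noise_cv = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_neurons = as.integer(n_neurons),
    frac_movement_related = frac_movement_related,
    reliability = reliability,
    modulation_amplitude = modulation_amplitude,
    baseline_event_rate = baseline_event_rate,
    event_amplitude = event_amplitude,
    tau_rise = tau_rise,
    tau_decay = tau_decay,
    noise_sd = noise_sd,
    frame_rate = frame_rate,
    n_trials = as.integer(n_trials),
    session_duration = session_duration,
    trial_duration = trial_duration,
    trajectory_dispersion = trajectory_dispersion,
    outcome_probs = outcome_probs,
    fepsp_baseline = fepsp_baseline,
    fepsp_post_gain = fepsp_post_gain,
    fepsp_noise_cv = fepsp_noise_cv,
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  nonneg <- c("reliability", "frac_movement_related", "modulation_amplitude",
              "baseline_event_rate", "event_amplitude", "noise_sd",
              "trajectory_dispersion", "fepsp_noise_cv", "session_duration")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] < 0)) {
      stop("`", f, "` must be nonnegative", call. = FALSE)
    }
  }
  for (f in c("frac_movement_related", "reliability")) {
    if (cfg[[f]] > 1) stop("`", f, "` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$frame_rate <= 0) stop("`frame_rate` must be > 0", call. = FALSE)
  if (cfg$tau_rise >= cfg$tau_decay) {
    stop("`tau_rise` must be smaller than `tau_decay`", call. = FALSE)
  }
  if (cfg$n_neurons < 1L || cfg$n_trials < 1L) {
    stop("`n_neurons` and `n_trials` must be at least 1", call. = FALSE)
  }
  if (length(cfg$trial_duration) != 2L || any(cfg$trial_duration <= 0) ||
      diff(cfg$trial_duration) < 0) {
    stop("`trial_duration` must be an increasing positive range", call. = FALSE)
  }
  op <- cfg$outcome_probs
  if (!is.matrix(op) || ncol(op) != 4L ||
      !identical(colnames(op), outcome_levels)) {
    stop("`outcome_probs` must be a matrix with columns ",
         paste(outcome_levels, collapse = ", "), call. = FALSE)
  }
  if (any(op < 0) || any(abs(rowSums(op) - 1) > 1e-8)) {
    stop("each row of `outcome_probs` must be a probability vector summing to 1",
         call. = FALSE)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  neurons:", x$n_neurons,
      sprintf("(%.0f%% movement-related, reliability %.2f)",
              100 * x$frac_movement_related, x$reliability), "\n")
  cat("  session:", x$session_duration, "s at", x$frame_rate, "Hz,",
      x$n_trials, "trials\n")
  cat("  events : baseline", x$baseline_event_rate, "/s, peak gain",
      x$modulation_amplitude, "/s, SNR",
      round(x$event_amplitude / max(x$noise_sd, .Machine$double.eps), 1), "\n")
  cat("  seed   :", x$seed, "\n")
  invisible(x)
}

# deterministic substream seed for one generator; Lehmer-style map keeps the
# result a valid 32-bit seed whatever the master seed
sim_substream <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + stream * 16807) %%
               2147483647)
}
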