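#' Peri-reach event-rate kernel
#'
#' Unit-peak rate kernel describing the modulation of calcium-event rate
#' around reach onset. The kernel is a shifted gamma bump that starts to rise
#' 0.2 s before movement onset and peaks 0.33 s after it, matching the
#' population-activity time course observed in motor cortex layer 2/3 during
#' single-pellet reaching. Multiplied by `modulation_amplitude` (events/s) it
#' gives the added event rate of a movement-related neuron in a trial it
#' participates in.
#'
#' @param t_rel Numeric vector of times in seconds relative to reach onset.
#' @return Numeric vector of kernel values in `[0, 1]`, zero before -0.2 s.
#' @examples
#' peri_reach_kernel(c(-0.5, -0.2, 0.33, 2))
#' @export
peri_reach_kernel <- function(t_rel) {
  u <- t_rel + .kernel_onset_lead
  k <- stats::dgamma(u, shape = .kernel_shape, scale = .kernel_scale)
  k[u <= 0] <- 0
  k / .kernel_peak_density
}

# kernel constants: gamma(shape = 3) in u = t + 0.2 with mode at u = 0.53,
# i.e. peak 0.33 s after onset; rise begins at t = -0.2 s
.kernel_onset_lead <- 0.2
.kernel_shape <- 3
.kernel_scale <- 0.53 / (.kernel_shape - 1)
.kernel_peak_density <- stats::dgamma(0.53, shape = .kernel_shape,
                                      scale = .kernel_scale)
# integral of the unit-peak kernel over all time (seconds); expected extra
# events per participated trial = modulation_amplitude * this
.kernel_integral <- 1 / .kernel_peak_density

#' Calcium transient kernel
#'
#' Difference-of-exponentials fluorescence impulse response
#' `exp(-t/tau_decay) - exp(-t/tau_rise)` for `t >= 0`, normalized to unit
#' peak. Its peak time has the closed form
#' `t* = log(tau_decay/tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)`.
#'
#' @param t Numeric vector of times in seconds since the event.
#' @param tau_rise,tau_decay Rise and decay time constants in seconds;
#'   `tau_rise < tau_decay`.
#' @return Kernel values in `[0, 1]`, zero for negative `t`.
#' @export
calcium_kernel <- function(t, tau_rise = 0.2, tau_decay = 1.5) {
  stopifnot(tau_rise > 0, tau_decay > tau_rise)
  t_peak <- calcium_peak_time(tau_rise, tau_decay)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  k <- (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak
  k[t < 0] <- 0
  k
}

#' @rdname calcium_kernel
#' @export
calcium_peak_time <- function(tau_rise = 0.2, tau_decay = 1.5) {
  log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
}
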