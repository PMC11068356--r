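---
title: "Quantifying motor-skill refinement: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motor-skill refinement: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

reachrefine quantifies how reaching movements and the motor-cortical
population activity that drives them become more stereotyped with practice.
Its inputs are the standard artifacts of a single-pellet reaching experiment
with head-mounted one-photon calcium imaging: per-neuron scaled fluorescence
traces from an upstream source-extraction tool (CNMF-E or similar), a
per-trial table of reach onset / retrieval end / outcome, 2-D reach
trajectories in cm, and (for the plasticity arm of such studies) fEPSP
amplitude series around high-frequency stimulation (HFS). This vignette
explains the models behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical decisions taken where the underlying procedures are
conventionally underspecified.

```{r setup}
library(reachrefine)
```

## Trajectory variability: pairwise Hausdorff distance

Each reach trajectory is treated as an unordered planar point set in cm. For
two sets $A$ and $B$, the directed distance is
$d(A \to B) = \max_{a \in A} \min_{b \in B} \lVert a - b \rVert$, and the
Hausdorff distance is $H(A,B) = \max\{d(A \to B),\, d(B \to A)\}$ — the
greatest of all distances from a point in one set to the closest point in
the other. Session-level variability is the mean of $H$ over all unordered
trial pairs; refinement shows up as this mean shrinking across training
days.

Two deliberate choices:

* **No resampling by default.** The set definition needs none, and raw
  trajectories with heterogeneous point counts are valid inputs. Because
  trajectories of very different lengths weight the distance toward the
  longer path, `pairwise_hausdorff(..., resample = 100)` offers uniform
  arc-length resampling; whether upstream analyses resampled is typically
  unreported, so both modes are exposed and recorded in the result.
* **Ties in the max/min are resolved by value only**; no index semantics are
  attached.

## From fluorescence to events

The event pipeline operates on the scaled fluorescence matrix (`C_raw`,
neurons x frames, unitless dF).

**Baseline statistics.** "Baseline fluctuation" has no standard estimator.
Because active neurons carry sparse, large, positively skewed transients,
the package uses the median as the baseline mean and $1.4826 \times$ MAD as
the baseline SD — robust to a moderate fraction of contaminated frames. An
optional second pass (`estimate_baseline(refine = TRUE)`) masks detected
excursions and re-estimates; it helps when transients occupy a substantial
minority of frames, but no estimator of this family survives sessions in
which most frames are elevated (stacked transients at high event rates) —
there the "baseline" is genuinely ill-defined.

**Event detection.** A calcium event is an excursion of the
baseline-subtracted trace above $k\sigma_b$ (default $k = 3$). Two numerical
details matter with a slow indicator (GCaMP6s-like, decay ~1.5 s):

* **Hysteresis termination** (`k_end`, default 1): the excursion is
  triggered at $k\sigma_b$ but ends only when activity falls back below
  `k_end`$\sigma_b$. A literal "maximal supra-threshold excursion" rule
  fragments one transient into many events, because the decay tail hovers
  at the threshold and noise re-crosses it repeatedly — on simulated
  sessions at SNR 5 the literal rule yields ~3 detections per true event
  (precision 0.34), while the hysteresis rule scores recall and precision
  both ~0.95. Setting `k_end = k` recovers the literal rule.
* **Minimum trigger duration** (`min_duration`, default 3 frames = 150 ms
  at 20 Hz): suppresses noise-pair triggers; genuine transients rise for
  ~0.5 s, so the cost in sensitivity is negligible.

The event **onset** is found by walking back from the first threshold
crossing to the preceding local minimum — "the rising phase" names a span
but not its start, and the local minimum is the natural foot of the
transient. The **peak** is the excursion maximum. Downstream metrics use
only the rising phase: `rising_phase_activity()` returns the positive part
of the baseline-subtracted trace on `[onset, peak]` frames and zero
elsewhere. Restricting to the rising phase sharpens timing, since the rise
tracks spiking while the decay reflects indicator kinetics.

**Deconvolution.** The upstream convention of deconvolving before event
detection is supported through a simple nonnegative AR(1) inverse filter
(`deconvolve_ar1()`, exact on noiseless AR(1) dynamics), but it is **off by
default**: the threshold rule here operates on the raw scaled traces, and
`analyze_session(deconvolve = gamma)` records in its output when the other
path was taken.

## Trials, windows and classification

Behavior and imaging are assumed on a common timebase (the generator
guarantees it; for real data a constant offset can be applied upstream,
offset *estimation* is out of scope). Event times map to the nearest frame,
exact midpoints to the earlier frame. The movement window of a trial runs
from 100 ms before reach onset to 100 ms after retrieval end; windows are
half-open, 1-based frame intervals `[start_frame, end_frame)` — stated once
here and used everywhere. Overlapping padded windows are flagged and merge
naturally in the in/out partition.

A neuron is **movement-related** iff a two-sided Wilcoxon rank-sum test
between its per-frame rising-phase activity inside vs outside the movement
windows gives $p < \alpha$ (default 0.05, uncorrected — deliberately
mirroring field practice, and a caveat worth knowing) **and** its mean
in-window activity exceeds its mean out-of-window activity. The direction
rule discards movement-suppressed neurons and halves the effective
false-positive rate, so on exchangeable per-frame null data the
movement-related fraction stays below $\alpha/2$.

A statistical caveat the package measures rather than hides: on full
sessions with a slow indicator, frames within one event's rising phase are
serially dependent, which inflates the per-frame rank-sum beyond its
nominal level (~20% of truly unmodulated neurons flagged at the defaults in
simulation, versus <2.5% on independent frames). This is a property of the
per-frame testing convention itself. Consumers needing strict type-I
control on real sessions should classify at a coarser temporal unit or
tighten $\alpha$; the package keeps the conventional per-frame default so
its output matches what the field computes.

## Population refinement metrics

Only movement-related neurons enter the population metrics (an
`all_neurons = TRUE` escape hatch exists for sensitivity analyses).

* **Sorted activity patterns.** Each neuron's peak time is the maximum of
  its trial-averaged peri-onset activity; neurons are ordered by ascending
  peak time, ties broken by id.
* **Population trace and activated activity.** Rising-phase activity is
  averaged over neurons, then over onset-aligned trials, on a peri-onset
  range of $[-2, +3]$ s. The summary statistic is
  `activated = peak - baseline`, with baseline the mean over $[-2, -0.5]$ s
  and peak the maximum over $[-0.5, +1.5]$ s. These windows are not
  standard anywhere; they were chosen once to bracket the observed
  population-activity rise (~0.2 s before onset) and peak (~0.33 s after
  onset) with margin, and are configurable. The averaging order (neurons
  first, then trials) is fixed; with equal trial lengths the alternative
  order is identical. Note that the *rising-phase fluorescence* trace peaks
  later than the underlying event-rate peak because the indicator rise
  takes ~0.5 s; the trace's rise onset, not its peak location, is the
  timing-sensitive readout.
* **Trial-to-trial correlation.** The per-trial population vector is each
  movement-related neuron's summed rising-phase activity within that
  trial's window (the per-trial "population activity" vector is not
  conventionally defined; a time-resolved variant — neuron x 100 ms bin,
  flattened — is available via `vector_mode = "timebin"` and recorded in
  the result). Recurrence is the mean Pearson correlation over unordered
  trial pairs; pairs involving a constant vector are undefined, excluded
  from the mean, and counted in the output.

## Behavioral rates and LTP quantification

Outcome rates are exact count ratios per day over the closed taxonomy
{miss, no-grasp, drop, success}; the success rate is successful attempts
over total attempts, and per-day rates sum to 1 by construction. Group
inference (ANOVA families) is intentionally not re-implemented — standard
routines exist and are not this package's contribution.

fEPSP series are normalized to percent of the mean amplitude over the
baseline interval $[-15, 0)$ min before HFS (the conventional ~15 min
baseline; half-open on the left-closed convention, so the sample at 0
belongs to the post-HFS epoch but to no averaging window). The before/after
comparison means are taken over $[-10, 0)$ and $[50, 60)$ min. Display
binning (1-min bins) is an output option only and never feeds the
statistics. Normalization is idempotent and scale-invariant; when the
baseline equals the "before" window, the before-mean is exactly 100 by
construction.

## The synthetic-data generator

Every stage is testable without animal data because `sim_session()`
generates sessions with the statistical structure the analysis assumes:

* **Trials**: 40 attempts in a session (default 600 s at 20 Hz), onsets
  jittered around an even grid and snapped to the 1/60 s behavior-camera
  grid, spaced so padded windows plus 2 s flanks never overlap.
* **Spikes**: movement-related neurons (default 40% of the population) fire
  an inhomogeneous Poisson process whose rate kernel rises 0.2 s before
  onset and peaks 0.33 s after it (a shifted gamma bump, unit peak);
  `modulation_amplitude` (events/s, default 2) scales it, and each neuron
  participates in each trial with probability `reliability` — per-trial
  Bernoulli participation is the package's model of trial-to-trial
  reproducibility (amplitude jitter is a noted alternative, not the
  default). Background activity is homogeneous Poisson (default 0.1
  events/s). Non-learner and learner outcome profiles reproduce the ~15%
  flat and ~15% to ~31% rising day-wise success probabilities of
  unsuccessful and successful learners; attempts are multinomial per day.
* **Fluorescence**: each event adds a unit-peak double-exponential
  transient ($\tau_{rise} = 0.2$ s, $\tau_{decay} = 1.5$ s, GCaMP6s-like
  stand-ins; the peak time has the closed form
  $t^* = \ln(\tau_d/\tau_r)\,\tau_r\tau_d/(\tau_d - \tau_r) \approx 0.465$
  s), plus iid Gaussian noise. The imaging frame rate of such recordings
  is usually unreported; 20 Hz is the configurable default, and no result
  asserts a particular rate.
* **Trajectories**: a fixed ~1 cm reach-out-and-back arc plus a smooth
  per-trial deviation built from three random sine harmonics whose joint
  RMS equals `trajectory_dispersion` (default 0.2 cm, which puts mean
  pairwise Hausdorff distances in the observed few-tenths-of-a-cm range).
  Deviations vanish at the endpoints (start and target are pinned).
* **fEPSP**: amplitude `fepsp_baseline` (0.5 mV) before HFS and
  `fepsp_baseline * fepsp_post_gain` after (default gain 1.34, matching
  robust potentiation), sampled at the 0.017 Hz test-stimulation cadence,
  with multiplicative Gaussian noise of CV 2%.

One master seed feeds fixed per-generator substreams (a Lehmer-style map),
so identical configs give bit-identical sessions and adding one generator
never perturbs another's output.

**What the generator does not emulate** — and hence what a green test does
not establish: no raw movies, motion artifacts, or source-extraction
crosstalk (traces are born clean); noise is white and Gaussian, with no
slow drift, photobleaching, or neuropil contamination; spike-to-fluorescence
gain is constant per event (no amplitude adaptation); behavior and imaging
clocks are perfectly aligned. Tests passing on this world validate the
computations downstream of source extraction, not the upstream imaging
pipeline.

Two interactions between the generator and the detector are worth knowing.
First, at the default background rate (0.1 events/s) with a 1.5 s decay,
distinct ground-truth events often stack inside a single excursion
envelope, so per-event recall benchmarks use a sparser world (0.02
events/s) where "one event" is well defined. Second, a background event
shortly before a reach can merge with the movement transient into one
envelope whose rising phase begins pre-onset — a small anticipatory leak in
the population trace; timing benchmarks therefore use an event-free
background.

## Degenerate inputs and numerical conventions

Constant traces are flagged at baseline estimation and excluded downstream
with a warning. All-zero neurons classify as excluded with $p = 1$ by
convention. Trials without full peri-onset coverage are dropped from the
population trace with a warning. Constant per-trial vectors produce
undefined correlations that are excluded from the mean and counted.
Midpoint timestamp ties go to the earlier frame. All frame intervals are
half-open and 1-based. CSV formats are comma-separated UTF-8 with mandatory
headers, seconds everywhere except fEPSP files (minutes, stated in the
header).

## Known limitations

* The per-frame rank-sum anti-conservativeness on autocorrelated sessions,
  discussed above.
* The baseline estimator degrades when transients occupy most frames.
* `activated` is only guaranteed nonnegative when the peak window contains
  the trace maximum and the baseline window sits in the quiet phase —
  asserted on high-SNR synthetic sessions, not in general.
* Merged excursions blur event counts at high event rates; event *timing*
  (onsets) is the robust quantity.
* No multiple-testing correction in classification, mirroring field
  practice.
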