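# reachrefine

Quantifying motor-skill refinement from single-pellet reaching behavior and
motor-cortical calcium imaging.

When a mouse learns to reach through a slit and grasp a food pellet, three
things sharpen together: the success rate rises, the paw trajectories become
more stereotyped, and the movement-locked activity of layer 2/3 motor-cortex
neurons becomes stronger and more reproducible from trial to trial.
reachrefine implements the quantification pipeline for all three axes, for
experimenters who already have per-neuron fluorescence traces from a
source-extraction tool (CNMF-E or similar), per-trial behavior tables, reach
trajectories, and — for the plasticity arm of such studies — fEPSP series
around high-frequency stimulation (HFS).

## What it computes

* **Trajectory variability** — the pairwise Hausdorff distance
  $H(A,B) = \max\{\max_a \min_b \lVert a-b\rVert,\ \max_b \min_a \lVert a-b\rVert\}$
  between reach trajectories treated as planar point sets (cm), summarized
  as the mean over unordered trial pairs.
* **Calcium events** — robust (median/MAD) baseline statistics per neuron;
  events as excursions of the baseline-subtracted trace above
  $k\sigma_b$ (default $k=3$) with hysteresis termination; rising-phase
  ([onset, peak]) activity extraction; optional nonnegative AR(1)
  deconvolution.
* **Movement-related neurons** — two-sided Wilcoxon rank-sum between
  activity inside vs outside per-trial movement windows (reach onset
  −100 ms to retrieval end +100 ms), labelled movement-related iff
  $p < 0.05$ and mean in-window > mean out-of-window.
* **Population refinement** — peak-time-sorted activity patterns; the
  onset-aligned population trace with **activated** = peak − baseline
  activity; mean trial-to-trial Pearson correlation of per-trial population
  vectors.
* **Behavioral rates** — exact per-day rates over
  {miss, no-grasp, drop, success} and day-to-day learning contrasts.
* **LTP quantification** — fEPSP normalization to % of pre-HFS baseline and
  before/after means over [−10, 0) and [50, 60) min.
* **Synthetic sessions** — a seeded generator (`sim_session()`) producing
  traces, trials, trajectories, outcomes and fEPSP series with the
  statistical structure above, so the whole pipeline is testable without
  animal data.

Everything user-facing takes and returns tibbles (matrices live in light
`calcium_traces` / `event_activity` containers); result objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(reachrefine)

cfg <- sim_config(n_neurons = 40, n_trials = 15, session_duration = 250,
                  reliability = 0.9, seed = 7)
ses <- sim_session(cfg)

res <- analyze_session(ses$traces, ses$trials, ses$trajectories, ses$outcomes)
res
#> <session_summary>
#>   40 neurons, 15 trials, 798 calcium events
#>   movement-related neurons: 24
#>   activated population activity: 0.5579
#>   mean trial-to-trial r: 0.1543
#>   mean pairwise Hausdorff: 0.4428 cm
```

Of 40 simulated neurons, 24 classify as movement-related (16 are
movement-modulated by construction, plus rank-sum false positives — see the
vignette's calibration discussion). The population of movement-related
neurons rises by 0.56 dF above its pre-movement baseline around reach onset
(`activated`); at generator reliability 0.9 the per-trial population vectors
correlate at mean r = 0.15 across trial pairs (a low-reliability "Day 1"
session lands near 0); and trajectories drawn with 0.2 cm dispersion sit at
a mean pairwise Hausdorff distance of 0.44 cm. Each component is inspectable:

```r
glance(res$correlation)
#> # A tibble: 1 × 4
#>   n_trials mean_r n_undefined_pairs vector_mode
#>      <int>  <dbl>             <int> <chr>
#> 1       15  0.154                 0 sum
autoplot(res$population)   # onset-aligned population trace

fepsp_before_after(normalize_fepsp(ses$fepsp))
#> # A tibble: 1 × 5
#>   before_pct after_pct ltp_pct n_before n_after
#>        <dbl>     <dbl>   <dbl>    <int>   <int>
#> 1       100.      134.    33.6       10      10
```

The fEPSP series, generated with a post-HFS gain of 1.34 and 2% measurement
noise, recovers a before/after contrast of 100% vs 134% of baseline — the
step-gain model of long-term potentiation.

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch on a
seeded synthetic session (simulation, event detection, classification,
population metrics, trajectory variability, outcome rates, LTP
normalization) and writes its result JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/reach-refinement.Rmd`) describes the
models and their assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, numerical
edge-case conventions, and known limitations.
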