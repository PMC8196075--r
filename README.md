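# strugglescope

Struggle-bout segmentation and fiber-photometry transient analysis for
rodent restraint stress.

During restraint, rodents engage in brief episodes of physical struggle —
the behavioral unit of active stress coping. `strugglescope` turns
markerless pose-tracking output (head-mounted fiber and tail tip at
10 fps) and simultaneously recorded two-channel fluorescence signals
into typed struggle bouts, baseline-corrected sensor transients,
bout-locked peri-event metrics, and the statistics linking transient
size to bout duration. It is written for experimenters analyzing
fiber-photometry recordings (calcium indicators with a 405 nm
isosbestic reference, or single-channel glutamate/GABA sensors) made
during restraint or comparable event-locked assays.

## The computation

**Behavior.** Per-frame speed of each tracked point (pixels/frame) is
thresholded adaptively: a point is mobile when its speed exceeds
`mean(S) + k·sd(S)` where `S` holds the speeds at or below the
session's `q` quantile — `q = 0.95, k = 1` for the head fiber,
`q = 0.99, k = 3` for the tail tip. A bout runs from the first mobile
frame until all points stay immobile for more than 0.7 s; bouts are
typed head-only / tail-only / full-body.

**Photometry.** The isosbestic reference is fit to the signal channel
by OLS; ΔF/F = (F₄₇₀ − fit(F₄₀₅)) / fit(F₄₀₅). Residual drift is removed
with airPLS (adaptive iteratively reweighted penalized least squares,
λ = 5·10⁴), the corrected trace is Z-scored over the session, and a
transient is any maximal run of samples with Z ≥ 2.91 (maximum peak,
trapezoidal area, frequency in Hz).

**Alignment.** Signals are extracted −5…+10 s around each bout onset
and Z-scored against the −5…−3 s baseline window:
`Z(t) = (x(t) − mean(baseline)) / sd(baseline)`. AUC and maximum peak
are computed over the fixed 0–5 s post-onset window (and −3–0 s
pre-onset), independent of bout length. Shifting the lock by +10 s is
the built-in negative control.

**Statistics.** Pearson correlation of AUC against bout duration with
slope and 95% CI, Welch and paired t tests, an exact binomial test for
the proportion of bouts with positive transients, and the
Benjamini–Krieger–Yekutieli two-stage step-up FDR procedure.

A synthetic-data generator (`simulate_pose_session()`,
`simulate_photometry_session()`, `simulate_study()`) produces sessions
and multi-day designs with full ground truth — true bout intervals and
types, true transient times and amplitudes, and the coupling and
habituation parameters — so that every stage is testable without any
recorded data.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
simulated 30-min session and write their tables under `results/`.
`Rscript analysis/01_simulate_session.R` then
`Rscript analysis/02_segment_bouts.R` prints:

```
adaptive thresholds (px/frame): head_fiber=0.574, tail_tip=1.221
       type count total_s   mean_s pct_of_trial
1 head_only    11    20.7 1.881818    1.1500000
2 tail_only     4     7.5 1.875000    0.4166667
3 full_body    11    18.2 1.654545    1.0111111
immobile: 97.4% of trial
recovery vs ground truth: recall 1.00, FDP 0.00, type accuracy 1.00
```

i.e. the session contained 26 true bouts, struggling occupied under 3%
of the trial, and every bout was recovered at the correct type with no
false detections. Continuing with `analysis/04_align_and_correlate.R`:

```
AUC (0-5 s) vs duration: r = 0.828, p = 1.84e-07, slope = 10.86 Z*s/s (95% CI 7.76..13.97)
bouts with positive AUC: 24/26 (exact binomial p = 1.05e-05)
offset +10 s control: mean AUC 15.21 -> -0.62 (104% reduction), r -> 0.079
```

The transient AUC grows by ≈11 Z·s per second of struggle; shifting the
behavior–photometry lock by +10 s abolishes both the signal and the
correlation, confirming the association is time-locked.
`analysis/05_multiday_study.R` runs the multi-day designs (drug-day
bout-rate increase; habituating coupling whose recovered per-day slope
falls monotonically).

In code, the same session-level analysis is one call:

```r
library(strugglescope)
sim  <- simulate_pose_session(behavior_sim_params(seed = 1))
phot <- simulate_photometry_session(photometry_sim_params(seed = 1),
                                    sim$truth$bouts)
rep  <- run_session(sim$track, phot$recording)
rep$stats$auc_duration$r
#> [1] 0.8276
```

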