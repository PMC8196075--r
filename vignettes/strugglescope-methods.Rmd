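---
title: "Methods: struggle-bout scoring and bout-locked photometry analysis"
author: "strugglescope"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`strugglescope` analyzes active stress-coping behavior during rodent
restraint together with fluorescence-sensor recordings made at the same
time. The pipeline has five computational stages, each exposed as plain
functions so that every intermediate object can be inspected and tested:

1. **Kinematics** — tracked body-point tables (head-mounted fiber and
   tail tip) become per-frame speeds and adaptive mobile/immobile
   states.
2. **Bouts** — mobility state is segmented into typed struggle bouts.
3. **Photometry** — two-channel recordings become baseline-corrected,
   standardized traces with detected transients.
4. **Alignment** — signals are time-locked to bout onsets; per-bout AUC
   and peak metrics are extracted.
5. **Statistics** — the inferential procedures applied to those tables.

A synthetic-data generator with complete ground truth drives all
validation; the repository's `analysis/` scripts walk through a full
session and a multi-day study.

# Behavioral scoring

## Speeds and adaptive thresholds

Speed is the Euclidean displacement of a tracked point between
consecutive frames, in pixels/frame, with the first frame's speed
defined as 0 (it has no predecessor; the choice only affects one frame
in half an hour of video). No pixel-to-millimeter calibration is
applied: thresholds are derived from each session's own speed
distribution, which makes them invariant to camera distance.

A point is **mobile** on a frame when its speed strictly exceeds a
threshold computed as

> mean(S) + k · sd(S),  S = { speeds ≤ the q-quantile of all speeds }

with the conventions q = 0.95, k = 1 for the head fiber and q = 0.99,
k = 3 for the tail tip. The phrase "k SD above the bottom q% of frame
speeds" admits a second reading (quantile + k·sd); we implement both
(`method = "mean_sd"` / `"quantile_sd"`) and default to the subset-mean
reading, which treats "of frame speeds" as qualifying the subset whose
dispersion is being measured. Quantiles use R's default
linear-interpolation definition (type 7) and sd uses the n−1
denominator, both fixed so that results are exactly reproducible.

## Bout segmentation

A bout opens when any point transitions immobile→mobile while no bout
is open; that frame is the bout's time 0. It closes when **all** points
have been immobile for strictly more than `gap_s = 0.7` s (at 10 fps: a
run of at least 8 all-immobile frames), so sub-gap pauses merge into one
bout. The offset is the last mobile frame before closure and the
duration includes the onset frame (duration = offset − onset + one
frame; the frame-edge convention is ours to fix and is asserted in
tests). Bouts reaching the session end without a confirmed closing gap
are kept but flagged `truncated`. Types are: head-only, tail-only, and
full-body (at least one mobile head frame *and* one mobile tail frame
anywhere within the bout — not necessarily the same frame).

# Photometry processing

For calcium-indicator recordings the 405 nm isosbestic channel is
regressed onto the 470 nm signal channel by ordinary least squares over
the whole session, and the fractional change is

> ΔF/F(t) = (F470(t) − fitted405(t)) / fitted405(t).

Sensors recorded single-channel skip the regression; the airPLS baseline
of the raw signal serves as F0 instead (`sensor_mode = "single"`).

Residual slow drift in ΔF/F is removed with **airPLS** (adaptive
iteratively reweighted penalized least squares): iterate a weighted
Whittaker smoother `(W + λDᵀD) z = W y`, zeroing the weights of points
at or above the current baseline (candidate peaks) and up-weighting
points below it. Defaults: λ = 5·10⁴, first-order differences, at most
50 iterations, convergence when the negative-residual mass falls below
0.1% of Σ|y|. Numerical notes, all asserted in tests:

* the weight exponent is capped (at 50) so late iterations cannot
  overflow;
* the stopping rule depends on the overall signal scale, so exact
  shift-equivariance of the baseline holds only when both runs take the
  same iteration path;
* with first-order differences the smoother has a boundary layer of
  roughly √λ samples: on a 600 s drift-only trace the boundary error
  reaches ~2% of the drift range, falling below 1% at the 1800 s
  session length the pipeline actually uses. λ is configurable when
  faster drift must be tracked on short recordings.

The corrected trace is standardized over the whole session
(`(y − mean)/sd`), and a **transient** is a maximal run of samples with
Z ≥ 2.91, the conventional outlier criterion, with its maximum peak and
trapezoidal area. No minimum duration is imposed by default
(`min_samples = 1`). With near-threshold signal-to-noise the run rule
naturally splits one physiological event into several runs as the trace
dips across the threshold; counts and frequencies inherit this property
of the rule, which is why recovery tests match detections to injected
events by footprint rather than one-to-one.

# Peri-event alignment

Rows are extracted over −5…+10 s around each bout onset (plus
`offset_s`, see below) by nearest-sample indexing at the photometry
sample period — no interpolation, so every aligned value is a measured
sample. Each row is Z-scored against its own −5…−3 s baseline window:

> Z(t) = (x(t) − mean(baseline)) / sd(baseline).

By construction every retained row has baseline mean 0 and sd 1 (to
1e−9; an acceptance check). Rows whose window leaves the recording, or
whose baseline has zero variance, are flagged with a reason and
excluded from metrics but never silently dropped. Bouts overlapping a
previous bout's post-window are retained — bout lists overlap heavily in
real sessions and no exclusion rule is stated for them.

Metrics are computed over fixed windows independent of bout length:
post = 0–5 s (the primary window), pre = −3–0 s. AUC is the signed
trapezoidal integral (negative deflections give negative area, needed
for inhibitory-sensor analyses); the peak is the signed maximum.
Trapezoidal integration makes AUC exactly additive over adjacent
windows, which is also tested.

The **offset control** shifts the behavior–photometry lock by +10 s
(`offset_s = 10`). On bout-locked simulations this reduces the mean
post-window AUC by ≈100% and collapses the AUC–duration correlation.
One subtlety: at +10 s the −5…−3 s baseline window lands on the decay
tail of the bout's own transient, whose size grows with duration, so
the control correlation is biased slightly *negative* (≈ −0.2 pooled)
rather than sitting exactly at 0. The control therefore demonstrates
destruction of the positive association, not a textbook null sample.

# Statistics

* `correlate_auc_duration()` — Pearson r with the t-distribution
  p-value (n−2 df) and the OLS slope of AUC on duration with its
  t-based 95% CI.
* `welch_t()` / `paired_t()` — unequal-variance and paired t tests
  (wrappers over `stats::t.test`, cross-checked against closed-form
  oracles in the suite).
* `positive_auc_proportion()` — exact two-sided binomial test of the
  fraction of bouts with AUC > 0 against 0.5, minimum-likelihood
  definition (`stats::binom.test`). The choice of the exact test is
  ours; the comparison it formalizes is "more bouts with positive
  transients than without".
* `bky_two_stage_fdr()` — the adaptive two-stage linear step-up FDR
  procedure: stage 1 runs Benjamini–Hochberg at q′ = q/(1+q), estimates
  the number of true nulls m0 = m − r1, and stage 2 reruns BH at
  q′·m/m0. Note that the two-stage procedure is guaranteed no less
  powerful than BH *at level q′*, not at level q: for small r1 the
  stage-2 level q′·m/m0 can fall below q. Under a simulated global null
  (m = 50, 2000 repetitions) the empirical false-rejection proportion
  is ≈ q′ ≈ 0.048 at q = 0.05, within Monte-Carlo error of the nominal
  guarantee.
* One-way ANOVA with post-hoc corrections and mixed-effects models are
  deliberately not reimplemented; the module exports tidy long-format
  tables (`count_bouts_by_day()`, `normalize_frequency_by_day()`) so
  standard routines (`aov`, `lme4`) can be applied directly.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which the pipeline's recovery guarantees are stated.

## Behavior

Bout onsets follow a homogeneous Poisson process (default 1/min over a
1800 s session — struggling is rare relative to the assay), durations
are gamma(2, 1) seconds (mean 2 s), and types are drawn with head-only
most frequent (0.45/0.20/0.35), matching the observed ordering of bout
types. Bouts closer than the 0.7 s contiguity gap are merged in the
ground truth, since no detector could (or should) distinguish them.

Idle tracking noise is modeled as the characteristic quantization
flicker of markerless pose estimators on a stationary target: the
detected point alternates between two locations 0.5 px apart
(switch probability 0.7/frame) plus a 0.005 px Gaussian component.
This bounded-noise model was chosen deliberately: for *any* smooth
(e.g. Gaussian) idle-jitter distribution, the mean + 1·sd threshold
over the bottom-95% subset sits near the ~80th percentile of a Rayleigh
speed distribution and would mark 15–25% of truly idle frames mobile,
which no detector downstream could repair. Bounded flicker is both a
realistic description of tracker output on a restrained animal and the
regime in which percentile-anchored thresholds behave as intended.
During bouts the involved points scatter around their anchors with a
4 px per-axis SD. What this generator does **not** emulate: gradual
posture drift, tracking dropouts/identity swaps, and camera motion —
so passing recovery tests demonstrate correctness of the segmentation
logic under clean tracking, not robustness to tracking failure.

## Photometry

Each channel carries its own exponential bleaching (time constants 2500
and 3500 s — different on purpose, so the isosbestic regression has
real work to do), a shared *fractional* motion artifact (both channels
modulated by 1 + 0.002·a(t) with a(t) a smoothed unit-SD process;
motion changes coupling efficiency, so the artifact scales with channel
brightness), and white noise. Channels are drawn directly on the 20 Hz
analysis grid with the noise SD scaled by √(20/1000) — exactly the
distribution of 1 kHz acquisition noise after block-average decimation
to 20 Hz, at a fraction of the cost.

Transients are unit-peak double-exponential kernels (rise 0.1 s, decay
1.5 s) whose amplitude grows with bout duration:
amp = max(0, 0.005 + β·duration + N(0, 0.008)) in ΔF/F units, β = 0.02
per second by default. The defaults define the fully coupled,
bout-locked regime — every bout triggers a transient (`p_trig = 1`) and
there are no spontaneous events (`spont_rate_hz = 0`) — because that is
the condition under which the per-seed coupling-recovery guarantees
(r > 0.5, p < 0.01 per session) are stated. Unreliable coupling and
spontaneous activity are parameters, not defaults, and are exercised in
tests; each one, when placed inside the −5…−3 s baseline window of a
neighboring bout, visibly corrupts single-session correlations — which
is a faithful property of the row-normalized peri-event Z, not a bug.

## Multi-day designs

`simulate_study()` derives a deterministic seed per subject-day and
applies per-day multipliers: habituation decays the coupling
geometrically (β_day = β·δ^(day−1)), and an optional drug day
multiplies the bout rate and spontaneous transient rate (default 1.5×),
emulating an anxiogenic challenge in a repeated-restraint protocol.

# Calibration design and problem sizes

Per-seed guarantees (bout recovery, coupling r, offset destruction) are
stated on single 1800 s sessions (~30 bouts). Null-band checks pool
bouts across a small cohort of sessions (~200 bouts per seed): the null
sampling SD of r is 1/√(n−1) ≈ 0.19 at n = 30, so a ±0.15 band is
meaningless for single sessions, while pooled-bout correlations are the
unit at which such correlations are reported in practice (hundreds of
bouts across animals). The test suite uses seeds 0–9 throughout, 100
seeds for null p-value calibration, 2000 repetitions for FDR control,
and 10 replicates of 2-subject × 4-day studies for habituation
recovery; these sizes put the whole suite within a few minutes on one
CPU while keeping every Monte-Carlo band comfortably wide.

# Repository shape

The package is organized as an analysis workflow: all computation lives
in `R/` behind tested functions, and the numbered scripts under
`analysis/` are thin narrative drivers that generate a session, run
each stage, and write tables under `results/`. `run_session()` and
`run_study()` are the end-to-end entry points; there is no shell CLI
because the intended interface is R itself.

# Known limitations

* The adaptive thresholds assume the session is mostly immobile; for a
  session dominated by movement the bottom-quantile subset would itself
  contain movement frames and the threshold would inflate.
* airPLS boundary layers bias the first and last ~√λ samples of the
  baseline; metrics near the session edges inherit this.
* The transient run rule splits noisy events; frequencies are
  comparable across conditions processed identically but are not counts
  of physiological events.
* Peri-event rows from closely spaced bouts share samples and baseline
  contamination; no deconvolution is attempted.
* The generator's clean-tracking and clean-coupling defaults mean the
  acceptance numbers certify the pipeline's logic, not its behavior on
  degraded recordings.
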