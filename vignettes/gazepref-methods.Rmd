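---
title: "Methods: models, parameters and design choices in gazepref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in gazepref}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazepref)
```

# The analysis problem

In a paired-image free-viewing paradigm, a head-restrained subject (here, a
male rhesus macaque) initiates a trial by fixating a central spot; two images
of the same stimulus monkey — a face and an anogenital region (AGR) — then
appear for 3 s, one on each side of the screen, while gaze position and pupil
size are recorded at 1000 Hz. Viewing preference is quantified per trial as

\[
\mathrm{pAGR} \;=\; \frac{n_{\mathrm{AGR}}}{n_{\mathrm{AGR}} + n_{\mathrm{face}}},
\]

the proportion of in-window fixations landing on the AGR image, together with
the total number of in-window fixations, the AOI of the first post-onset gaze
shift, per-AOI dwell times, fixation counts on hand-drawn facial regions of
interest (forehead, eyes, nose, mouth), and per-fixation pupil size z-scored
against the session's pre-stimulus central-fixation baseline. Conditions are
treatment (saline SL, oxytocin OT, testosterone TE) crossed with stimulus sex
and the stimulus monkey's identity class (young/old, familiar/unfamiliar).

`gazepref` implements this entire chain — sample logs to fixation events to
AOI/ROI labels to per-trial metrics to condition summaries and tests — plus a
synthetic-gaze generator with known ground truth, so every stage can be
validated by parameter recovery rather than by eye.

# Fixation detection (I-DT)

Eye trackers usually perform event detection in proprietary firmware; this
package makes it explicit so that it is deterministic, parameter-transparent
and testable. We use dispersion-threshold identification (I-DT): a candidate
window grows sample by sample while its dispersion, defined classically as
(max−min of x) + (max−min of y), stays within `dispersion_deg`; the maximal
window is emitted as a fixation if it spans at least `min_duration_ms`,
otherwise the start position advances one sample. A velocity-threshold
detector is deliberately out of scope.

Defaults: dispersion 1.0°, minimum duration 60 ms, merge gap 20 ms, blink
padding 50 ms. Blinks are maximal runs of zero-pupil or invalid samples,
padded on both sides (pupil estimates are unreliable around lid closure);
samples inside padded intervals are excluded from both fixation detection and
pupil averaging, and a blink always terminates the current window — fixations
never span a blink. Consecutive fixations closer than the merge gap are
merged only when their combined dispersion still fits the threshold.

Two numerical conventions matter and are pinned by tests:

* A fixation covering samples $t_i \dots t_j$ has `offset = t_j + dt`
  (half-open interval, `dt` the nominal sampling period), so a 300-sample
  constant trace at 1000 Hz yields a 300 ms fixation.
* The greedy maximal-window semantics are checked *exactly* against a
  brute-force enumeration oracle that recomputes every dispersion from
  scratch (200 random traces of up to 2000 samples per run).

The test suite demonstrates two practical limits. First, when two successive
landing points fall within one dispersion span (|Δx|+|Δy| ≤ 1°), I-DT cannot
distinguish them from a single fixation — with uniformly drawn landing
points this affects a few percent of fixation pairs and is inherent to the
algorithm, not a defect. Second, *independent* per-sample position noise
accumulates into the window's range statistic, so the tolerable i.i.d. noise
SD (~0.02–0.03° at these durations) sits well below the dispersion threshold
itself; real tracker noise is temporally correlated and better behaved. The
recovery tests therefore inject noise at 0.02°.

# AOI and ROI assignment

Fixations are assigned to `face`, `agr` or `off` by their centroid (not by
per-sample majority — the simplest deterministic rule). Window rectangles are
half-open (left/top edges inclusive) so that every point receives exactly one
label. Facial ROIs are closed polygons tested in the fixed precedence order
forehead → eyes → nose → mouth, with inclusive boundaries; anything else in
the window is `other`. Polygon membership is even-odd ray casting and areas
are shoelace sums, both implemented here with explicit boundary semantics
(no installed geometry package documents its boundary behaviour). The default
ROI layout concentrates forehead+eyes in ~10.3% of the window area, matching
the compact hand-drawn regions typical of macaque face stimuli.

Heat maps are 50×50 histograms per image window (raw counts conserve the
sample count exactly); optional Gaussian smoothing (σ = 1 bin) produces a
density normalized to sum 1.

# The synthetic-gaze generator

The generator emulates the behavioural structure the analysis assumes, with
every generative parameter exposed in `gaze_config()`:

* **Trial skeleton** — 500 ms central-fixation baseline, then exactly 3000 ms
  of display samples at 1000 Hz; jittered 2–3 s inter-trial gaps (timestamps
  jump; no samples are emitted between trials).
* **Fixation targets** — the first display fixation lands on the AGR window
  with probability `q_first` (condition-dependent; optionally shifted by a
  side bias), subsequent targets are i.i.d. Bernoulli(`theta_pagr`). The
  i.i.d. choice makes E[pAGR] equal θ exactly, keeping recovery tests sharp;
  a stay/switch Markov option (`stay_prob`) is accepted but off by default
  because the switching dynamics are not part of the measured design.
* **Durations** — lognormal, calibrated by
  `calibrate_lognormal(mean, median)`: μ = log(median),
  σ = √(2·log(mean/median)), which reproduces both moments exactly. The
  defaults (mean 246.65 ms, median 213.00 ms) give ~10.5 fixations per 3 s
  trial once 40 ms linear saccade sweeps are added — consistent with the
  ~11 fixations/trial seen in unconstrained macaque viewing.
* **Landing points** — within the AGR window uniform; within the face window
  a mixture over ROIs (default weights: forehead .345, eyes .35, nose .12,
  mouth .08, other .105, uniform within each region), concentrating gaze on
  forehead and eyes as macaques do.
* **Pupil** — per-trial baseline level ~ N(`pupil_base_mean`,
  `pupil_base_sd`), plus an AOI-dependent offset expressed on the z scale of
  the session baseline (default: AGR −0.3 z, mirroring the smaller pupils
  seen during AGR viewing), plus stationary AR(1) noise (φ = 0.95, SD 60 au).
  Offsets are scaled internally by the total baseline SD so the z-scored
  recovery target equals the configured value.
* **Blinks** — a Poisson process (default 0.1/s, 100 ms) of zero-pupil gaps
  with gaze marked invalid.
* **Determinism** — one root seed; per-trial streams are derived by counter,
  so any trial is reproducible in isolation and session CSVs are
  byte-identical across reruns.

Condition defaults encode the study design the package addresses: per-trial
AGR preference θ for female images 0.68/0.70/0.71 under SL/OT/TE and
0.69/0.69/0.70 for male images; first-gaze probability 0.78 (SL and OT) and
0.84 (TE) for female images, 0.81 throughout for male images. Screen
geometry is not part of the measured design, so windows default to 8°×8°
centred ±8° horizontally with a 3°×3° central fixation window — plumbing
choices, stated once and never tuned. Condition structure is treatment ×
image sex; identity-class-specific generative effects are not modelled
(trials still carry age/familiarity labels, so class-level analyses run on
synthetic data and recover null effects, which is the correct truth for this
generator).

What the generator does **not** emulate: smooth pursuit, microsaccades, head
motion, saliency-driven scan paths beyond the ROI mixture, luminance-driven
pupil responses, or any dependence of fixation duration on content. Passing
recovery tests therefore validates the *pipeline arithmetic* on data with
the assumed structure; they say nothing about detector performance on
pursuit-rich or noisy real recordings.

# Pupillometry

The baseline is the pooled set of valid pre-stimulus central-fixation pupil
samples of a session (per-trial baselining is available but not the default:
500 ms baselines are noisy, and the pooled variant makes z-scores comparable
across a session). Per-fixation pupil is the arithmetic mean of valid,
non-blink samples in the fixation's half-open interval, and
z = (pupil − baseline mean)/baseline SD. A zero-SD baseline is flagged
degenerate and refuses to produce z-scores. Pupil units are arbitrary and
never converted; all inference uses z-scores. No luminance correction is
attempted (stimuli in this paradigm are luminance-matched upstream).

# Statistical battery

All tests are two-tailed. The battery mirrors the paradigm's standard
toolkit:

* **Wilcoxon signed-rank** (paired): zeros dropped, ties through average
  ranks; exact null by sign-pattern convolution for n ≤ 25, else normal
  approximation with tie and continuity correction.
* **Wilcoxon rank-sum**: exact for min(n) ≤ 10 without ties, else
  tie-corrected normal approximation.
* **Pearson χ²** against a null proportion (df 1) or independence; no
  continuity correction (plain Pearson statistic); expected counts below 1
  raise an error advising an exact test.
* **Factorial ANOVA (1–3 factors)** with type-II sums of squares (via
  `car::Anova`): near-balanced designs make type-II the stable choice for
  main effects, and the choice is recorded in the result object. Empty cells
  with interactions requested raise an error naming the cell.
* **Tukey HSD** on a fitted factor (studentized range; degenerates to the
  plain t-test for two groups), and **Pearson r** with the t-transform p.

The exact-versus-approximate thresholds are documented constants. The
acceptance suite checks the exact branches against enumeration oracles
(identical p to 1e-12) and calibrates each test's type-I error to 5% ± 1%
over 10⁴ null replicates.

# Problem sizes and tolerances used by the validation suite

The recovery checks run at the paradigm's own scale: 9 sessions × 120
female-image trials (1080 trials) per condition for preference and
first-gaze recovery (tolerances ±0.02 and ±0.03), 2040 trials for the
pAGR-vs-total-fixations decorrelation bound (|r| < 0.05), 10⁵ draws for the
duration calibration (±2%), ≥10⁴ fixations for pupil-offset recovery
(±0.05), and 200 traces for detector-oracle equivalence (exact). The full
suite completes in a few minutes on one CPU; these sizes were chosen so that
Monte-Carlo error sits well inside each tolerance.

Two aggregate behaviours deserve explicit notes:

* Mean per-trial pAGR slightly exceeds θ (by ≈ (q_first−θ)·E[1/N] ≈ 0.01
  under defaults) because the first fixation follows the first-gaze
  probability, not θ. This is a property of the measured quantity itself,
  not an estimator bias, and stays well inside the recovery tolerance.
* Fixation count and dwell correlate strongly *per image* (more fixations on
  an image ⇒ more dwell on it). Trial-total dwell is nearly constant at 3 s
  display length, so the count–dwell coupling is tested per image cell.

# Known limitations

* The detector is offline and single-pass; no velocity-based or
  machine-learned event classification.
* ROI maps are hand-specified polygons; no automatic extraction from image
  content.
* The battery covers the paradigm's summary statistics; trial-level mixed
  models are out of scope.
* Familiarity is binary room co-residence; dominance is not inferred.
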