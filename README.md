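# gazepref

Free-viewing gaze-preference analysis for paired-image eye-tracking
paradigms, built for the macaque "face versus anogenital region (AGR)"
design: on each 3 s trial a face and an AGR image of the same stimulus
monkey appear side by side while gaze and pupil are sampled at 1000 Hz, and
the question is which image attracts gaze, how strongly, and how treatments
(saline, oxytocin, testosterone) shift that preference.

The core statistic is the per-trial proportion of fixations on the AGR
image,

```
pAGR = n_AGR / (n_AGR + n_face),
```

complemented by the total in-window fixation count, the first-gaze AOI, per
image dwell time, facial region-of-interest (forehead/eyes/nose/mouth)
fixation percentages, and per-fixation pupil size z-scored against the
session's pre-stimulus fixation baseline.

The package provides every stage as a tested, reusable function:

* `read_samples()` / `write_samples()` — open TSV sample logs
  (`session trial t_ms x_deg y_deg pupil_au valid`), `segment_trials()`.
* `detect_blinks()`, `detect_fixations()` — dispersion-threshold (I-DT)
  event detection with documented parameters
  (`detector_params()`: 1.0° dispersion, 60 ms minimum duration, 50 ms blink
  padding, 20 ms merge gap), checked exactly against a brute-force oracle.
* `assign_aoi()`, `assign_roi()`, `roi_area_fractions()`, `gaze_heatmap()`.
* `compute_trial_metrics()`, `first_gaze()`, `aggregate_metrics()`,
  `roi_fixation_percentages()`.
* `baseline_stats()`, `fixation_pupil()`, `zscore_pupil()`.
* A two-tailed statistical battery: `wilcoxon_signed_rank()`,
  `wilcoxon_rank_sum()` (exact at small n), `chi2_proportion()`,
  `chi2_contingency()`, `anova_factorial()` (type-II SS), `tukey_hsd()`,
  `pearson_r()`.
* A synthetic-gaze generator (`gaze_config()`, `simulate_trial()`,
  `simulate_session()`) with known ground truth, so the whole pipeline is
  validated by parameter recovery.
* `run_pipeline()` / `make_report()` to orchestrate catalogue → plans →
  simulate (or ingest) → detect → map → metrics → pupil → stats, with full
  seed determinism and CSV outputs.

## Worked example

Simulate one session per treatment for the female image set (6 stimulus
monkeys × 20 image pairs = 120 trials per session) and run the full
analysis:

```r
library(gazepref)

cfg <- pipeline_config(
  catalogue = "female",
  sessions = data.frame(subject = "M1", treatment = c("SL", "OT", "TE")),
  seed = 2024)
res <- run_pipeline(cfg)
res
#> <gaze_analysis> 3 sessions, 360 trials, 3825 fixations
#> mean pAGR by condition:
#>   OT/female: 0.730 +/- 0.012 (n = 120)
#>   SL/female: 0.694 +/- 0.013 (n = 120)
#>   TE/female: 0.719 +/- 0.013 (n = 120)
```

Each line is the condition mean ± s.e.m. of per-trial pAGR over that
session's 120 trials: values near 0.7 say that roughly seven of ten
in-window fixations landed on the AGR image, and the saline condition sits
lowest because the generator's default preference parameters rise from
0.68 (SL) to 0.70 (OT) and 0.71 (TE) for female images. `make_report(res)`
renders the full set of condition tables (counts, dwell, first-gaze
proportions, ROI percentages, pupil z contrasts) and the test battery as
Markdown; `run_pipeline()` writes the same tables as CSVs when
`out_dir` is set, alongside a provenance JSON carrying the seed and a config
hash.

## Documentation

The methods vignette (`vignettes/gazepref-methods.Rmd`) describes the
detection algorithm and its conventions, the generator's assumptions and
what passing recovery tests do and do not establish, the pupil model, the
statistical battery's exact/approximate branches, and all numerical
defaults.
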