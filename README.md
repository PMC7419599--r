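# postprime

Analysis of fear-primed step-and-reach experiments: from raw multi-rate
laboratory channels to movement-preparation metrics and group statistics.

## The scientific problem

Fear of falling reshapes how people prepare and execute whole-body
movement. A fear-priming paradigm exposes standing participants to four
blocked surface conditions of increasing slip threat — no lubricant (NL),
lubricant under the planted leg (LP), under the step landing area (LL), and
both (LB) — while they reach to a target "as fast as possible" and step
forward. Each 8 s trial records 16-channel surface EMG (2000 Hz), two
tri-axial force plates (1000 Hz), whole-body kinematics (100 Hz) and a
binary infrared reach sensor; before each condition block participants mark
two 100 mm visual-analogue scales (likelihood of, and concern about,
falling). The question is whether primed fear changes *preparatory*
behaviour (anticipatory CoP shifts, muscle onsets before the reach,
co-contraction) and *compensatory* behaviour (step geometry, CoM
excursions, joint excursions), and whether age moderates those changes.

postprime implements the full analysis chain for this paradigm, aimed at
movement scientists who want a tested, configurable, scriptable
reimplementation rather than lab-specific MATLAB code:

* **Signal conditioning** — 40-point Savitzky–Golay kinematic smoothing
  with quiet-stance DC removal; EMG notch (60 Hz) → demean → rectify →
  zero-lag 4th-order Butterworth (100 Hz) envelopes, normalized per
  participant × muscle across all conditions.
* **Event detection** — reach onset/offset from the sensor edges; CoP
  onset (baseline mean ± 3 SD sustained 25 ms, with back-extrapolation
  refinement); step onset/offset from landing-limb unloading and
  landing-zone loading (5% thresholds).
* **EMG metrics** — muscle onsets via the sustained supra-threshold rule
  (envelope > baseline mean + 7 SD held for 50 ms), latencies relative to
  reach onset, and co-contraction indices (amplitude-weighted min/max
  form) over four reach-anchored phases.
* **Movement metrics** — step length/width/time from malleoli positions at
  landing; preparatory CoM excursion and peak acceleration on
  `[CoP onset, step onset]`; total CoM and peak-to-peak joint excursions
  across the movement.
* **Statistics** — per-metric two-way mixed repeated-measures ANOVA
  (Condition × AgeGroup) from first-principles sums of squares, Mauchly /
  Greenhouse–Geisser sphericity handling, partial eta squared, the
  divided family-wise alpha `0.05 / (#DVs × 2)`, and Bonferroni post hocs.
* **Synthetic cohorts** — a ground-truth generator reproducing the
  2 × 10 participant, 4-condition × 3-trial blocked design at native
  sampling rates, used by the test suite to validate every stage.

The core effect-size identity used throughout is
`η²p = F·df1 / (F·df1 + df2)`.

## Worked example

Audit a published effect size from its printed F statistic and degrees of
freedom:

```r
library(postprime)
partial_eta_squared(19.020, 1, 18)
#> 0.5137802
```

Simulate a small cohort and run the whole pipeline (conditioning → events →
metrics → mixed ANOVA):

```r
spec <- cohort_spec(n_per_group = 4, trials_per_condition = 2, seed = 42)
res  <- analyze_cohort(spec)
subset(res$anova, metric %in% c("step_width", "total_com_exc_ml"))
```

```
           metric          effect     F df1 df2        p eta_p2 alpha_adj significant
       step_width       condition  72.0   3  18 3.21e-10  0.923   0.00625        TRUE
 total_com_exc_ml       condition  30.7   3  18 2.70e-07  0.837   0.01250        TRUE
 total_com_exc_ml condition:group 114.3   3  18 6.56e-12  0.950   0.01250        TRUE
```

Step width widens with surface threat (condition main effect, tested at its
family's divided alpha of 0.05/8), and total mediolateral CoM excursion
shows the configured group × condition interaction: the generator injects a
YOUNG increase and a slight OLDER decrease under the double-lubricant
condition, and the pipeline recovers both the effect and its direction.
`res$cohort_metrics` holds the long per-trial metric table,
`res$posthoc` the Bonferroni-adjusted pairwise follow-ups, and `res$qc`
per-trial quality flags.

Trial bundles can also be written to and read from disk
(`simulate_cohort_bundles()`, `read_trial_bundle()`), and
`run_pipeline("config.yaml", out_dir = "run1")` drives the same stages from
a single YAML configuration; a thin command-line front end lives at
`inst/cli/postprime` (`postprime simulate|analyze|run-all`).

See the vignette (`vignettes/fear-priming-methods.Rmd`) for the model,
every threshold and its provenance, and known limitations.

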