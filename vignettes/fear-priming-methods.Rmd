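---
title: "Methods: from multi-rate step-and-reach recordings to mixed-ANOVA tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multi-rate step-and-reach recordings to mixed-ANOVA tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postprime)
```

## The analysis problem

postprime analyses a fear-priming step-and-reach experiment: standing
participants reach to a target "as fast as possible" while stepping forward,
under four blocked surface conditions of increasing slip threat — no
lubricant (NL), lubricant under the planted leg (LP), under the landing area
(LL), and both (LB). Two age groups (YOUNG, OLDER; 10 participants each)
perform 3 trials per condition, and before each condition block report two
100 mm visual-analogue fear scores ("likely to fall", "concerned about
falling"). Each 8 s trial records 16-channel surface EMG at 2000 Hz, two
tri-axial force plates at 1000 Hz, whole-body kinematics (CoM, seven joint
angles, malleoli) at 100 Hz, and a binary infrared reach sensor.

The pipeline turns these raw channels into (a) an event timeline per trial,
(b) muscle-onset latencies and co-contraction indices, (c) preparatory and
compensatory movement metrics, and (d) a per-metric two-way mixed
repeated-measures ANOVA (Condition × AgeGroup) with family-wise alpha
control.

## Signal conditioning

Kinematic channels are smoothed with a 40-point Savitzky–Golay filter
(polynomial order 3). Two conventions deserve a note. First, a symmetric
least-squares smoother needs an odd window, so a 40-sample request runs as a
41-point fit; at 100 Hz that is a 0.41 s window. Second, the polynomial
order is not dictated by the window length; order 3 is the standard choice
for positional data because it preserves curvature while suppressing noise.
The quiet-stance DC offset (mean of the first 0.5 s) is subtracted from CoM
channels; malleoli positions keep their absolute values because step length
and width are inter-landmark distances.

Raw EMG goes through, in order: a 60 Hz biquad notch (quality factor 30 —
narrow enough to leave the EMG spectrum essentially untouched), demeaning,
full-wave rectification, and a zero-lag 4th-order Butterworth low-pass at
100 Hz. "Zero-lag 4th order" is realised as a 2nd-order design run forward
and backward: the effective magnitude response is 4th order and the phase is
exactly zero. The alternative reading (a 4th-order design applied twice,
effective 8th order) is a common ambiguity; this package uses the first.
All filtering reflect-pads the trial so onsets near the boundaries are not
distorted, and small negative excursions left by filter ringing are clipped
to zero to preserve envelope semantics. Envelopes are then normalized per
participant and muscle by the maximum amplitude across *all* trials of all
four conditions, so within-participant condition contrasts survive
normalization.

## Event timeline

Five events anchor every metric (all snapped to samples of their source
stream; time zero at the first sample):

* **reach_on / reach_off** — rising and falling edges of the infrared beam
  channel (hand departure, target contact).
* **cop_on** — onset of the net centre-of-pressure shift. The criterion is
  the first excursion of either CoP axis beyond the quiet-stance mean ± 3 SD
  sustained for 25 ms; the original study does not state its algorithm, so
  every threshold is configurable. The raw sustained-crossing time is biased
  late by construction (the signal must climb to the threshold), so by
  default the crossing is refined by fitting a line to the 50 ms after the
  crossing and extrapolating back to the baseline mean — exact for ramp-like
  shifts at zero noise, and unbiased in the presence of noise. For noisy
  plates a zero-phase low-pass (`lp_hz`) can be applied first; the sustain
  requirement should then be stretched to match the smoothed noise
  correlation time (e.g. 10 Hz with 100 ms).
* **step_on** — landing-limb unloading: vertical force of the landing limb
  first drops below 5% of its quiet-stance value.
* **step_off** — landing-zone loading first exceeds 5% of body weight.
  Both fractions are configurable; the study states neither.

A deviation threshold floor of 1 µm keeps a numerically noiseless baseline
from firing on floating-point residue.

## Movement metrics

Step length and width are the AP and ML distances between support and
landing malleoli evaluated at `step_off` (foot flat at landing); step time
is `step_off − step_on`. Preparatory CoM excursion and peak acceleration are
computed on `[cop_on, step_on]`; total CoM excursions and the seven
peak-to-peak joint excursions on the movement interval, taken as
`[cop_on, reach_off]` — the study does not state whether "duration of
movement" ends at target contact or trial end, and target contact was chosen
because every analysed behaviour completes by then; the interval is an
argument.

Peak CoM acceleration uses a Savitzky–Golay second-derivative filter (same
window and order as the smoother) rather than double-differencing the
smoothed position: at realistic kinematic noise the double difference
roughly triples the apparent peak, while the SG derivative stays close to
the noiseless value. Whether the study reports a peak or a mean preparatory
acceleration is unstated; the peak magnitude is used, with its sign kept in
a separate column. Note that any finite smoothing window attenuates an
acceleration peak that sits at a curvature discontinuity — on the synthetic
cohort the recovered peak is roughly 60–65% of the analytic value of the
constructed path. Excursions are unaffected (the smoother is linear, so
between-condition differences pass through exactly).

## Muscle onsets and co-contraction

A muscle onset is the first envelope sample exceeding the quiet-stance
baseline mean + 7 baseline SD that stays above threshold for a full 50 ms.
"7 SD of average baseline activity" is read as mean + 7 × SD; the reading
7 × mean was rejected as dimensionally inconsistent with "SD". The baseline
window is the first 0.5 s of the trial (configurable). The original
analysis confirmed onsets visually; here implausible onsets are surfaced as
queryable QC flags instead, and muscles with no detected onset are excluded
from onset statistics (never imputed), with counts reported. Latencies are
signed relative to `reach_on` (negative = preparatory).

The co-contraction index of an agonist–antagonist pair over a window is, by
default, the amplitude-weighted form

$$\mathrm{CCI} = \frac{1}{n}\sum_t \frac{\min(a_t, b_t)}{\max(a_t, b_t)}\,(a_t + b_t),$$

symmetric in the pair, bounded by [0, 2] for normalized envelopes, and
deliberately *not* scale-invariant (doubling both envelopes doubles it): it
measures how much the pair co-contracts, not merely how similar the traces
are. The literature's CCI variants differ; the plain ratio mean
(`method = "ratio"`, range [0, 1], scale-invariant) is provided as an
alternative, and results should state which was used. CCI is evaluated over
four phases anchored to the reach: (i) early, −1.5 to −0.5 s; (ii)
preparatory, −0.5 to 0 s; (iii) movement, 0 to +0.5 s; (iv) termination, the
0.5 s before target contact. Phases i–ii are tagged preparatory, iii–iv
compensatory. Which muscles formed pairs originally is unstated; defaults
are trunk (erector spinae vs rectus abdominis) and shank (tibialis anterior
vs gastrocnemius), bilaterally, and the pair table is fully configurable.

## Statistical layer

Trials are averaged to one score per participant × condition before
analysis (the study analyses condition-level values; per-trial mixed models
would be an alternative, deliberately not taken). Each metric then gets a
two-way mixed repeated-measures ANOVA with sums of squares computed from
first principles on the balanced design; the decomposition is verified
against the total sum of squares on every call, and the test suite checks
the F statistics against R's independent `aov()` Error-stratum route to
1e-10.

Sphericity of the condition factor is assessed with Mauchly's test on the
pooled within-group contrast covariance; when rejected at 0.05 the
Greenhouse–Geisser ε (bounded by [1/(k−1), 1]) multiplies both
within-factor degrees of freedom. Effect sizes are partial eta squared,
η²p = F·df1/(F·df1 + df2), an identity that also lets published effect
sizes be audited from their printed F and dfs. Four published joint- and
CoM-excursion effect sizes (0.597, 0.585, 0.402, 0.391) are inconsistent
with this identity at their printed dfs of (1, 18) — possibly different
error terms or typos — and are flagged rather than used as references.

The family-wise correction follows the study's stated rule literally: the
significance level is 0.05 divided by (number of DVs in the family × 2
tests per DV), e.g. 0.005 for a five-DV family. This is a Bonferroni-style
divided alpha, not the sequentially rejective Holm procedure; the true
step-down procedure is available as `holm_sequential()` for comparison.
Post hoc paired comparisons (conditions within group, groups per condition
for interactions) are Bonferroni-multiplied and capped at 1, and are
refused when the omnibus effect is not significant — matching the original
workflow.

## The synthetic cohort generator

Because the study's recordings are available only on request, every stage
is validated against a generator whose constructions *are* the ground
truth:

* **EMG** — baseline Gaussian noise (SD 0.02 a.u.) plus a 60 Hz mains
  component, with each muscle burst an amplitude-modulated noise carrier
  whose envelope rises over a 10 ms half-cosine ramp (ground-truth onset =
  ramp start; an instantaneous step would make "the" onset ambiguous after
  filtering). Default burst SNR is 10.
* **Force plates** — logistic landing-limb unloading (≈90 ms 5–95% width)
  crossing the 5% threshold exactly at the true `step_on`; landing-zone
  reloading likewise anchored to `step_off`; net vertical force equals body
  weight in quiet stance. The anticipatory CoP shift is a linear ML ramp
  (0.03 m over 150 ms) starting exactly at `cop_on`, with the AP shift
  50 ms later.
* **Kinematics** — piecewise half-cosine CoM paths reaching the configured
  preparatory excursion at `step_on` and the total excursion at
  `reach_off`; raised-cosine joint-angle bumps with configured peak-to-peak
  amplitudes; the swing foot reaches its landing position halfway through
  `[step_on, step_off]` (feet are flat before the loading threshold trips),
  which makes zero-noise step-geometry differences recover exactly through
  the smoothing chain.
* **Design effects** — each metric follows
  `base + condition + group + interaction + participant-intercept +
  trial noise`, clipped where physically required (VAS to [0, 100]). The
  defaults encode the study's qualitative findings as generative truth:
  VAS rising ≈15 mm per condition step; wider (≈+0.03 m in LB) and slightly
  shorter steps under threat; +8° lumbar, +3° thoracic, −5° ankle excursion
  in LB; a group × condition interaction on total ML CoM excursion (YOUNG
  +0.03 m in LB, OLDER −0.01 m); and rectus abdominis/gastrocnemius onsets
  that precede the reach in YOUNG (−50 ms) but follow it in OLDER
  participants (+80 ms), with OLDER steps following the reaching arm in LB.
  Magnitudes the study does not print were chosen once at values a movement
  scientist would call realistic for this task and are not tuned.

Streams are generated at their native rates (2000/1000/100 Hz), so the
pipeline genuinely exercises multi-rate alignment. A single master seed is
expanded per trial by a counter scheme: any trial can be regenerated alone,
bit-identically, and trials are mutually independent. All synthetic trials
are analyzable by construction — the study reports no exclusions or falls,
so none are modelled.

What the generator does *not* emulate: marker-level kinematics,
musculoskeletal dynamics, non-stationary or heteroscedastic EMG noise,
slips/falls, or learning across blocks. Passing tests therefore demonstrate
the correctness of the algorithms on signals with the study's structure,
not robustness to every artefact of real laboratory data.

## Numerical choices and problem sizes

Event detection runs on the force-plate clock (1000 Hz); kinematic metrics
interpolate to event times. Interval memberships use a 1 ns tolerance so
grid rounding cannot drop an endpoint sample. Degenerate inputs fail loudly:
zero-variance responses, unbalanced cells, dead EMG channels and degenerate
baselines are errors, while a failing trial inside a cohort run is QC-flagged
and excluded without stopping the run.

The test suite exercises: detector-vs-brute-force equivalence on 200
envelopes; onset recovery on a 16-trial cohort at burst SNR 8 plus 500 null
channels; 50 random designs against the `aov()` oracle; type-I calibration
on 500 null score cohorts at the 0.005 family alpha; and one full
240-trial end-to-end cohort. These sizes were chosen to give stable
statistics while keeping a complete run comfortably fast on a laptop.

## Known limitations

* The divided-alpha rule is implemented as stated by the study even though
  it is Bonferroni, not sequential Holm; both are available.
* The CCI formula of the study's cited reference is not reproduced in the
  text; two standard variants are implemented and flagged until the
  reference formula is confirmed.
* Peak accelerations at curvature discontinuities are attenuated by the
  smoothing window (see above); comparisons across conditions remain valid
  because the attenuation is a fixed linear factor for a fixed movement
  duration.
* Real-data CoM estimation (segmental weighted sum from markers) is out of
  scope; the CoM stream is a pluggable input.
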