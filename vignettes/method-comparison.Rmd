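---
title: "Validating a cardiac-output monitor: the statistics behind cotrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a cardiac-output monitor: the statistics behind cotrend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotrend)
```

## The problem

A new continuous cardiac-output (CO) monitor — here, an uncalibrated
arterial pulse-contour device — must be validated against an accepted
reference such as transpulmonary thermodilution before clinicians can trust
it. A validation study measures both methods simultaneously in the same
patients at several perioperative timepoints and asks three questions:

1. **Accuracy** — do absolute CO values agree (bias, limits of agreement,
   percentage error)?
2. **Trending ability** — when CO changes between timepoints, does the
   device change in the same direction and by a comparable amount
   (four-quadrant and polar-plot analysis)?
3. **Fluid responsiveness** — does the device classify the stroke-volume
   (SV) response to a fluid bolus the same way the reference does?

cotrend implements this full analysis pipeline, plus a synthetic-study
generator with known ground truth, so that every statistic can be verified
by parameter recovery rather than against an unavailable patient dataset.

## Data model

Measurements live in long format: one row per (subject, timepoint, method,
variable, calibration state). Variables are CO (L/min) and SV (mL);
calibration states are `precal` / `postcal` for devices with an on-demand
auto-calibration mode and `na` for the reference. Timepoints are categorical
labels with a declared order (default `T0`–`T7`, induction of anesthesia to
16 h after ICU admission); elapsed-time analyses are out of scope. The fluid
challenge occupies one adjacent timepoint pair, by default `T4 → T5`.

### Thermodilution triplicates

The reference value at a timepoint is the mean of three thermodilution
readings. Each reading carries a global end-diastolic volume (GEDV) as a
quality signal: if the GEDV readings vary excessively, a fourth measurement
is taken and the extreme one excluded. Two details are under-determined in
common protocol wording and were fixed here as explicit conventions:

* *"varied by more than 10%"* is interpreted as the relative range
  (max − min)/mean of the GEDV readings exceeding the threshold (default
  0.10, configurable). It is the simplest symmetric spread criterion.
* *"the extreme one"* is the reading whose GEDV lies farthest from the
  median GEDV — the trigger is GEDV variation, so extremeness is judged on
  GEDV. Ties break by the larger CO deviation from the CO median, then by
  the later position, making the rule deterministic and
  permutation-invariant.

Three readings with excessive spread and no fourth available raise an
"incomplete set" error rather than silently averaging.

## Agreement: Bland-Altman with repeated measurements

Differences are $d = \mathrm{CO}_{ref} - \mathrm{CO}_{test}$ (configurable;
with this convention a negative bias means the device over-reads). Because
each subject contributes several pairs *and the true CO genuinely changes
between timepoints*, the variance of a difference is estimated by the
variant of the repeated-measures Bland-Altman method for true values that
vary within subjects: a one-way random-effects decomposition of the
differences by subject,

$$\widehat\sigma_d^2 = MSW + \frac{MSB - MSW}{m_0},\qquad
  m_0 = \frac{N^2 - \sum_i m_i^2}{(n-1)\,N},$$

where $m_i$ is subject $i$'s number of pairs, $N=\sum m_i$, $n$ the number
of subjects, and MSB/MSW the between-/within-subject mean squares. The
limits of agreement are $\bar d \pm 1.96\,\widehat\sigma_d$. Numerical
conventions:

* a negative moment estimate of the between-subject component is clamped to
  zero and flagged (`clamped`), the standard moment-estimator practice;
* when every subject has exactly one pair the decomposition is undefined;
  the function falls back to the ordinary SD of the differences with a
  warning and a result flag — in that case the repeated-measures analysis
  coincides with the classical Bland-Altman, which the test suite asserts;
* the estimator is verified against a brute-force sums-of-squares oracle
  over the exhaustive grid of designs with up to 5 subjects × 4 pairs, to
  1e-10.

The percentage error is
$PE = 1.96\,\widehat\sigma_d \big/ \tfrac12(\bar{CO}_{ref} +
\bar{CO}_{test}) \times 100\%$, with the denominator read literally as the
arithmetic mean of the two method means over the same pairs. PE is
scale-invariant. The conventional acceptability bound is 30%.

Pre- and post-calibration pairs are analysed separately by default (the
calibration state is an argument to `align_pairs()`); pooling is possible by
relabelling, but mixing states hides exactly the drift effects the study
design separates.

## Trending: four-quadrant and polar analysis

`compute_deltas()` forms per-subject changes between consecutive *observed*
timepoints. A missing intermediate timepoint is bridged (the delta spans the
gap, recorded in `gap`) rather than discarding the segment — with occasional
catheter failures this preserves the delta counts a study reports. Both
interval ends use the same calibration state; for the post-calibration
analysis that means the previous timepoint's post-calibration value is the
baseline, which is the implemented reading of an ambiguous convention.

**Four-quadrant.** A pair is concordant iff
$\Delta_{ref}\cdot\Delta_{test} > 0$. Pairs with a zero product lie on an
axis, belonging to neither agreement nor disagreement, and are dropped from
the denominator. Small changes are noise-dominated, so a central exclusion
zone (default 0.75 L/min, about 12.5% of a typical 6 L/min CO) removes pairs
whose *mean absolute* delta is below the zone; rates with and without
exclusion are both reported. The mean-rule is symmetric in the two methods
and matches the polar radius definition; `either`/`both` rules are available.

**Polar.** Each pair maps to the angle of $(\Delta_{ref}, \Delta_{test})$
to the identity line: $\theta_{raw} = \operatorname{atan2}(\Delta_{test},
\Delta_{ref})$, reflected by 180° into the right half-plane when the mean
change is negative (so a negative change tracked perfectly by both methods
also scores 0°), then rotated by −45° and wrapped to (−180°, 180°]. The
radius is $|\Delta_{ref}+\Delta_{test}|/2$ — the mean CO change — read from
the conventional plot description as the average of the two methods'
changes, which keeps the radius in L/min and comparable to the 0.5 L/min
polar exclusion zone (the plausible alternative, the average CO *level*, is
documented but not implemented). Reported statistics: the angular bias
(arithmetic mean of included angles — acceptable rather than a circular mean
because reflection confines angles near 0; a limitation at extreme
discordance) and the polar concordance rate (fraction within ±30°,
inclusive). Exclusion is strict (`radius < zone`), concordance inclusive
(`|angle| ≤ limit`). A pair with zero change in both methods has no
direction and must be excluded by the caller (the pipeline does so and logs
it).

## Fluid responsiveness

$\Delta SV\% = 100\,(SV_{post}-SV_{pre})/SV_{pre}$ across the bolus
interval; a responder has *strictly more than* a 10% increase (so exactly
10.0% is a non-responder — the wording "more than" is taken literally;
threshold configurable). The device's change is computed in two pairing
modes — auto-calibrated before and after the bolus, and auto-calibrated
before with non-calibrated after — because recalibrating between the two
readings can mask or mimic a true SV change; the pipeline reports both.
Cross-method agreement is the count of identical classifications. The
fluid-induced changes are correlated by Spearman's rank coefficient
(exact p-value below n = 10, t-approximation otherwise), and correlations
from different arterial sites are compared with the Fisher z transformation.
That comparison assumes independent correlations even though both share the
thermodilution arm; the dependence makes the test conservative in typical
positive-dependence settings, and the printed form is what validation
studies report, so it is implemented as such with this caveat.

## Descriptive summaries and contrasts

`describe_values()` reports mean (SD) and median (25th–75th percentile) with
a Shapiro-Wilk test (α = 0.05) choosing the displayed form; percentiles use
linear interpolation between order statistics (`quantile()` type 7), a
convention that must be fixed because protocols rarely state one.
`baseline_contrasts()` tests each timepoint against baseline on paired
differences — paired t when Shapiro-Wilk on *the differences* (per contrast,
not per variable) is non-significant, Wilcoxon signed-rank otherwise, with
zero differences dropped (Wilcoxon's original convention) — flagged
significant at the Bonferroni level 0.05/m (default m = 7 non-baseline
timepoints). All-equal differences yield p = 1: a constant shift without
variance is not testable by a paired test and, in the all-zero case, is
correctly never significant.

## The synthetic-study generator

`simulation_config()` defaults encode the study conditions the pipeline is
designed for: 25 subjects × 8 timepoints; a true-CO trajectory with
population means (4.3, 6.8, 6.2, 5.9, 5.5, 5.9, 5.8, 5.9) L/min — low
before bypass, elevated after, overall mean ≈ 5.9 — with between-subject
SD 1.0 and within-subject SD 0.5 L/min; heart-rate means rising from 59 to
≈ 80 bpm so SV = CO/HR × 1000 is realistic; triplicate thermodilution with
per-reading SD 0.3 L/min and GEDV readings at 2% CV around a subject mean
(≈ 1500 ± 200 mL), with a configurable probability (default 5%) of a GEDV
outlier that forces a fourth reading and exercises the exclusion rule; a
fluid bolus between T4 and T5 with responder fraction 7/22 and ΔSV% drawn
from N(20, 5²) for responders and N(2, 4²) for non-responders; and two test
channels with additive biases +0.31 (radial) and +0.57 (femoral) L/min under
the reference-minus-test sign convention.

A device reading at 0-based schedule step $t$ is

$$\text{pre} = s\cdot CO_{true} + b + \delta\,t + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma^2),$$

the simplest model exposing all downstream statistics; the auto-calibration
reset replaces the accumulated drift term with an independent residual
$N(0, \sigma_{res}^2)$. Drift magnitudes are **illustrative**: no published
estimate exists for the modelled device class, so the defaults
(0.1 L/min/step) merely create a visible pre/post contrast. All draws come
from one seeded stream in a documented order, so identical (config, seed)
gives byte-identical output, and the generator restores the caller's RNG
state.

What the generator does *not* emulate: arterial waveforms or any
physiological (Windkessel) mechanism, the reversed central-to-radial
pressure gradient after bypass (site differences are parameters, not
mechanisms), informative missingness (catheter failures must be imposed by
deleting records), and non-Gaussian error tails. Passing parameter-recovery
tests therefore shows the *statistics* are computed correctly under a known
model — not that any real device behaves like the model.

## Validation design and problem sizes

The test suite checks each statistic against an independent oracle: longhand
sums-of-squares for the Bland-Altman components (exhaustively over all
designs up to 5 subjects × 4 pairs), closed-form trigonometry for the polar
transform, hand enumeration for the four-quadrant rules, and parameter
recovery on simulated studies — bias recovery and the closed-form PE
prediction over 100 replicates of 500 subjects, a known 25% sign-discordance
rate over 10,000 deltas, and the responder fraction over 4,000 subjects.
These sizes give Monte-Carlo standard errors comfortably inside the asserted
tolerances while keeping the whole suite under a minute.

One design subtlety the validation surfaced: a drift-induced sign flip
implies $|\Delta_{ref}|+|\Delta_{test}| \approx \delta$, so under the
mean-rule zone such pairs are excluded whenever the per-step drift is below
twice the zone — the with-exclusion concordance is structurally insensitive
to moderate drift. The drift-reset property (post-calibration trending beats
pre-calibration) is therefore asserted on the zone-free concordance, with a
drift (1.0 L/min/step) large against the within-subject CO-change SD
(≈ 0.7 L/min) so the mechanism is identifiable.

## Known limitations

* No confidence intervals on the limits of agreement, and no
  regression-based comparisons (Passing-Bablok, Deming) — deliberate scope
  bounds, natural extension points.
* The angular bias uses the arithmetic, not circular, mean.
* The Fisher comparison ignores the shared reference arm (above).
* Responder classification near the 10% boundary is sensitive to SV noise;
  with only ~22–25 subjects per study, agreement counts have wide sampling
  variation — the generator makes this visible.
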