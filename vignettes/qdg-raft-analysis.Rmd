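---
title: "Quantifying Parkinsonian motor signs from repetitive alternating finger tapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Parkinsonian motor signs from repetitive alternating finger tapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdgraft)
```

## The measurement

Quantitative digitography (QDG) instruments two adjacent, tensioned levers
that record the displacement (mm) and timing of finger presses. In the
repetitive alternating finger tapping (RAFT) task the subject presses and
releases the levers with the index and middle finger in alternation, as fast,
fully and regularly as possible, for 30 seconds per hand. The displacement
traces carry all the cardinal motor signs of Parkinson's disease:

* **bradykinesia** — fewer taps per minute, smaller press amplitude, slower
  press speed, and progressive amplitude decrement ("sequence effect",
  visible as press-amplitude variability);
* **rigidity** — slower key release (release slope);
* **arrhythmicity** — irregular cycle timing (CV of the inter-strike
  interval), a correlate of gait impairment;
* **tremor** — runs of rapid, low-amplitude involuntary strikes.

`qdgraft` turns one such trace into a per-hand metric panel and two composite
scores: a **Mobility Score** (0–100, voluntary movement only) and a
**Tremor Severity Score** (unbounded, involuntary movement only), each
referenced to an age-adjusted healthy-control distribution.

## Strike detection

A *strike* is one press/release cycle with four phase boundaries: press
onset, press bottom, release onset, release end. Dwell is the bottom phase
(`release onset − press bottom`).

Detection proceeds per lever:

1. **Gating.** The signal is smoothed with a centered moving average
   (`smoothing_window_s`, default 0.02 s, rounded to an odd sample count) and
   gated by hysteresis: a press activates when the smoothed displacement
   exceeds `press_onset_threshold_mm` (0.3 mm) and stays active until it
   falls below threshold − `hysteresis_mm` (0.15 mm). Hysteresis prevents
   chatter from re-triggering on noise near the threshold.
2. **Boundary refinement.** The gate crossings sit well above the resting
   position, so onset and release end are extended outward to the take-off
   and landing samples. The refinement is noise-adaptive: the noise level is
   estimated from the smoothing residual (robust MAD estimate) and, when it
   is negligible, the raw series is walked to the exact last/first resting
   sample; under real noise the smoothed series is walked to a resting band
   whose cut is derived from robust resting statistics (median + 3.5 robust
   SDs of the below-threshold samples), which also accommodates the
   clipped-at-zero noise floor of a real device.
3. **Bottom phase.** The press bottom is the first sample, inside the
   maximum-displacement approach (samples above `approach_fraction` = 0.9 of
   the cycle peak), where the lever is stationary: velocity magnitude below
   `bottom_velocity_epsilon_mm_s` (2 mm/s). Velocity is the raw central
   difference, whose first stationary sample lags the plateau start by one
   sample; the boundary is corrected for that group delay, making noise-free
   recovery exact. Release onset is the symmetric last stationary sample.
   Under real noise single-sample velocities are noise-dominated (at 100 Hz,
   0.1 mm of noise is ~7 mm/s of velocity noise), so the stationary phase is
   instead taken as the samples statistically indistinguishable from the
   plateau level (within 3 smoothed-noise SDs plus 1.5% of the level) — the
   same criterion in estimator form.
4. **Bookkeeping.** Cycles shorter than `min_cycle_duration_s` (0.05 s) are
   discarded; incomplete cycles at either trace boundary are dropped (they
   would bias duration metrics), where "begins mid-press" is decided by
   whether the signal ever rests before the first activation. Ties (a
   plateau exactly at a threshold) resolve to the earliest sample. Press
   amplitude is the mean raw displacement over the bottom phase above the
   robust resting level — averaging over the plateau rather than taking the
   single maximum removes the positive bias a noisy maximum would add.

Detected boundary timing is exact (0–1 samples) on noise-free signals. Under
measurement noise it is noise-limited: at 0.05–0.1 mm noise SD roughly 95% of
boundaries land within 2 samples, and individual boundaries can slip a few
samples where the pulse tail changes by less than one noise SD per sample. No
estimator can do materially better there, because those samples are
statistically indistinguishable from rest.

## Kinematic metrics

Per finger, averaged over **voluntary** strikes only (tremor strikes are
excluded everywhere; they have their own score):

| metric | definition |
|---|---|
| press amplitude (mm) | mean bottom-phase displacement |
| press amplitude CV | sample SD / mean (the sequence-effect proxy) |
| ISI (s) | press-onset to press-onset of the *same* finger |
| ISI CV | sample SD / mean of those intervals ("arrhythmicity" = 100 × ISI CV) |
| press speed (mm/s) | press amplitude / press duration, per strike, averaged |
| release slope (mm/s) | release amplitude / release duration ("release speed") |
| dwell time (s) | bottom-phase duration |

Hand-level values are the unweighted mean of the two finger values; a finger
with fewer than two voluntary strikes yields absent metrics (CVs need at
least two values), and absence propagates to the hand. Two metrics are
defined at the hand level directly: rest tremor percent (100 × summed
tremor-strike durations / trace duration) and taps per minute
(60 × voluntary strike count / duration).

Conventions fixed here, where more than one reading was defensible:

* **ISI is per-finger onset-to-onset** — the time to complete one full cycle
  of that finger's movement. The alternative (half-interval between
  alternating fingers) conflates the two fingers' rhythms and is rejected.
* **CVs use the sample (n−1) SD.**
* **Release slope and release speed are the same quantity** (release
  amplitude over release duration); both names appear in dashboard practice.
* **Dwell time is computed and reported but never scored**: it is not one of
  the six Mobility metrics, and its clinical direction is ambiguous.

## Tremor classification

Tremor is identified per strike. The classifier is pluggable
(`tremor_classifier(kind = "external", predict = ...)` accepts any function
of the strike table and trace) so that a trained model — e.g. a validated
gradient-boosted classifier — can be dropped in. The packaged default is a
transparent heuristic, a stand-in rather than a reproduction of any trained
model: a strike is tremor iff

* its press amplitude is below `amplitude_fraction_threshold` (0.45) of the
  hand's median voluntary amplitude, **and**
* its local same-lever cycle rate (reciprocal of the smaller adjacent
  onset gap) lies in `cycle_rate_band_hz` (3–8 Hz, the parkinsonian
  rest-tremor band).

The median voluntary amplitude is iterated to a fixed point so abundant
tremor strikes cannot drag the reference median down. The default does not
distinguish rest from action tremor; all flagged strikes feed the tremor
percent. Note the amplitude condition means tremor at more than ~45% of
voluntary amplitude needs either a raised threshold or an external
classifier.

## Normative reference and scores

`build_reference()` consumes a healthy-control metric table (one row per
session, with subject id and age).

* **Age adjustment.** A linear mixed-effects model (`value ~ age +
  (1 | subject)`, REML via lme4; plain OLS when each subject contributes one
  session or the random-intercept fit is singular) estimates an age slope
  for the three metrics where age has a strong effect: press amplitude CV,
  release slope, press speed. Values are mapped to the reference age of 60
  years as `value − slope × (age − 60)`. The subtraction direction is the
  only one under which controls of all ages share one distribution — each
  subject is moved to their expected value at age 60. The other metrics are
  left unadjusted.
* **Distributions and thresholds.** Adjusted control values give per-metric
  means and SDs, plus a normal/abnormal threshold at the 25th percentile for
  metrics where lower is worse (press amplitude, press speed, release slope,
  taps/min, Mobility Score) and the 75th where higher is worse (ISI, ISI CV,
  press amplitude CV). Percentiles use linear interpolation between order
  statistics (`quantile type 7`), one of several accepted conventions, fixed
  and documented here. A value exactly at its threshold is normal.
* **Directional z.** `z = (adjusted − mean)/SD`, sign-flipped for
  lower-is-worse metrics so deficits are positive, floored at 0 so
  above-average performance in one metric cannot offset deficits in another.
* **Press-amplitude transform.** Control amplitudes cluster tightly
  (calibration 8.67 ± 0.12 mm), so a low-amplitude trial produces an extreme
  z that would dominate the composite. Above z = 10 (amplitude below
  ~7.5 mm under that calibration) the z is compressed by the power law
  `3.2 · z^0.495` — which equals 10.004 at z = 10, i.e. the transition is
  continuous — and explicitly capped at 20, since the power law alone
  exceeds 20 for z beyond ~40.
* **Mobility Score** = `100 − 14 × mean(z)` over the six metrics (ISI,
  ISI CV, press speed, press amplitude [transformed], press amplitude CV,
  release slope), clamped to [0, 100]. The clamp at 0 makes the stated range
  explicit; 100 means every metric at or better than the control mean.
* **Tremor Severity** = `%RT + 100 × mean((Amp_i / AmpMax)²)` over tremor
  strikes, where AmpMax is the device ceiling. Below 10% tremor the
  amplitude component is suppressed by `4^(0.05·pct − 1)` (0.25 at 0%,
  0.5 at 10%) so a handful of large tremor strikes cannot inflate the score;
  how the suppression enters is configurable (`multiplicative` — the
  default, scaling the amplitude component; `replace`; or `none`) because
  the combination rule is underdetermined, and the multiplicative default
  leaves a factor-of-two step at pct = 10 that is documented rather than
  smoothed. The score has no upper cap. With no tremor strikes it equals
  the tremor percent.
* The control cohort's own Mobility Scores are summarized into the
  reference too, so longitudinal dashboards can flag an abnormal Mobility
  Score (below the control 25th percentile) like any other metric.

Two device constants are configuration with documented defaults, because
they are properties of the hardware rather than the scoring model: the
sampling rate (simulator default 100 Hz; all algorithms are written
rate-independently) and the displacement ceiling AmpMax (default 12.5 mm,
back-computed from published worked score examples; healthy full-amplitude
presses average 8.67 mm, so the ceiling plausibly exceeds that by some
margin). Both are overridable.

## The synthetic trace generator

Every stage is testable without patient data through `simulate_trace()`:

* **Pulse shape.** Raised-cosine press and release segments around a flat
  dwell — smooth, differentiable, and with unambiguous phase boundaries for
  ground truth. All boundaries are snapped to the sample grid, so noise-free
  traces have exactly sample-aligned ground truth (this is what makes the
  "exact recovery" tests sharp rather than half-sample-quantized).
* **Timing.** Per-finger cycles with log-normal ISI jitter at a target CV;
  the middle finger lags the index by half a cycle (alternation). A 0.05 s
  rest margin is kept before the trace end so every generated cycle is
  complete.
* **Sequence effect** as multiplicative per-tap amplitude decay, plus
  log-normal-like per-strike amplitude jitter.
* **Tremor** as bursts of rapid (default 5 Hz) low-amplitude strikes on one
  lever that suspend voluntary tapping for their duration — matching the
  per-strike classification contract — rather than an additive sinusoid.
  Burst count is sized so tremor occupies the requested percent of the
  trace (achieved within ~1.5 points for targets ≥ 3%).
* **Noise** as additive Gaussian measurement noise clipped to the device
  range `[0, AmpMax]`.

`simulate_control_cohort()` draws per-subject parameters and runs every
trace through the full pipeline, so its output table contains *extracted*,
not nominal, metrics. Only the press-amplitude calibration
(8.67 ± 0.12 mm between subjects) follows published healthy-control
statistics; all other distribution choices — 2 Hz per finger, 0.1 s press
and release, 5% timing jitter, and mild synthetic aging effects (0.4%/year
slowing of press/release speed, 0.1%/year cycle lengthening, 0.8%/year
amplitude-CV growth past age 60) — are the package's own choices of what a
plausible healthy cohort looks like, labeled synthetic. The packaged
reference (`inst/extdata/reference_synthetic.json`, loaded by
`default_reference()`) is built from 42 such subjects (seed 20240601),
mirroring a typical control-cohort size; `simulate_control_metrics()`
additionally draws metric tables directly from the same distributions for
large-n distributional checks (e.g. threshold flag rates at n = 10,000)
where simulating full traces would add nothing.

### What passing tests do and do not show

The simulator reproduces the *phenomenology* the metrics target (amplitude
decrement, slowing, arrhythmicity, burst tremor) with idealized pulse
shapes, stationary parameters, white measurement noise, and tremor that
politely alternates with voluntary tapping. Real traces have correlated
sensor noise, partial releases, co-occurring tremor and voluntary movement,
hesitations and hand repositioning. Green tests therefore certify the
*algorithmic contract* — detection recovers what the generator wrote,
metrics equal their definitions, scores follow their formulas — not
clinical validity on real recordings, which requires the original device
and cohorts.

## Reporting

`analyze_session()` composes the stages statelessly (the suite asserts it
equals the independently chained calls). Sessions with fewer than two
voluntary strikes on either finger return an `insufficient_performance`
status with no scores — scoring a near-empty trace would be noise.
`compliance_ratio()` counts distinct subject-days with a completed test over
possible days in a calendar month (days elapsed for an in-progress month)
and checks the 16-of-30-days remote-monitoring criterion over any 30-day
window. `timeseries_report()` produces per-day metric series with
normal/abnormal flags and medication adherence deltas
(actual − prescribed, minutes). All reports are pure functions of their
inputs and serialize to schema-versioned JSON.

## Problem sizes and numerical choices

The test suite and acceptance script run on 6–30 s traces at 100 Hz,
42-subject end-to-end cohorts, and 10,000-row parametric cohorts — sizes
chosen so the full pipeline, including the mixed-model fits, runs end to end
in seconds while keeping Monte-Carlo bands (e.g. the 24–26% flag-rate check)
tight. Fixed seeds make every stochastic check reproducible; the simulator
uses a private RNG stream and restores the caller's. Known limitations
beyond those above: the heuristic tremor classifier is amplitude-gated (high
amplitude tremor requires an external classifier), boundary timing under
heavy noise is noise-limited, and the age model assumes a linear age effect
over the cohort's age range.
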