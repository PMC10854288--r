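# qdgraft

Kinematic analysis of repetitive alternating finger tapping (RAFT) for the
motor signs of Parkinson's disease.

Quantitative digitography (QDG) records the displacement (mm) and timing of
finger presses on two adjacent tensioned levers. In the RAFT task a subject
alternates index- and middle-finger presses as fast, fully and regularly as
possible for 30 s per hand. `qdgraft` is for researchers and tool builders in
digital movement biomarkers who need the full analysis chain from raw
displacement trace to clinically interpretable scores:

* **strike detection** — segments each lever's signal into press/release
  cycles with four phase boundaries (press onset, press bottom, release
  onset, release end);
* **kinematic metrics** — press amplitude and its CV (sequence effect), ISI
  and its CV (arrhythmicity), press speed, release slope (rigidity proxy),
  dwell time, rest tremor %, taps/min; per finger, then averaged per hand;
* **per-strike tremor classification** — a pluggable interface with a
  transparent amplitude + cycle-rate heuristic default;
* **normative scoring** — age-adjusted z-scores against a healthy-control
  reference, with quartile-based normal/abnormal flags;
* **a calibrated trace simulator** with exact ground-truth annotations, so
  every stage is testable without patient data;
* **remote-monitoring reports** — testing compliance and medication
  adherence.

## The scores

Each of the six Mobility metrics m (ISI, ISI CV, press speed, press
amplitude, press amplitude CV, release speed) is age-adjusted
(`x' = x − slope_m · (age − 60)`, slopes from a random-intercept mixed model
on controls) and standardized against the control distribution,
`z = (x' − μ_m)/σ_m`. Signs are flipped where lower is worse, and
above-average performance is floored at zero. Because healthy press
amplitudes cluster tightly, press-amplitude z-scores beyond 10 are
compressed by a power law, continuous at the transition and capped:

    z_PA ← min(3.2 · z_PA^0.495, 20)   for z_PA > 10

The composite scores are

    Mobility Score   = 100 − 14 · mean(z_1..z_6)            (clamped to [0, 100])
    Tremor Severity  = %RT + 100 · mean((Amp_i / AmpMax)²)  (over tremor strikes)

where %RT is the percent of the trace occupied by tremor strikes and AmpMax
the device ceiling; below 10% tremor the amplitude term is suppressed by
`4^(0.05·%RT − 1)`. A metric is flagged abnormal beyond the control 25th
(lower-worse) or 75th (higher-worse) percentile.

## Worked example

Simulate a mildly bradykinetic, tremulous session and score it against the
packaged (synthetic, simulator-calibrated) normative reference:

```r
library(qdgraft)

ref <- default_reference()
sim <- simulate_trace(
  simulation_params(base_amplitude_mm = 8.3, isi_mean_s = 0.56,
                    press_duration_s = 0.115, release_duration_s = 0.115,
                    dwell_s = 0.07, amplitude_decay_per_tap = 0.002,
                    isi_cv = 0.07, tremor_pct_target = 9),
  seed = 7,
  meta = list(subject_id = "PD01", age_years = 67,
              therapy_state = "off medication"))
panel <- analyze_session(sim$trace, ref)
print(panel)
```

```
QDG session (R hand): Mobility 55.5, Tremor Severity 10.4
  press_amplitude_mm       7.896  z   5.47  [abnormal]
  press_amplitude_cv       0.048  z   2.43  [abnormal]
  isi_s                    0.564  z   3.30  [abnormal]
  isi_cv                   0.062  z   0.95  [abnormal]
  press_speed_mm_s        68.502  z   3.55  [abnormal]
  release_slope_mm_s      68.423  z   3.37  [abnormal]
  taps_per_minute        172.000  z   7.47  [abnormal]
```

Reading: presses average 7.9 mm (vs the 8.65 mm control mean — z 5.5 after
the directional flip), tapping runs at 172 taps/min with a 0.56 s per-finger
cycle, and every metric sits beyond its control quartile, giving a mid-range
Mobility Score of 55.5. Tremor occupies 9.1% of the trace at a mean 2.1 mm
amplitude; with tremor under 10% the amplitude term is suppressed, so Tremor
Severity is 10.4. The panel's z-scores and flags are what a monitoring
dashboard would color; `panel$dashboard` exposes them as a flat named
record, and `write_session_report()` serializes the session to versioned
JSON.

A command-line wrapper covers the same flow
(`exec/qdg simulate|analyze|build-reference|report`).

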