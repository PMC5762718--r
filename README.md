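# turnwatch

Turn-protocol compliance analytics for continual patient position
monitoring.

Hospitalised patients at risk of pressure injury are placed on turning
protocols — a position change at least every 2 hours is the common nursing
standard. Wearable accelerometer systems sample each patient's transverse
roll angle every 10 seconds and score protocol compliance continuously,
crediting self-turns as well as caregiver-assisted turns. `turnwatch` is for
analysts evaluating such monitoring deployments: it implements the scoring
engine, the compliance statistics, the pre/post statistical comparison, and
a seeded simulator that generates realistic position-trace cohorts to
exercise the whole chain.

## What it computes

**Engine.** Roll angles classify into regions by a turn-angle threshold
*θ* = 20°: right if angle > +θ, left if angle < −θ, back on [−θ, +θ]. A
position change is a *qualifying turn* when the vacated region stays
continuously offloaded for the decompression time *D* = 15 min; otherwise
the region's sustained-time clock resumes across the interruption. With
turn period *T* = 120 min and grace *G* = 15 min, the patient is
non-compliant whenever sustained time *s* on the current region satisfies
*s* ≥ *T* + *G* = 135 min. The bedside display ignores the grace period:
green for *s* < 105 min, yellow for 105 ≤ *s* ≤ 120, red for *s* > 120.
Documented exemption intervals override the state so missed turns with a
valid reason never penalise compliance.

**Metrics.** Per-patient compliance (compliant/monitored time), pooled
phase compliance (time-weighted, not a mean of fractions), adherence per
100-patient-hour block (fraction of hours with zero non-compliant time),
and hour-of-day compliance over the 24-hour clock.

**Statistics.** The sample-size formula *n* = *z*²·sd²/*e*², a two-sample
t test (Student or Welch) on per-patient compliance fractions, and a 2×2
chi-square test of independence.

## Worked example

```r
library(turnwatch)
report <- run_pipeline(run_config(seed = 20130501))
print(report)
#> <turnwatch_report>
#>   baseline  n= 75     4630 h  pooled compliance 65.2%
#>   post      n= 63     5206 h  pooled compliance 96.4%
#>   primary t test: t = 18.792, df = 136.0, p = 1.27e-39
```

This simulates a 75-patient baseline cohort whose caregiver-turn miss
probability was calibrated to a pooled compliance near 64%, and a 63-patient
post-intervention cohort at the simulator's scheduled-turning ceiling
(≈ 96%), scores every trace with the engine, and compares per-patient
compliance fractions: here the phases separate at t = 18.8 (p ≈ 10⁻³⁹).
Supporting results in the same report: sex chi-square p = 0.298 (cohorts
balanced), Braden t test p = 0.059, mean 100-h block adherence 0.52
(baseline) vs 0.93 (post), and the 63-patient enrolment target from
`sample_size(1.96, 0.5, 0.123)`.

Lower-level pieces compose directly:

```r
tr <- patient_trace(seq(0, 200 * 60 - 10, 10), angle_deg = 0)  # 200 min supine
tl <- compliance_timeline(tr)
state_times(tl) / 60
#>    COMPLIANT NONCOMPLIANT       EXEMPT
#>    134.83333     65.16667      0.00000
```

Non-compliance begins with the reading in which minute 135 is reached —
the 120-min turn period plus the 15-min grace.

A thin command-line front end with `simulate`, `score`, `summarize`,
`compare` and `run-all` subcommands lives at `inst/cli/turnwatch.R`; all
outputs are CSV/JSON with a config-hash provenance header.

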