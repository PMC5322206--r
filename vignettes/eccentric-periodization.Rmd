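---
title: "Periodized isokinetic eccentric training: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Periodized isokinetic eccentric training: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccperiod)
```

## The problem

Eccentric muscle actions — active lengthening under load — allow high
torque output at low metabolic cost, which makes them attractive for
strengthening older adults and clinical populations. They also carry a
real risk of muscle damage in people naive to the stimulus, so the
exercise dose has to be introduced gradually and progressed by rule
rather than by feel. On an isokinetic dynamometer in reactive eccentric
mode the machine drives the joint at a set angular velocity while the
participant resists; resistance *accommodates*, so a missed workload
never stops the movement and has to be detected from the torque-time
curve itself.

This package implements a complete periodized prescription method for
reciprocal eccentric knee extension/flexion training: workload
estimation, visual torque-target bands, an intra-session fatigue
classifier driving a ±5% workload progression rule, macrocycle plan
construction and scheduling, progression analytics on the session
ledger, and a virtual-participant simulator that closes the loop for
testing.

## The prescription model

**Initial workload.** Eccentric strength in untrained individuals is
estimated from measured concentric strength as

τ_ecc = 1.35 · τ_con

with the concentric peak itself taken as the mean of the three highest
peak torques from a five-repetition maximal test
(`peak_torque_five_rep()`). The 1.35 cofactor is deliberately
conservative (eccentric strength typically runs 20–100% above
concentric) and is configurable in `estimate_ecc_peak_torque()`.

**Compliance bands.** Each session displays three torque lines
(`make_bands()`): line A at the designated workload, line B at 90% of
it (the acceptable lower bound), and line C at 75% (the fatigue
criterion). `classify_session()` grades a session from its
per-repetition peak torques:

* *excessive* — at least 3 consecutive (cued) peaks strictly below
  line C in any set;
* *moderate* — otherwise any peak strictly below line B;
* *compliant* — all peaks at or above line B.

`adjust_workload()` then sets the next session's target: ×1.05 after a
compliant session, ×1.00 after moderate fatigue, ×0.95 after excessive
fatigue. Two readings of the rule are provided: the default compounds
multiplicatively on the current target; an additive mode steps by 5
percentage points of the estimated eccentric peak. The published group
trajectory (70, 75, 85, … % across the progression phase) is group-mean
data and does not discriminate between the two, so the choice is
surfaced in configuration rather than hidden.

**Safety rails.** The dynamometer's torque limit sits at most 50 N m
above the target (`workload_target()`), the reactive mode engages only
above 10% of that limit (`engagement_threshold()`), and
`stoppage_check()` stops exercise outright above a VAS pain score of 8,
flagging large rises over baseline (default +4 while still ≤ 8) for
clinician review. The flag delta is our own policy; the underlying
criterion names only the >8 stoppage and the concern about large
proportional increases over a low baseline.

## The macrocycle

`build_initial_macrocycle()` encodes the 12-week/24-session plan: one
familiarization week at 45°/s and a 40–50% target, two acclimatization
weeks at 60°/s (50%, 60%), then a progression phase from microcycle 4
(fixed 70%) with per-session ±5% adjustment from microcycle 5. Volume
rises from 3×10 to 4×10 repetitions at microcycle 6, velocity
transitions from 60 to 90°/s via mixed 3+1 / 2+2 / 1+3 set splits
across microcycles 7–9, and the final three weeks run entirely at
90°/s. Published tables print several of these cells as "3 × 1",
"2 × 1", "1 × 1"; we read them as typographic truncations of "× 10",
consistent with the narrative set/repetition scheme and the
neighbouring "4 × 10" cells.

The familiarization week's "40–50%" target is resolved as 40% for
session 1 and 50% for session 2 (the attained-workload row shows 40%);
this is configurable. The ±5% chain seeds from the attained 70% of
microcycle 4 and every training session may trigger an adjustment
("following each exercise session"), not once per microcycle.

`recommend_recovery()` revises a plan by inserting active-recovery
microcycles: the progression phase is partitioned into blocks of four
consecutive microcycles, with a shorter remainder absorbed into the
final block, and a recovery week follows each block. Applied to the
initial plan (9 progression microcycles) this gives blocks 4–7 and 8–12
and hence recovery at positions 8 and 14 — the revised 14-microcycle
macrocycle that `build_revised_macrocycle()` constructs directly. We
chose the remainder-absorbing partition because it is the only reading
of "recovery after every four loading microcycles" that reproduces the
published revised topology; a strict counter-reset rule would place the
second recovery at position 13 and strand the final week. Active
recovery content is unspecified in the source material ("–"): the
default policy schedules two light sessions (2×10 at 60°/s, half the
current target, outside the adjustment chain); full rest is available
via `recovery_policy = "rest"`.

`schedule_sessions()` maps microcycles 1:1 onto calendar weeks with two
sessions at evenly spaced day offsets (days 1 and 4), which guarantees
the required full rest day between sessions for every start date.

## Progression analytics

Session total work (J) is the integral of torque over angular
displacement, `total_work()`, computed by the trapezoidal rule on the
sampled torque-angle path; extension and flexion phases both accumulate
positive work under the package's sign conventions (0° = full
extension, extension torque positive). Note that dynamometer vendors
may integrate over time rather than angle internally; we define work as
∫τ dθ. Mean power is work over active movement time, so at a fixed
torque profile it scales exactly with the velocity ratio.

`index_total_work()` expresses each progression-phase session as a
percentage of the work attained when the 5% increments began.
`rolling_slopes()` fits ordinary least squares lines over sliding
4-session windows (two microcycles) advanced by 2 sessions (one
microcycle), the serial overlapping analysis. The regressor is the
within-window session ordinal, so slopes are in indexed-percent per
session; published absolute slope values depend on unpublished raw
series and are not reproducible, which is why the detectors are
validated on synthetic data only. `detect_events()` labels a maximal
run of ≥ 2 consecutive windows with slope in [0, 10) as a training
plateau and any negative-slope window as a capacity decline; the
threshold 10 follows the "consecutive slope values < 10" criterion and
is configurable.

`velocity_condition_comparison()` compares paired 60 vs 90°/s
observations at the same torque target, indexing each pair to its own
60°/s value and averaging the per-pair percent changes (the published
radar-graph summary indexes participants to themselves). The percent
change of the group means is also reported: on the published group
means it differs (+32.7% for power) from the per-participant summary
(~+25%), which is why both are exposed.

## The virtual participant

`participant_model()` + `run_closed_loop()` simulate the whole
macrocycle so that the decision engine, scheduler and analytics can be
tested end to end without clinical data. The generative model is the
simplest one consistent with the method's assumptions:

* **Peak tracking.** Each repetition's peak torque tracks
  min(target, current capacity), times a mild velocity gain (+7% per
  30°/s above 60, the observed torque difference between velocity
  conditions), times multiplicative lognormal noise.
* **Motor learning.** Variability decays exponentially across sessions:
  CV(s) = floor + (cv0 − floor)·2^(−(s−1)/half-life), with cv0 = 0.68
  and floor = 0.12 — the repetition-interval CVs observed at the start
  and end of familiarization. Only the two endpoints are documented, so
  the exponential form and the half-life (default 0.2 sessions, which
  reproduces the session-1→2 drop) are modeling choices. Peak-to-peak
  intervals are gamma-distributed with this CV around a 5.5 s nominal
  interval; draws shorter than a full reciprocal cycle are realized as
  partial-range repetitions (erratic early reps genuinely are partial,
  which is how a mean interval of ~3.3 s can undercut the ~4 s motion
  time of a full cycle) and longer draws become pre-repetition pauses.
  Peak *amplitude* is far better controlled than timing — the
  participant steers it against a visual target — so amplitude tracking
  CV is a fixed fraction (default 0.25) of the interval CV; without
  this separation nearly every simulated session would fail the 10%
  band on a single-repetition dip, which contradicts the intended
  behaviour of the band system.
* **Fatigue and adaptation.** Capacity falls by a fixed fraction per
  joule of set work and part of the intra-session deficit is restored
  during each 60 s inter-set rest; compliant sessions raise capacity by
  the adaptation rate. No per-session raw data exist to calibrate
  these rates, so the defaults (2×10⁻⁵ /J, 80% inter-set recovery, +1%
  per compliant session, true ceiling 1.6× concentric) are illustrative
  values chosen to produce the qualitative trajectory the method
  expects — early compliant growth, then a capacity-limited plateau or
  decline late in the macrocycle.
* **Pain.** VAS follows a bounded random walk from a baseline of
  2.9/10; stoppage events are rare at the defaults and truncate the
  session when they occur.

All randomness flows from the single seed given to
`run_closed_loop()`; identical seeds give identical ledgers.

What the simulator does *not* attempt: Hill-type muscle mechanics,
delayed-onset soreness carryover between sessions, inter-participant
heterogeneity, or any physiology beyond what the decision algorithm
consumes. Passing closed-loop tests therefore show that the method's
logic behaves correctly under its own assumptions, not that those
assumptions describe any particular patient.

## Numerical choices and degenerate inputs

* Repetition segmentation is threshold-crossing at 10% of the
  series-wide maximum on a 0.1 s moving-average copy of the torque
  channel, with same-direction runs rejoined across sub-threshold gaps
  shorter than 0.15 s, segments shorter than 0.1 s discarded as
  impulsive noise, and peaks closer than 0.5 s merged. The source
  protocol never specifies a segmentation algorithm; every constant is
  a tunable argument.
* Interval statistics use the sample (n−1) SD, which reproduces the
  published CVs within rounding (67.9→68%, 12.4→12%); CV is reported at
  full precision and rounded to whole percent only for display. Both
  intra-session pooling modes are available: the lowest-variability set
  (the published choice) or all within-set intervals pooled.
* Band boundaries are strict for the worse class: a peak exactly on
  line B is compliant, exactly on line C is moderate.
* Adjusted targets are rounded to 0.1 N m; the percent-space chain kept
  by the plan state is not rounded.
* The gravity model is a single-point calibration at terminal extension
  scaled by the cosine of the angular offset; the measurement posture
  is protocol, the scaling law is ours and is isolated in
  `gravity_correct()`. Calibrations drifting >10% from baseline warn.
* Degenerate inputs fail with classed conditions
  (`ep_insufficient_data`, `ep_invalid_input`, `ep_plan_exhausted`,
  `ep_parse_error`, …) rather than silent NA: fewer than two
  repetitions for interval statistics, fewer than two samples for work,
  zero baseline work for indexing, advancing past the plan's end, and
  malformed CSVs all raise identifiable errors.

## Problem sizes used in the test suite

Unit and property tests run on synthetic series of tens of repetitions
and full 24–28-session closed loops at the dynamometer's 100 Hz (50 Hz
where only interval statistics matter); the variability half-life
recovery check uses eight session ordinals with three replicate bouts
of 4×30 repetitions each. These sizes were chosen so the entire suite
exercises every code path in well under a minute of simulation time per
scenario.

## Known limitations

* Plateau/decline positions from the published cohort are not
  reproducible without its raw per-participant series; the detectors
  are validated against closed-form oracles and simulated data.
* The slope units (indexed-% per session) are this package's
  convention; published slope magnitudes may be on a different x-scale.
* The engagement parenthetical in the source ("~22.5–44.5 N m above the
  targeted workload") conflicts grammatically with "10% of the assigned
  torque limit"; we implement 10%-of-limit.
* The simulator's fatigue/adaptation defaults are illustrative, not
  calibrated.
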