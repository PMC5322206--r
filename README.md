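# eccperiod

Periodized **isokinetic eccentric strength training**: workload
prescription, progression decisions, macrocycle planning, progression
analytics, and closed-loop simulation.

Eccentric (lengthening) muscle actions let older adults and clinical
populations train at high torque with low metabolic cost, but the dose
must be introduced gradually and progressed by explicit rule. On a
dynamometer in reactive eccentric mode the resistance *accommodates* —
a missed workload never stops the movement — so failure has to be read
off the torque-time curve. `eccperiod` is aimed at rehabilitation
researchers and exercise scientists who want that whole decision
pipeline as testable code.

## The method

* **Initial workload** from concentric strength testing:
  τ<sub>ecc</sub> = 1.35 · τ<sub>con</sub>, with τ<sub>con</sub> the
  mean of the three highest peaks of a five-repetition maximal test.
* **Visual torque bands** per session: line A = target, line B = 0.90
  · target (tolerance bound), line C = 0.75 · target (fatigue
  criterion).
* **Fatigue classification** per session from repetition peak torques:
  *excessive* if ≥ 3 consecutive peaks fall below line C, *moderate* if
  any peak falls below line B, else *compliant*.
* **Workload adjustment** for the next session: ×1.05 (compliant),
  ×1.00 (moderate), ×0.95 (excessive).
* **Macrocycle**: 12 weekly microcycles × 2 sessions — familiarization
  (45°/s, 40–50%), acclimatization (60°/s, 50–60%), progression from
  70% with the ±5% chain, volume rising 3×10 → 4×10 and velocity
  60 → 90°/s; a revised 14-microcycle variant inserts active-recovery
  weeks after every loading block (positions 8 and 14).
* **Progression analytics**: session total work W = ∫ τ dθ indexed to
  the start of the increments; OLS slopes over rolling 4-session
  windows; slopes in [0, 10) flag plateaus, negative slopes flag
  capacity declines; recovery placement follows the loading blocks.
* **Safety**: torque limit ≤ 50 N m above target, 10%-of-limit
  engagement threshold, exercise stoppage above VAS 8.
* **Simulator**: a virtual participant (capacity, work-proportional
  fatigue, inter-set recovery, session-over-session adaptation, motor
  learning as a CV decay 68% → 12%, VAS random walk) closes the loop:
  prescribe → simulate → classify → adjust.

## Worked example

```r
library(eccperiod)

# strength testing: five-repetition concentric test
con <- peak_torque_five_rep(c(142, 151, 148, 139, 145))
ecc <- estimate_ecc_peak_torque(con)   # 148 * 1.35 = 199.8 N m

# session at 70% of the eccentric estimate
bands <- make_bands(0.7 * ecc)         # lines A/B/C = 139.9 / 125.9 / 104.9
peaks <- c(142, 140, 99, 97, 96, 138, 141, 139, 140, 142)
cls <- classify_session(list(peaks), bands)
adjust_workload(0.7 * ecc, cls)
#> <adjustment_decision> excessive: x0.95, 139.9 -> 132.9 N m
```

Three consecutive peaks (99, 97, 96) fell more than 25% below the
target, so the session classifies *excessive* and the next session's
workload drops 5% to 132.9 N m.

A full simulated macrocycle and its analysis:

```r
sim <- run_closed_loop(participant_model(concentric_peak = con),
                       build_initial_macrocycle(), seed = 42)
sim
#> <ecc_simulation> initial plan, seed 42: 24 sessions
#>   fatigue classes: compliant 18, moderate 6
#>   progression targets: 70.0% -> 125.7% of estimated eccentric peak

summary(progression_analysis(sim$ledger))
#> indexed total work: start 100%, end 200% (increase 100%)
#> slopes: mean 5.7, SD 8.2, range -3.2 to 21.2
#> plateau spans: 0; decline windows: 3
```

The virtual participant rides the +5% chain while capacity allows
(targets 70% → 125.7% of the estimate), doubles its indexed total work,
and shows late negative-slope windows as the workload outgrows
capacity — the pattern the recovery-placement rule responds to:
`recommend_recovery(build_initial_macrocycle())` reproduces the revised
macrocycle with active-recovery weeks at positions 8 and 14.

A command-line interface wrapping the same functions lives at
`system.file("cli", "eccperiod.R", package = "eccperiod")` with
subcommands `plan`, `simulate`, `analyze`, `adjust`, `report`.

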