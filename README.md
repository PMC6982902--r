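# motionteach

Adaptive vibrotactile teaching of periodic human motions.

`motionteach` implements the machine-learning core of an automatic motor-
learning system: a learner wears MEMS inertial sensors (triaxial
accelerometer + orientation quaternion at 100 Hz) and a band of four
directional vibrotactile units; the system watches the motion in real time,
classifies it, and delivers corrective vibration cues *during* the movement
(concurrent feedback). The target applications are rehabilitation, sports
drills and machine-operation training, where periodic limb trajectories
(here, a butterfly-stroke hand drill: a closed x–z curve with a timed pause
at the top) must be taught without occupying the learner's eyes or ears.

Because no hardware or human subjects ship with an R package, a seeded
**virtual learner** generates sensor streams with the statistical structure
the system assumes — periodic closed trajectory, timed pause, per-period
amplitude/timing variability, orientation wobble, accelerometer noise of
0.4 mg/√Hz — so the entire loop is testable end to end.

## The method

**Preprocessing.** Each sensor reports acceleration `a` in its local frame
and a quaternion `q = (vx, vy, vz, k)` giving its rotation `A` relative to
the Earth frame. The chain per selected signal is

    a_iner = A⁻¹ a  →  a_motion = a_iner − (0, 0, g₀)  →  first-order IIR
    low-pass (o_k = (1−α) o_{k−1} + α f_k, α from the RC relation)  →
    cumulative integration to velocity and position with per-period mean
    removal (bounded drift).

**Pattern matching.** The system's distance between a one-period pattern
`P = (p¹…p^w)` and the trailing window of a signal `S = (s¹…s^m)` is

    g(P, S, a, b, c, d) = 1/n Σ_{k=0}^{n−1} (p^{wrap(round(b − a k))} · c + d − s^{m−k})²
    h(P, S) = min_{a,b,c,d} g

— mean-squared error under a time scale/shift `(a, b)` and value
scale/offset `(c, d)`, so similarity is invariant to linear transforms of
the signal. The minimum is found by a two-stage coarse-to-fine grid search;
normalizing both windows to the fixed band (−0.6, 0.6) shrinks the useful
`(c, d)` ranges and cuts the stage-1 scan from 225,000 candidate points
(cardinalities 30·20·15·25) to a few thousand. An exhaustive oracle
(`h_oracle`) cross-checks the two-stage minimizer in the tests.

**Classification (kNNModel).** A multi-dimensional signal is compared to a
labelled bank of multi-dimensional patterns via the arithmetic mean of
member `h` distances; the label of the largest subset among the `k` nearest
entries wins (ties: smaller mean distance, then bank order).

**Teaching.** The fitted shift `b` of *time patterns* yields the "time
point" τ — the pattern probe corresponding to the present instant
(aggregated over signals by a reliability-weighted circular mean). *Shape
patterns* aligned at τ give the motion-error vector `e`; per actuator,
`o = G A C e` projects the error onto the actuator plane and selects the
vibration unit by direction. Two algorithms are dispatched by the per-period
class decision: the regulator **Cα** fires the strongest-error actuator at a
period end, gated by a length threshold (`len` = 0.03 m), an activation
spacing (`elaps` = 2.5 s) and an outward-crossing test (radial error and
radial velocity both positive); the time-triggered **Cβ** fires a
teacher-chosen unit when τ crosses a configured probe, used against the
typical error of skipping the pause.

**Evaluation.** RMSE of position signals against phase-aligned shape
patterns gives the efficiency scores E1 (central 0.3–0.9 of the test
signal), E2 (30 s window starting at the longest all-Cα interval of the
class timeline) and E3 = E2_test − 0.25·E2_pre, compared across teaching
methods by Shapiro–Wilk, Levene and one-sided pooled-variance Student t
tests.

## Worked example

```r
library(motionteach)

## simulate a learner performing the correct motion (class Calpha)
cfg    <- learner_config(class_mode = "alpha", duration = 12, seed = 1)
stream <- synth_stream(make_trajectory(cfg), cfg)
S      <- select_signals(stream, default_selection(), period_w = 200)
S
#> <multi_signal: K = {1,2,3}, 1200 samples @ 100 Hz>

## build a two-class pattern bank (positions classify, acceleration synchronizes)
roles <- list("1" = c("class", "shape"), "2" = c("class", "shape"), "3" = "time")
cfg_b <- learner_config(class_mode = "beta", duration = 12, seed = 2)
S_b   <- select_signals(synth_stream(make_trajectory(cfg_b), cfg_b),
                        default_selection(), period_w = 200)
bank  <- pattern_bank(list(
  build_pattern_md(S,   roles = roles, label = "Calpha", w = 200),
  build_pattern_md(S_b, roles = roles, label = "Cbeta",  w = 200)))

## classify a new, unseen recording
cfg_new <- learner_config(class_mode = "alpha", duration = 6, seed = 99)
S_new   <- select_signals(synth_stream(make_trajectory(cfg_new), cfg_new),
                          default_selection(), period_w = 200)
classify_knn(bank, S_new, k = 2)
#> <class_decision: 'Calpha' (k = 2; cards: Calpha=1, Cbeta=1)>

## analyse the bundled per-participant efficiency scores
efficiency_analysis(load_efficiency_fixture(), sw_draws = 20000, seed = 1)
#> E1: <stat_report: t(16) = 1.848 (crit 1.746), one-sided p = 0.042>
#>   means 71.3 vs 94.6; sd 15.0 vs 34.6; Levene 3.61 (crit 4.49); S-W 0.89/0.92 (crit 0.83)
#> E2: <stat_report: t(16) = 1.911 (crit 1.746), one-sided p = 0.037>
#>   means 69.1 vs 95.9; sd 20.7 vs 36.6; Levene 3.01 (crit 4.49); S-W 0.95/0.93 (crit 0.83)
#> E3: <stat_report: t(16) = 1.933 (crit 1.746), one-sided p = 0.036>
#>   means 44.2 vs 70.2; sd 25.7 vs 31.1; Levene 0.93 (crit 4.49); S-W 0.94/0.87 (crit 0.83)
```

Method 1 (classification-driven algorithm selection) scores significantly
better (lower) than method 2 (fixed regulator) on every efficiency
parameter at the 0.05 level: both groups pass the Shapiro–Wilk normality
check (W above the 0.83 critical value) and Levene's homogeneity check
(below 4.49), and each one-sided t exceeds 1.746. The t statistics shown
are recomputed from the bundled (rounded, integer-mm) scores; analyses of
the unrounded originals give slightly smaller values.

A command-line wrapper covers the same pipeline
(`simulate`, `build-patterns`, `classify`, `teach`, `evaluate`, `stats`):

```sh
Rscript exec/motionteach simulate --out alpha.csv --seed 11 --duration 16
Rscript exec/motionteach stats --table inst/extdata/table3.csv --out report.json
```

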