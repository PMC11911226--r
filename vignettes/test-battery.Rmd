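---
title: "Standardized, individualized wheelchair capacity testing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized, individualized wheelchair capacity testing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheelergo)
```

## The problem

Anaerobic (Wingate, WAnT) and aerobic (graded exercise test, GXT) capacity
tests on a wheelchair roller ergometer only produce comparable numbers when
the braking resistance suits the athlete. Too little resistance lets hand
velocity exceed what upper-body coordination can follow; too much resistance
ends a GXT in muscular fatigue after a few minutes. Wheelchair athletes are
heterogeneous in sport, impairment, sex and mass, so fixed settings fail.
The protocol implemented here individualizes both resistances from earlier
tests in the same session: an isometric strength test and a 10-s sprint
predict 30-s anaerobic power (P30), which sets the WAnT resistance; measured
P30 predicts aerobic peak power (PO~peak~), which sets the GXT staircase.
Validity gates check afterwards whether the settings worked: the WAnT is
valid when peak rim velocity stays below 3.0 m·s^-1^, the GXT when exhaustion
arrives between 8 and 12 min.

`wheelergo` implements the full chain: trace-level signal processing,
outcome extraction for all four tests, resistance design, the regression
machinery used to refit the prediction equations on a cohort, and a
physics-based synthetic-data generator so that every step is testable
without access to an ergometer.

## Signals and primitives

The ergometer samples tangential torque at the wheel and wheel velocity at
100 Hz for each side. All channels are low-pass filtered with a fourth-order
Butterworth filter at 10 Hz. The filter is applied forward and backward
(zero phase): the protocol's outcome definitions include single-sample peak
locations (PO~max~, v~max~), and a causal filter would lag those peaks. We
pad both ends by odd reflection (up to 100 samples) before the two passes so
that constant signals pass with DC gain exactly 1 and the startup transients
of the recursion stay out of the retained region. Phase handling and edge
policy are package design choices; the protocol itself specifies only the
filter order and cutoff.

Per-side rim force is `F = M / r_r` and per-side power `P = M v_w / r_w`,
with `r_r` the handrim radius and `r_w` the wheel radius. Conventions used
everywhere: *combined force and velocity are the mean of the two sides;
total power is the sum* ("power is the sum of both arms, velocity the
mean"). Rolling windows are `round(window × sample_rate)` samples with ties
rounding half up, and only fully populated windows are eligible when a
maximum is extracted.

Loading rejects traces whose sampling interval deviates more than 1% from
nominal instead of resampling them. A resampling policy would silently
change outcome values; failing loudly is safer for a measurement pipeline.

## Outcome definitions

* **Isometric strength** F~iso~: highest 3-s rolling mean of the
  left/right-averaged force, over (typically three) 5-s maximal efforts.
  A saturation heuristic flags trials whose force sits within 0.5% of its
  own ceiling for more than half of the best window — the signature of an
  athlete stronger than the ergometer's brakes. The flag never rejects a
  result automatically, because the ergometer's actual force limit is not
  part of the protocol.
* **Sprint**: mean and single-sample peak of summed power and mean-side
  velocity over the first 10 s; the repetition with the highest v~max~ is
  reported. Because tests start from stand still, pre-start idle is trimmed
  at the first sample where summed power exceeds 2% of the trace maximum
  (configurable).
* **WAnT**: P30 (30-s mean of summed power), P5 (highest 5-s rolling mean),
  PO~max~, and peak rim velocity v~max-rim~ (mean-side wheel velocity times
  `r_r / r_w`). Valid iff v~max-rim~ < 3.0 m·s^-1^; exactly 3.0 is invalid
  under the literal strict inequality.
* **GXT**: PO~peak~ is the highest 30-s rolling mean of summed power over
  windows fully inside the final 1-min block that was entered. If the final
  partial block is shorter than 30 s, the last completed stage is used
  instead — the protocol is silent on partial blocks, and this fallback
  never invents a window that spans a resistance change. Duration runs from
  test start to termination: the first moment the velocity stays more than
  0.28 m·s^-1^ below target continuously for 3 s (the margin is from the
  protocol; the 3-s persistence is a package choice — a single noisy dip
  should not end a test). Durations of exactly 8 or 12 min are valid
  (boundaries inclusive). VO~2peak~ and RER~peak~ are the highest 30-s means
  of the breath records, VO~2~ normalized by body mass only (not wheelchair
  mass); HR~peak~ is a single-sample maximum. Overall RPE is the mean of the
  peripheral and central scores; the RPE ≥ 8 criterion is evaluated on this
  overall value.
* **Secondary maximality criteria**: RER~peak~ ≥ 1.10, HR~peak~ ≥ 95% of
  (200 − age), overall RPE ≥ 8; met when two of three hold. For athletes
  with a lesion above T5 the HR criterion is not applicable (impaired
  sympathetic cardiac drive), and both remaining criteria must hold.

## Resistance design

Prediction equations live in one registry (`prediction_equation()`), all on
the per-kg scale with sport entering as three dummies against a tennis
reference. The legacy pair is `P30/kg = 0.51 F_iso/kg − 0.18` and
`PO_peak/kg = 0.67 P30/kg + 0.11`; the updated, sport-specific fits add the
dummy block, and the recommended defaults are the sprint-based P30 equation
(R² 0.84) and the Wingate-based PO~peak~ equation (R² 0.78). Predictions are
kept at full precision; rounding to whole watts happens only in reports.

The WAnT resistance coefficient dissipates the predicted P30 at a mean rim
velocity of 2.0 m·s^-1^: μ = P / (v_wheel · m_total · g), with v_wheel =
2.0 · r_w / r_r and m_total the athlete-plus-wheelchair mass. μ is a
dimensionless rolling-resistance coefficient (force over supported weight),
so the mass term enters as weight with g = 9.80665 m·s^-2^. This reading is
fixed by the standardized sprint resistance μ = 0.012, a typical court
rolling-resistance value on that same scale.

The GXT staircase starts at 20% of predicted PO~peak~ and adds 10% of the
difference between start load and prediction — 8% of the prediction — every
minute: `power(k) = 0.2 P + 0.08 P (k − 1)`. Stage power first equals the
prediction at stage 11, which is what places expected exhaustion "around
minute 10"; inverting the progression, athletes whose true capacity lies
between 0.76 and 1.08 of the prediction land inside the 8–12-min validity
window. Stage 1 lasts a full minute before the first increment. Per-stage μ
is computed at the athlete's self-chosen velocity, which is treated as a
free input (court athletes typically 1.4–2.5 m·s^-1^, racing athletes much
faster).

## Refitting the prediction equations

The model-construction procedure mirrors classical clinical-prediction
practice: univariate screening keeps candidates associated with the
response at p < 0.10 (sport as a three-dummy block judged by a joint
F-test); within the sprint family (v~mean~, v~max~, PO~mean~, PO~max~) and
the Wingate family (P30, P5, PO~max~), variables with pairwise |r| > 0.8
never enter the same model and only the member with the highest univariate
R² survives; backward elimination then removes the least significant term
until all remaining terms have p < 0.05. The sport dummies enter and leave
as one block via a partial F-test — that is how printed equations can retain
individually non-significant dummies. Missing values are handled
complete-case per model with the used n reported. Plain OLS t/F machinery
is used throughout; nothing in the procedure calls for robust or mixed
alternatives.

`compare_pred_meas()` tests predicted against measured values with a paired
t-test when the Shapiro–Wilk test does not reject normality of the paired
differences, otherwise a Wilcoxon signed-rank test. The per-athlete percent
difference is 100·(pred − meas)/meas — the measured value is the
denominator; the source protocol never defines this convention, so it is
fixed here and documented. Deviation boundaries for scatter plots sit at
±20% around the identity line, matching the acceptable 10 ± 2 min duration
band.

## What the synthetic generator emulates — and what it does not

The generator exists so that every analyzer and the full design loop can be
exercised against known ground truth.

* **Propulsion model**: half-sine force pulses with 50% duty cycle at a
  fixed cadence (1.0 Hz court, 1.5 Hz racing), driving
  `m dv/dt = F_app − μ m g` integrated at 100 Hz. The pulse train is scaled
  so its cycle mean matches a prescribed power envelope; an exact
  midpoint-rule energy ledger (work = friction + kinetic energy) is attached
  to every trace and checked in tests to 1%.
* **Isometric trials** ramp, hold a plateau at the true F~iso~ (best trial
  exact, others jittered low) with multiplicative noise, and release; an
  optional clip limit emulates force-limit saturation.
* **Wingate traces** follow a linearly decaying power envelope whose 30-s
  mean equals the true P30 and whose start/end ratio defaults to 1.6,
  consistent with observed P5 > P30. A rolling-start option begins at the
  steady-state velocity for steady-propulsion checks.
* **GXT sessions** interpolate the staircase at the athlete's true PO~peak~
  to obtain the exhaustion time — capacity equal to stage-k power means
  exhaustion exactly at minute k — then fade the velocity so the 0.28
  m·s^-1^ margin is crossed at that (sample-aligned) moment. Breath records
  follow first-order VO~2~ kinetics (τ = 30 s) toward a peak implied by
  ~10% gross mechanical efficiency, with RER crossing 1.10 and HR
  approaching 97% of (200 − age) near exhaustion.
* **Cohorts** sample sport (11:9:12:11 mix), sex, mass and sprint velocity
  from sport-specific truncated normals matching the study cohort's summary
  statistics; P30/kg then follows the sprint generating equation plus
  Gaussian noise calibrated so the population R² equals the equation's
  nominal value, and PO~peak~/kg likewise from the Wingate equation.
  Relative isometric strength is generated through the *inverse* of the
  strength equation plus noise (SD 1.2 N·kg^-1^), which reproduces the
  reported univariate structure (sprint velocity ≈ 0.77, strength ≈ 0.45,
  sport ≈ 0.31) and keeps the cohort consistent with both fitted equations,
  as real athletes are.

Not emulated: push-by-push biomechanics (joint kinetics, hand-rim contact),
left/right asymmetry beyond a symmetric default, sex effects on performance,
day-to-day variability, and metabolic-cart measurement error structure.
Passing round-trip tests therefore demonstrates correctness of the analysis
chain under the stated signal model, not validity of the protocol on new
human data.

## Numerical choices and degenerate inputs

* Window widths round half up (`floor(w + 0.5)`) for cross-platform
  determinism; R's default banker's rounding would make 0.5-sample ties
  platform-ambiguous.
* Termination falls back to end-of-trace when the velocity never stays
  below the margin.
* The saturation heuristic, idle-trim threshold (2% of peak power) and
  termination dwell (3 s) are configurable arguments with the defaults
  stated here.
* Equation evaluation refuses missing predictors and unknown sports rather
  than imputing; rank-deficient elimination fits abort naming the aliased
  terms; constant screening candidates are excluded with a warning record.
* All generators are deterministic given one explicit seed; no hidden RNG
  state survives between calls.

## Problem sizes used in the test suite

The suite runs at desk scale by design: oracle-equivalence checks use 1000
random traces at 10–50 Hz with 3/5/30-s windows; the parameter-recovery
experiment uses 200 replicate cohorts of n = 43 (the study's size); cohort
calibration checks use up to n = 5000. These sizes give the binomial
coverage assertions (≥ 90% of replicates) comfortable margins while keeping
the whole suite in the order of a minute.

## Known limitations

* The sport-block retention rate under resampling is governed by the power
  of the 3-degree-of-freedom partial F-test at n = 43; with noise
  calibrated to R² = 0.84 the block survives elimination in roughly four of
  five replicate cohorts. On any single cohort (like the original study's)
  retention is a draw from exactly this distribution.
* The Table-style percent differences between predicted and measured group
  values are not recomputable from group summary statistics alone; the
  package computes them per athlete and aggregates.
* The GXT exhaustion model is deliberately simple (staircase interpolation
  plus velocity fade); it reproduces duration arithmetic exactly but says
  nothing about pacing, thermoregulation or motivation.
* Ergometer friction calibration, metabolic-cart calibration, the 2×4-min
  submaximal test and gross mechanical efficiency are out of scope.
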