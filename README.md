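# wheelergo

Standardized, individualized wheelchair ergometer capacity testing in R.

Valid anaerobic (Wingate, WAnT) and aerobic (graded exercise test, GXT)
capacity tests on a wheelchair roller ergometer require a braking resistance
matched to the athlete — too low and hand velocity outruns coordination, too
high and the test ends in early muscular fatigue. `wheelergo` implements a
test-battery protocol that derives those resistances from the athlete's own
earlier results in the same session, for sport scientists and practitioners
testing wheelchair athletes (rugby, basketball, tennis, racing):

* **Signal processing** for 100 Hz torque/velocity traces: zero-phase 4th
  order Butterworth filtering (10 Hz), rim force `F = M / r_r`, power
  `P = M v_w / r_w`, rolling-window statistics.
* **Outcome extraction** for all four tests: F_iso (highest 3-s rolling mean
  force), sprint PO/v mean/max over 10 s, WAnT P30 / P5 / PO_max /
  v_max-rim, GXT PO_peak (highest 30-s mean in the final 1-min block),
  VO2peak, RER_peak, HR_peak — with the protocol's validity gates
  (v_max-rim < 3.0 m s⁻¹; 8 ≤ duration ≤ 12 min; two-of-three secondary
  criteria with heart-rate exclusion for lesions above T5).
* **Resistance design.** Anaerobic power per kg is predicted from isometric
  strength (legacy: `P30/kg = 0.51 F_iso/kg − 0.18`) or, preferably, from
  sprint velocity and sport
  (`P30/kg = −1.19 + 1.02 v_mean − 0.59 racing − 0.26 basketball − 0.15 rugby`);
  the WAnT rolling-resistance coefficient dissipates that power at a mean
  rim velocity of 2.0 m s⁻¹: `μ = P30_pred / (v_wheel · m_total · g)`.
  Aerobic power is predicted from measured P30
  (`PO_peak/kg = 0.56 + 0.47 P30/kg − 0.35 racing − 0.01 basketball − 0.37 rugby`),
  and the GXT staircase starts at 20% of the prediction, adding 8% of it
  every minute so exhaustion lands around minute 10.
* **Regression toolkit** reconstructing the model-building procedure:
  univariate screening (p < 0.10), collinearity pruning within the sprint
  and Wingate variable families (|r| > 0.8), backward elimination (p < 0.05)
  with sport as a tennis-referenced dummy block, paired
  t / Wilcoxon predicted-vs-measured comparisons, ±20% deviation plots.
* **Synthetic data**: physics-based push-cycle simulation (half-sine pulses,
  `m dv/dt = F − μ m g`), isometric/Wingate/GXT session generators and a
  cohort generator with known generating equations, so the whole chain is
  testable without an ergometer.

## Worked example

Design a Wingate and a GXT for a 67 kg tennis player (13 kg chair, wheel
radius 0.31 m, rim radius 0.26 m) whose isometric strength is 262 N, then
simulate and analyze the session:

```r
library(wheelergo)

pro  <- athlete_profile(mass_user = 67, mass_wheelchair = 13,
                        sex = "male", age = 26, sport = "tennis")
geom <- wheel_geometry(wheel_radius = 0.31, rim_radius = 0.26)

wplan <- design_wingate(pro, geom, inputs = list(f_iso = 262),
                        equation = "p30_strength_legacy")
wplan
#> <wingate_plan> P30_pred = 121.6 W (1.81 W/kg, p30_strength_legacy)
#>   mu = 0.0650 at rim velocity 2.0 m/s (wheel 2.385 m/s), m_total = 80.0 kg

gt <- athlete_ground_truth(pro, true_f_iso = 262,
                           true_p30 = wplan$p30_pred, true_po_peak = 95)
wres <- analyze_wingate(filter_trace(
  synth_wingate_trace(gt, mu = wplan$wingate_mu, seed = 1)))
wres
#> <wingate_result> P30 = 121.9 W, P5 = 144.8 W, PO_max = 466.9 W, v_max-rim = 2.33 m/s [valid]

gplan <- design_gxt(pro, inputs = list(p30 = wres$p30), chosen_velocity = 2.0)
sess  <- synth_gxt_session(gt, gplan, seed = 1)
analyze_gxt(sess$trace, gplan$stages, target_velocity = 2.0, profile = pro,
            breaths = sess$breaths, rpe_peripheral = 8, rpe_central = 7)
#> <gxt_result> PO_peak = 94.9 W, duration = 11.03 min [valid], VO2peak = 40.6 mL/min/kg, secondary criteria met
```

Reading the output: the designed μ of 0.0650 brings the athlete's 30-s
all-out effort to a mean rim velocity near the 2.0 m s⁻¹ design point, so the
measured P30 (121.9 W) reproduces the prediction and the peak rim velocity
(2.33 m s⁻¹) stays under the 3.0 m s⁻¹ validity limit. The GXT staircase
(19.0 W start, +7.6 W per minute) brings this athlete — whose true PO_peak
sits at 100% of the prediction — to exhaustion at minute 11, inside the
8–12 min validity window, and the extracted PO_peak (94.9 W) recovers the
true value.

Refitting the prediction equations on a cohort file with the published
procedure:

```r
cohort <- synth_cohort(43, seed = 1)   # or read_cohort("cohort.csv")
cmd_refit(cohort, response = "p30_per_kg")
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/wheelergo.R` with subcommands `analyze`, `plan`, `refit` and
`simulate`.

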