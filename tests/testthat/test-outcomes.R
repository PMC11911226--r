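test_that("isometric analysis extracts the highest 3-s rolling mean force", {
  pro <- std_profile(mass = 67)

  # constant 262 N: the group-mean worked example (262 N, 67 kg -> 3.91 N/kg)
  res <- analyze_isometric(force_to_trace(rep(262, 500)), pro)
  expect_equal(res$f_iso, 262)
  expect_equal(res$f_iso_per_kg, 3.91, tolerance = 0.001)

  # max over trials
  trials <- lapply(c(80, 90, 84), function(f) force_to_trace(rep(f, 400)))
  expect_equal(analyze_isometric(trials, pro)$f_iso, 90)

  # ramp-hold-release with plateau 300 N recovers the plateau
  gt <- athlete_ground_truth(pro, true_f_iso = 300, true_p30 = 100,
                             true_po_peak = 80, noise_level = 0)
  tr <- synth_isometric_trials(gt, seed = 3)
  expect_equal(analyze_isometric(tr, pro)$f_iso, 300, tolerance = 1)

  expect_error(analyze_isometric(force_to_trace(rep(100, 150)), pro),
               "shorter")
})

test_that("isometric saturation flag trips on clipped plateaus only", {
  pro <- std_profile()
  gt <- athlete_ground_truth(pro, true_f_iso = 400, true_p30 = 120,
                             true_po_peak = 90, noise_level = 0.05)
  clipped <- analyze_isometric(synth_isometric_trials(gt, seed = 9,
                                                      clip_limit = 320), pro)
  expect_true(clipped$saturation_flag)
  expect_equal(clipped$f_iso, 320, tolerance = 2)
  free <- analyze_isometric(synth_isometric_trials(gt, seed = 9), pro)
  expect_false(free$saturation_flag)
})

test_that("sprint analysis selects the trial with the highest peak velocity", {
  n <- 1100
  mk <- function(v) power_to_trace(rep(100, n), v = rep(v, n))
  res <- analyze_sprint(list(mk(4.0), mk(4.2)))
  expect_equal(res$trial, 2L)
  expect_equal(res$v_max, 4.2)

  # constant power and velocity: all outcomes equal the constants
  res2 <- analyze_sprint(power_to_trace(rep(100, n), v = rep(3, n)))
  expect_equal(res2$po_mean, 100)
  expect_equal(res2$po_max, 100)
  expect_equal(res2$v_mean, 3)
  expect_equal(res2$v_max, 3)

  expect_error(analyze_sprint(power_to_trace(rep(100, 500), v = rep(3, 500))),
               "less than 10")
})

test_that("sprint outcomes equal brute-force sample statistics over [0,10)s", {
  pro <- std_profile(mass = 63, sport = "racing")
  gt <- athlete_ground_truth(pro, 253, 200, 110, noise_level = 0.03)
  tr <- synth_sprint_trace(gt, seed = 21)
  res <- analyze_sprint(tr, start_threshold = 0)
  pw <- power_trace(tr)
  idx <- 1:1000
  expect_equal(res$po_mean, mean(pw$total[idx]))
  expect_equal(res$po_max, max(pw$total[idx]))
  expect_equal(res$v_mean, mean(pw$velocity[idx]))
})

test_that("Wingate outcomes and the 3.0 m/s rim-velocity validity gate", {
  n <- 3100
  # constant 139 W: P30 = P5 = 139 (constant-signal identity)
  g1 <- wheel_geometry(0.31, 0.31)
  res <- analyze_wingate(power_to_trace(rep(139, n), v = rep(2.6, n),
                                        geometry = g1))
  expect_equal(res$p30, 139)
  expect_equal(res$p5, 139)
  expect_equal(res$po_max, 139)
  # with r_r = r_w rim velocity equals wheel velocity
  expect_equal(res$v_max_rim, 2.6)
  expect_true(res$valid)

  fast <- analyze_wingate(power_to_trace(rep(139, n), v = rep(3.1, n),
                                         geometry = g1))
  expect_false(fast$valid)
  # exactly 3.0 is invalid under the strict inequality
  at_limit <- analyze_wingate(power_to_trace(rep(139, n), v = rep(3.0, n),
                                             geometry = g1))
  expect_false(at_limit$valid)

  expect_error(analyze_wingate(power_to_trace(rep(139, 2000),
                                              v = rep(2, 2000))),
               "less than 30")
})

test_that("Wingate P5 window equals the brute-force argmax on decaying power", {
  set.seed(5)
  n <- 3200
  p <- 250 * exp(-(0:(n - 1)) / 2500) * (1 + 0.05 * rnorm(n))
  tr <- power_to_trace(p, v = rep(2.2, n))
  res <- analyze_wingate(tr, start_threshold = 0)
  total <- power_trace(tr)$total[1:3000]
  expect_equal(res$p30, mean(total))
  expect_equal(res$p5, max(brute_rolling_mean(total, 500)))
  expect_equal(res$po_max, max(total))
})

test_that("Wingate outcome ordering po_max >= p5 >= p30 holds on random traces", {
  set.seed(31)
  for (rep in 1:200) {
    n <- 3000 + sample(0:300, 1)
    p <- pmax(0, rnorm(n, 150, 60))
    v <- abs(rnorm(n, 2.2, 0.4)) + 0.1
    res <- analyze_wingate(power_to_trace(p, v = v), start_threshold = 0)
    expect_true(res$po_max >= res$p5 - 1e-9)
    expect_true(res$p5 >= res$p30 - 1e-9)
    expect_gte(res$p30, 0)
  }
})

test_that("termination detection honors the margin and dwell persistence", {
  sr <- 100
  n <- 3001  # 30 s
  v_const <- rep(2, n)
  tr <- power_to_trace(rep(80, n), v = v_const)
  expect_equal(detect_termination(tr, 2.0), 30)

  # step to target - 0.30 at t = 5 s and stays: termination at 5 s
  v_step <- ifelse(seq(0, 30, by = 0.01) < 5, 2.0, 1.70)
  tr2 <- power_to_trace(rep(80, n), v = v_step)
  expect_equal(detect_termination(tr2, 2.0), 5)

  # a 2-s dip shorter than the 3-s dwell does not terminate
  t <- seq(0, 30, by = 0.01)
  v_dip <- ifelse(t >= 10 & t < 12, 1.70, 2.0)
  tr3 <- power_to_trace(rep(80, n), v = v_dip)
  expect_equal(detect_termination(tr3, 2.0), 30)
  # but a 4-s dip does, at its start
  v_dip2 <- ifelse(t >= 10 & t < 14, 1.70, 2.0)
  tr4 <- power_to_trace(rep(80, n), v = v_dip2)
  expect_equal(detect_termination(tr4, 2.0), 10)
})

test_that("secondary criteria implement two-of-three with HR exclusion", {
  # all three met; HR cutoff for age 26 is 0.95 * 174 = 165.3
  r <- check_secondary_criteria(1.15, 190, 9, age = 26)
  expect_true(r$met)
  expect_equal(r$detail$threshold[r$detail$criterion == "hr"], 165.3)
  expect_true(all(r$detail$satisfied))

  # only RPE met: 1 of 3 fails
  expect_false(check_secondary_criteria(1.05, 150, 9, age = 30)$met)

  # lesion above T5: HR excluded, both remaining must be met
  r3 <- check_secondary_criteria(1.12, hr_peak = NA, rpe_overall = 8,
                                 age = 30, lesion_above_T5 = TRUE)
  expect_true(r3$met)
  expect_false(check_secondary_criteria(1.12, hr_peak = NA, rpe_overall = 7,
                                        age = 30, lesion_above_T5 = TRUE)$met)
  # boundary equalities count as met (>=)
  expect_true(check_secondary_criteria(1.10, 165.3, 8, age = 26)$met)
})

test_that("GXT analysis: final-block PO_peak, duration, and boundary validity", {
  pro <- std_profile()
  powers <- seq(20, by = 8, length.out = 12)
  stages <- std_stages(powers)

  # 10 full stages, final-block power 90 W: po_peak = 90, duration 10.0
  st90 <- std_stages(c(powers[1:9], 90, 95, 100))
  tr <- make_gxt_trace(st90$power, t_term = 600)
  res <- analyze_gxt(tr, st90, target_velocity = 2, profile = pro,
                     rpe_peripheral = 8, rpe_central = 8)
  expect_equal(res$po_peak, 90)
  expect_equal(res$duration, 10)
  expect_true(res$duration_valid)
  expect_equal(res$final_stage, 10L)

  # duration validity flips exactly at 8 and 12 minutes (inclusive)
  for (case in list(c(479, FALSE), c(480, TRUE), c(720, TRUE),
                    c(721.2, FALSE))) {
    tr_b <- make_gxt_trace(powers, t_term = case[1])
    r_b <- analyze_gxt(tr_b, stages, 2, pro)
    expect_equal(r_b$duration_valid, as.logical(case[2]),
                 label = paste("termination at", case[1], "s"))
  }
  # a 7-min test is invalid
  r7 <- analyze_gxt(make_gxt_trace(powers, t_term = 420), stages, 2, pro)
  expect_false(r7$duration_valid)
  expect_equal(r7$duration, 7)
})

test_that("GXT partial final block shorter than 30 s falls back a stage", {
  pro <- std_profile()
  powers <- seq(20, by = 8, length.out = 12)
  stages <- std_stages(powers)
  # termination 20 s into stage 10: stage-10 block cannot host a 30-s window
  tr <- make_gxt_trace(powers, t_term = 560)
  res <- analyze_gxt(tr, stages, 2, pro)
  expect_equal(res$final_stage, 10L)
  expect_equal(res$po_peak, powers[9])
  # termination 40 s into stage 10: the partial block itself is used
  tr2 <- make_gxt_trace(powers, t_term = 580)
  expect_equal(analyze_gxt(tr2, stages, 2, pro)$po_peak, powers[10])
})

test_that("GXT PO_peak equals a brute-force scan over admissible windows", {
  pro <- std_profile()
  powers <- seq(20, by = 8, length.out = 12)
  stages <- std_stages(powers)
  sr <- 100
  t_term <- 545  # mid-stage 10
  t <- seq(0, t_term + 8, by = 1 / sr)
  set.seed(17)
  stage_idx <- pmin(floor(t / 60) + 1L, 12L)
  p <- powers[stage_idx] * (1 + 0.08 * rnorm(length(t)))
  p[t >= t_term] <- 0
  v <- ifelse(t < t_term, 2, 1.5)
  tr <- power_to_trace(p, v)
  res <- analyze_gxt(tr, stages, 2, pro)
  # brute force over windows fully inside [540, 545) fails (< 30 s), so the
  # admissible windows live in stage 9: [480, 540)
  total <- power_trace(tr)$total
  sel <- which(t >= 480 & t < 540)
  expect_equal(res$po_peak, max(brute_rolling_mean(total[sel], 30 * sr)))
})

test_that("GXT gas outcomes are 30-s rolling maxima of the breath records", {
  pro <- std_profile(mass = 70)
  powers <- seq(20, by = 8, length.out = 10)
  stages <- std_stages(powers)
  tr <- make_gxt_trace(powers, t_term = 540)
  bt <- seq(0, 540, by = 2)
  vo2 <- 300 + 4 * bt          # rising; peak 30-s mean near the end
  rer <- 0.85 + bt / 1000
  hr <- 80 + 0.2 * bt
  br <- breath_records(bt, vo2, rer, hr)
  res <- analyze_gxt(tr, stages, 2, pro, breaths = br,
                     rpe_peripheral = 9, rpe_central = 8)
  # oracle: best 30-s window of a linear series is its last full window
  last_win <- vo2[bt >= 540 - 30 & bt < 540]
  expect_equal(res$vo2peak, mean(last_win) / 70, tolerance = 1e-6)
  expect_equal(res$hr_peak, max(hr))
  expect_equal(res$rpe_overall, 8.5)
})
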