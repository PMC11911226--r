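#' Latent ground truth for a synthetic athlete
#'
#' Encodes the quantities the test battery measures (true isometric strength,
#' true 30-s anaerobic power, true aerobic peak power) together with the
#' propulsion style, so that generated traces can be analyzed and the
#' recovered outcomes compared against known values.
#'
#' @param profile An [athlete_profile()].
#' @param true_f_iso True maximal isometric rim force, N.
#' @param true_p30 True 30-s mean anaerobic power, W.
#' @param true_po_peak True aerobic peak power, W.
#' @param geometry A [wheel_geometry()] (default r_w 0.31 m, r_r 0.26 m).
#' @param push_cadence Push frequency, Hz; court sports propel around 1.0 Hz,
#'   racing around 1.5 Hz.
#' @param noise_level Multiplicative noise fraction on generated signals.
#' @return An \code{athlete_ground_truth} object.
#' @export
athlete_ground_truth <- function(profile, true_f_iso, true_p30, true_po_peak,
                                 geometry = wheel_geometry(0.31, 0.26),
                                 push_cadence = if (profile$sport == "racing")
                                   1.5 else 1.0,
                                 noise_level = 0.05) {
  stopifnot(inherits(profile, "athlete_profile"),
            inherits(geometry, "wheel_geometry"))
  if (any(c(true_f_iso, true_p30, true_po_peak) <= 0)) {
    stop("true quantities must be positive", call. = FALSE)
  }
  if (push_cadence <= 0) stop("push_cadence must be positive", call. = FALSE)
  if (noise_level < 0) stop("noise_level must be >= 0", call. = FALSE)
  structure(
    list(profile = profile, true_f_iso = true_f_iso, true_p30 = true_p30,
         true_po_peak = true_po_peak, geometry = geometry,
         push_cadence = push_cadence, noise_level = noise_level),
    class = "athlete_ground_truth"
  )
}

#' Simulate isometric strength trials
#'
#' Each trial ramps up over ~1 s, holds a plateau near the true maximal force
#' for 5 s with multiplicative noise, and releases. The best trial plateaus
#' exactly at the true force (the remaining trials jitter downward), so with
#' zero noise [analyze_isometric()] recovers the ground truth exactly. An
#' optional force limit emulates an athlete surpassing the ergometer's
#' braking capacity: the force is clipped and the saturation flag should
#' trip.
#'
#' @param gt An [athlete_ground_truth()].
#' @param seed Integer seed.
#' @param n_trials Number of repetitions (default 3).
#' @param clip_limit Optional ergometer force limit, N.
#' @param noise Multiplicative noise fraction (default from \code{gt}).
#' @return List of [ergo_trace()] objects (velocity ~ 0 throughout).
#' @export
synth_isometric_trials <- function(gt, seed = 1L, n_trials = 3L,
                                   clip_limit = NULL,
                                   noise = gt$noise_level) {
  stopifnot(inherits(gt, "athlete_ground_truth"))
  set.seed(seed)
  sr <- ergo_constants()$sample_rate
  r_r <- gt$geometry$rim_radius
  # best trial plateaus exactly at true_f_iso; others slightly lower
  jitter <- -abs(stats::rnorm(n_trials, 0, 0.02))
  jitter[sample.int(n_trials, 1L)] <- 0
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    t <- seq(0, 8, by = 1 / sr)
    plateau <- gt$true_f_iso * (1 + jitter[i])
    env <- ifelse(t < 1, 0,
           ifelse(t < 2, (t - 1) * plateau,
           ifelse(t < 7, plateau,
                  pmax(0, plateau * (1 - (t - 7) / 0.5)))))
    f <- env * (1 + noise * stats::rnorm(length(t)))
    f <- pmax(f, 0)
    if (!is.null(clip_limit)) f <- pmin(f, clip_limit)
    trials[[i]] <- ergo_trace(
      time = t,
      torque_left = f * r_r, torque_right = f * r_r,
      velocity_left = rep(0, length(t)), velocity_right = rep(0, length(t)),
      geometry = gt$geometry, sample_rate = sr
    )
  }
  trials
}

# Half-sine push pulse train with 50% duty cycle; cycle mean is exactly 1/pi,
# so multiplying an envelope by pi * pulse keeps the cycle-mean power equal to
# the envelope.
push_pulse <- function(t, cadence) {
  phase <- (t * cadence) %% 1
  ifelse(phase < 0.5, sin(pi * phase / 0.5), 0)
}

# Integrate the roller dynamics m dv/dt = F_app - mu m g (v > 0) under an
# applied-power profile with push pulses. Returns the trace plus an exact
# (midpoint-convention) energy ledger.
integrate_propulsion <- function(gt, power_envelope, mu, duration,
                                 seed, noise, v0 = 0) {
  set.seed(seed)
  k <- ergo_constants()
  sr <- k$sample_rate
  dt <- 1 / sr
  m <- total_mass(gt$profile)
  g <- k$g
  t <- seq(0, duration, by = dt)
  n <- length(t)
  pulse <- push_pulse(t, gt$push_cadence)
  p_app <- power_envelope(t) * pi * pulse
  v <- numeric(n)
  v[1L] <- v0
  f_app <- numeric(n)
  v_floor <- 0.3
  work <- fric <- 0
  for (i in seq_len(n - 1L)) {
    f_app[i] <- p_app[i] / max(v[i], v_floor)
    f_res <- if (v[i] > 0) mu * m * g else 0
    a <- (f_app[i] - f_res) / m
    v[i + 1L] <- max(0, v[i] + a * dt)
    v_mid <- (v[i] + v[i + 1L]) / 2
    work <- work + f_app[i] * v_mid * dt
    fric <- fric + f_res * v_mid * dt
  }
  f_app[n] <- p_app[n] / max(v[n], v_floor)
  torque_side <- (f_app / 2) * gt$geometry$wheel_radius *
    (1 + noise * stats::rnorm(n))
  trace <- ergo_trace(
    time = t,
    torque_left = torque_side, torque_right = torque_side,
    velocity_left = v, velocity_right = v,
    geometry = gt$geometry, sample_rate = sr
  )
  attr(trace, "energy") <- list(
    work = work, friction_loss = fric,
    kinetic = 0.5 * m * (v[n]^2 - v0^2)
  )
  trace
}

#' Simulate a 10-s sprint trace
#'
#' Integrates the wheelchair-roller dynamics from stand still under half-sine
#' push pulses at the athlete's cadence against the standardized court
#' rolling resistance. The applied power budget defaults to a level
#' consistent with the athlete's anaerobic power.
#'
#' @param gt An [athlete_ground_truth()].
#' @param mu Rolling-resistance coefficient (default 0.012, gym court).
#' @param seed Integer seed.
#' @param duration Trace length, s (default 12, leaving margin around the
#'   10-s analysis window).
#' @param power_budget Cycle-mean applied power, W (default
#'   \code{0.9 * true_p30}).
#' @param noise Multiplicative torque noise fraction.
#' @return An [ergo_trace()] with an \code{"energy"} attribute
#'   (\code{work}, \code{friction_loss}, \code{kinetic}).
#' @export
synth_sprint_trace <- function(gt, mu = ergo_constants()$sprint_mu,
                               seed = 1L, duration = 12,
                               power_budget = 0.9 * gt$true_p30,
                               noise = gt$noise_level) {
  stopifnot(inherits(gt, "athlete_ground_truth"))
  integrate_propulsion(gt, function(t) rep(power_budget, length(t)),
                       mu = mu, duration = duration, seed = seed,
                       noise = noise)
}

#' Simulate a 30-s Wingate trace
#'
#' Applied power follows a linearly decaying fatigue envelope whose mean over
#' the 30-s window equals \code{true_p30} and whose start/end ratio defaults
#' to 1.6, so that P5 exceeds P30 as in real tests. Propulsion is pulsed at
#' the athlete's cadence and the dynamics run against the designed resistance
#' coefficient; \code{start = "rolling"} begins at the steady-state velocity
#' instead of stand still (useful for steady-propulsion checks).
#'
#' @param gt An [athlete_ground_truth()].
#' @param mu Resistance coefficient, typically \code{design_wingate()$wingate_mu}.
#' @param seed Integer seed.
#' @param duration Trace length, s (default 33).
#' @param decay_ratio Envelope start/end power ratio (default 1.6).
#' @param start \code{"standstill"} (protocol) or \code{"rolling"}.
#' @param noise Multiplicative torque noise fraction.
#' @return An [ergo_trace()] with an \code{"energy"} attribute.
#' @export
synth_wingate_trace <- function(gt, mu, seed = 1L, duration = 33,
                                decay_ratio = 1.6,
                                start = c("standstill", "rolling"),
                                noise = gt$noise_level) {
  stopifnot(inherits(gt, "athlete_ground_truth"))
  if (mu <= 0) stop("mu must be > 0", call. = FALSE)
  start <- match.arg(start)
  T30 <- ergo_constants()$wingate_duration
  p0 <- 2 * gt$true_p30 * decay_ratio / (1 + decay_ratio)
  p_end <- p0 / decay_ratio
  env <- function(t) pmax(0, p0 + (p_end - p0) * pmin(t, T30) / T30)
  v0 <- if (start == "rolling") {
    gt$true_p30 / (mu * total_mass(gt$profile) * ergo_constants()$g)
  } else 0
  integrate_propulsion(gt, env, mu = mu, duration = duration, seed = seed,
                       noise = noise, v0 = v0)
}

#' Simulate a graded exercise test session
#'
#' The athlete holds the target velocity while the stage power is within
#' capacity; exhaustion time interpolates the staircase at the true PO_peak
#' (so an athlete whose capacity equals the stage-8 power lasts exactly 8
#' min). As exhaustion approaches, velocity sags slightly and then collapses
#' below the 0.28 m s^-1 termination margin at the exhaustion time. Breath
#' records rise with a first-order lag toward the implied VO2peak; RER
#' crosses 1.10 and HR approaches 97% of the age-predicted maximum near
#' exhaustion.
#'
#' @param gt An [athlete_ground_truth()].
#' @param plan A \code{gxt_plan} from [design_gxt()].
#' @param seed Integer seed.
#' @param breath_interval Breath-record spacing, s (default 2).
#' @param noise Multiplicative power noise fraction.
#' @return List with \code{trace} ([ergo_trace()]), \code{breaths}
#'   ([breath_records()]), \code{exhaustion_time} (s) and
#'   \code{stages_completed}.
#' @export
synth_gxt_session <- function(gt, plan, seed = 1L, breath_interval = 2,
                              noise = gt$noise_level) {
  stopifnot(inherits(gt, "athlete_ground_truth"), inherits(plan, "gxt_plan"))
  set.seed(seed)
  k <- ergo_constants()
  sr <- k$sample_rate
  stage_len <- k$gxt_stage_duration
  target <- plan$gxt_target_velocity
  margin <- k$gxt_termination_margin
  stages <- plan$stages
  po_peak <- gt$true_po_peak

  # exhaustion time: linear interpolation of the staircase at true PO_peak
  over <- which(stages$power > po_peak + 1e-9)
  if (!length(over)) {
    t_ex <- nrow(stages) * stage_len
    k_star <- nrow(stages)
  } else {
    k_star <- over[1L]
    f <- if (k_star == 1L) {
      max(0.05, min(1, po_peak / stages$power[1L]))
    } else {
      (po_peak - stages$power[k_star - 1L]) /
        (stages$power[k_star] - stages$power[k_star - 1L])
    }
    t_ex <- ((k_star - 1L) + f) * stage_len
  }
  t_ex <- round(t_ex * sr) / sr  # snap to the sample grid

  duration <- t_ex + 8
  t <- seq(0, duration, by = 1 / sr)
  n <- length(t)
  fade <- min(5, t_ex / 2)
  v <- rep(target, n)
  hold <- t < t_ex - fade
  v[hold] <- target * (1 + 0.005 * stats::rnorm(sum(hold)))
  fading <- t >= t_ex - fade & t < t_ex
  v[fading] <- target - 0.25 * (t[fading] - (t_ex - fade)) / fade
  collapsed <- t >= t_ex
  v[collapsed] <- pmax(0.05 * target,
                       target - margin - 0.07 - 0.8 * (t[collapsed] - t_ex))

  stage_idx <- pmin(floor(t / stage_len) + 1L, nrow(stages))
  mu_t <- stages$mu[stage_idx]
  m <- plan$m_total
  p_total <- mu_t * m * k$g * v * (1 + noise * stats::rnorm(n))
  p_total <- pmax(p_total, 0)
  torque_side <- (p_total / 2) * gt$geometry$wheel_radius / pmax(v, 0.05)
  trace <- ergo_trace(
    time = t,
    torque_left = torque_side, torque_right = torque_side,
    velocity_left = v, velocity_right = v,
    geometry = gt$geometry, sample_rate = sr
  )

  # breath-by-breath records with first-order VO2 kinetics (tau = 30 s)
  bt <- seq(0, duration, by = breath_interval)
  stage_p <- stages$power[pmin(floor(bt / stage_len) + 1L, nrow(stages))]
  stage_p[bt >= t_ex] <- 0
  drive <- numeric(length(bt))
  tau <- 30
  for (i in seq_along(bt)[-1L]) {
    targ <- min(1, stage_p[i] / po_peak)
    drive[i] <- drive[i - 1L] +
      (targ - drive[i - 1L]) * (1 - exp(-breath_interval / tau))
  }
  vo2_rest <- 300
  vo2peak_abs <- 29.3 * po_peak  # ~10% gross efficiency
  age <- gt$profile$age
  frac <- pmin(bt / t_ex, 1)
  breaths <- breath_records(
    time = bt,
    vo2 = pmax(0, vo2_rest + (vo2peak_abs - vo2_rest) * drive *
                 (1 + 0.02 * stats::rnorm(length(bt)))),
    rer = 0.85 + 0.32 * frac^2 + 0.01 * stats::rnorm(length(bt)),
    hr = pmax(50, 70 + (0.97 * (200 - age) - 70) * frac^0.7 +
                stats::rnorm(length(bt), 0, 1))
  )
  list(trace = trace, breaths = breaths, exhaustion_time = t_ex,
       stages_completed = if (length(over)) k_star - 1L else nrow(stages))
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

# Per-sport sampling parameters calibrated to the athlete cohort summary
# statistics (means +/- SD); truncation bounds are realism guards only.
COHORT_PARAMS <- list(
  rugby      = list(mass = c(74, 9), v_mean = c(3.0, 0.4),
                    male_prop = 1.0, lesion_prob = 0.7),
  basketball = list(mass = c(67, 14), v_mean = c(3.2, 0.4),
                    male_prop = 3 / 9, lesion_prob = 0.05),
  tennis     = list(mass = c(64, 13), v_mean = c(3.4, 0.4),
                    male_prop = 6 / 12, lesion_prob = 0.05),
  racing     = list(mass = c(63, 9), v_mean = c(4.6, 0.9),
                    male_prop = 8 / 11, lesion_prob = 0.1)
)

# Noise SD (N kg^-1) on relative isometric strength around the inverse of the
# strength->P30 equation; calibrated so the univariate association between
# F_iso/kg and P30/kg lands near the reported R^2 of 0.45.
F_ISO_NOISE_SD <- 1.2

#' Generate a synthetic athlete cohort with known generating equations
#'
#' Samples sport, sex, body mass, isometric strength and sprint velocity from
#' sport-specific truncated normals calibrated to the athlete cohort's
#' summary statistics, then derives anaerobic (P30/kg) and aerobic
#' (PO_peak/kg) power from the chosen generating equations plus Gaussian
#' noise. The noise standard deviations are calibrated so the population
#' R-squared of each generating equation matches its nominal value (0.84 for
#' the sprint equation, 0.78 for the Wingate equation) unless overridden.
#' Correlated sprint and Wingate companion outcomes are included so the
#' collinearity-pruning rules can be exercised.
#'
#' @param n Number of athletes (>= 10).
#' @param seed Integer seed.
#' @param p30_equation Generating equation for P30/kg (name or object;
#'   default \code{"p30_sprint"}).
#' @param popeak_equation Generating equation for PO_peak/kg (default
#'   \code{"popeak_wingate"}).
#' @param sport_mix Named sampling proportions over the four sports; default
#'   matches the study cohort (11/9/12/11 of 43).
#' @param noise_sd Optional named list \code{list(p30 = ..., po_peak = ...)}
#'   of response noise SDs (W kg^-1) overriding the R-squared calibration.
#' @return A tibble with one row per athlete; the \code{"generating"}
#'   attribute records the equations and realized noise SDs.
#' @export
synth_cohort <- function(n, seed = 1L,
                         p30_equation = "p30_sprint",
                         popeak_equation = "popeak_wingate",
                         sport_mix = c(rugby = 11, basketball = 9,
                                       tennis = 12, racing = 11) / 43,
                         noise_sd = NULL) {
  if (n < 10L) stop("cohort generation needs n >= 10", call. = FALSE)
  set.seed(seed)
  p30_eq <- if (is.character(p30_equation)) prediction_equation(p30_equation)
            else p30_equation
  pop_eq <- if (is.character(popeak_equation))
              prediction_equation(popeak_equation) else popeak_equation

  sport <- sample(names(sport_mix), n, replace = TRUE, prob = sport_mix)
  draw <- function(field, lower, upper) {
    vapply(sport, function(s) {
      p <- COHORT_PARAMS[[s]][[field]]
      rtruncnorm(1L, p[1L], p[2L], lower, upper)
    }, numeric(1), USE.NAMES = FALSE)
  }
  mass <- draw("mass", 35, 120)
  sprint_v_mean <- draw("v_mean", 1.5, 7)
  male_prop <- vapply(sport, function(s) COHORT_PARAMS[[s]]$male_prop,
                      numeric(1), USE.NAMES = FALSE)
  lesion_prob <- vapply(sport, function(s) COHORT_PARAMS[[s]]$lesion_prob,
                        numeric(1), USE.NAMES = FALSE)
  sex <- ifelse(stats::runif(n) < male_prop, "male", "female")
  lesion <- stats::runif(n) < lesion_prob
  age <- rtruncnorm(n, 26, 7, 16, 60)
  tsi <- rtruncnorm(n, 21, 9, 1, 40)
  exper <- rtruncnorm(n, 8, 6, 0.5, 30)
  training <- rtruncnorm(n, 18, 6, 2, 35)
  chair <- ifelse(sport == "racing", rtruncnorm(n, 10, 1.5, 6, 16),
                  rtruncnorm(n, 14, 1.5, 8, 20))

  dummies <- t(vapply(sport, sport_dummies, numeric(3)))
  lin_pred <- function(eq, values) {
    eq$intercept + as.numeric(values[, names(eq$coefficients), drop = FALSE] %*%
                                eq$coefficients)
  }
  predictors <- cbind(sprint_v_mean = sprint_v_mean, dummies)
  det_p30 <- lin_pred(p30_eq, predictors)
  sd_p30 <- if (!is.null(noise_sd$p30)) noise_sd$p30 else
    stats::sd(det_p30) * sqrt((1 - p30_eq$r_squared) / p30_eq$r_squared)
  p30_per_kg <- det_p30 + stats::rnorm(n, 0, sd_p30)
  p30_per_kg <- pmax(p30_per_kg, 0.2)

  # relative strength through the inverse of the strength->P30 equation, so
  # the cohort is consistent with both fitted equations (as real athletes are)
  strength_eq <- prediction_equation("p30_strength")
  f_iso_per_kg <- (p30_per_kg - strength_eq$intercept -
                     as.numeric(dummies %*% strength_eq$coefficients[
                       SPORT_DUMMIES])) /
    strength_eq$coefficients[["f_iso_per_kg"]] +
    stats::rnorm(n, 0, F_ISO_NOISE_SD)
  f_iso <- pmin(pmax(f_iso_per_kg * mass, 50), 450)
  f_iso_per_kg <- f_iso / mass

  predictors2 <- cbind(predictors, f_iso_per_kg = f_iso_per_kg,
                       p30_per_kg = p30_per_kg)
  det_pop <- lin_pred(pop_eq, predictors2)
  sd_pop <- if (!is.null(noise_sd$po_peak)) noise_sd$po_peak else
    stats::sd(det_pop) * sqrt((1 - pop_eq$r_squared) / pop_eq$r_squared)
  po_peak_per_kg <- pmax(det_pop + stats::rnorm(n, 0, sd_pop), 0.1)

  # correlated companions within the sprint and Wingate variable families
  v_max <- 1.30 * sprint_v_mean + stats::rnorm(n, 0, 0.12)
  po_mean <- 9 * sprint_v_mean^2 + stats::rnorm(n, 0, 8)
  po_max_sprint <- 6.5 * po_mean + stats::rnorm(n, 0, 60)
  p5_per_kg <- 1.33 * p30_per_kg + stats::rnorm(n, 0, 0.06)
  po_max_wingate <- 2.6 * p30_per_kg * mass + stats::rnorm(n, 0, 15)

  out <- tibble::tibble(
    id = seq_len(n), sport = sport, sex = sex, age = age,
    mass_user = mass, mass_wheelchair = chair,
    time_since_injury = tsi, sport_experience = exper,
    training_hours_per_week = training, lesion_above_T5 = lesion,
    f_iso = f_iso, f_iso_per_kg = f_iso / mass,
    sprint_v_mean = sprint_v_mean, sprint_v_max = v_max,
    sprint_po_mean = po_mean, sprint_po_max = po_max_sprint,
    p30_per_kg = p30_per_kg, p30 = p30_per_kg * mass,
    p5_per_kg = p5_per_kg, po_max_wingate = po_max_wingate,
    po_peak_per_kg = po_peak_per_kg, po_peak = po_peak_per_kg * mass
  )
  attr(out, "generating") <- list(
    p30_equation = p30_eq, popeak_equation = pop_eq,
    sd_p30 = sd_p30, sd_po_peak = sd_pop
  )
  out
}
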