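# Shared fixtures and independent oracles for the test suite.

std_geometry <- function() wheel_geometry(0.31, 0.26)

std_profile <- function(mass = 67, chair = 13, sport = "tennis", age = 26,
                        sex = "male", lesion = FALSE) {
  athlete_profile(mass, chair, sex, age, sport, lesion_above_T5 = lesion)
}

# Build a trace directly from channel vectors at a given rate.
make_trace <- function(torque_left, torque_right = torque_left,
                       velocity_left = rep(0, length(torque_left)),
                       velocity_right = velocity_left,
                       sr = 100, geometry = std_geometry()) {
  n <- length(torque_left)
  ergo_trace(seq(0, by = 1 / sr, length.out = n),
             torque_left, torque_right, velocity_left, velocity_right,
             geometry = geometry, sample_rate = sr)
}

# Trace with prescribed combined force (N): equal per-side torque F * r_r.
force_to_trace <- function(force, sr = 100, geometry = std_geometry()) {
  make_trace(force * geometry$rim_radius, sr = sr, geometry = geometry)
}

# Trace with prescribed summed power (W) at constant velocity v (m/s):
# per-side torque = (P/2) * r_w / v.
power_to_trace <- function(power, v, sr = 100, geometry = std_geometry()) {
  n <- length(power)
  vv <- if (length(v) == 1L) rep(v, n) else v
  make_trace(power / 2 * geometry$wheel_radius / vv,
             velocity_left = vv, sr = sr, geometry = geometry)
}

# Exhaustive O(n*w) rolling-mean oracle, independent of the implementation.
brute_rolling_mean <- function(x, w) {
  vapply(seq_len(length(x) - w + 1L),
         function(i) sum(x[i:(i + w - 1L)]) / w, numeric(1))
}

# Closed-form Butterworth magnitude response for one pass; zero-phase
# two-pass filtering squares it.
butter_gain <- function(f, cutoff, order) {
  1 / sqrt(1 + (f / cutoff)^(2 * order))
}

# GXT session trace: constant per-stage summed power at target velocity,
# velocity dropping below the termination margin at t_term (s).
make_gxt_trace <- function(stage_powers, t_term, target = 2,
                           duration = t_term + 8, sr = 100,
                           geometry = std_geometry(), stage_len = 60) {
  t <- seq(0, duration, by = 1 / sr)
  stage_idx <- pmin(floor(t / stage_len) + 1L, length(stage_powers))
  p <- stage_powers[stage_idx]
  v <- ifelse(t < t_term, target, target - 0.5)
  p[t >= t_term] <- 0
  power_to_trace(p, v, sr = sr, geometry = geometry)
}

std_stages <- function(powers) {
  data.frame(index = seq_along(powers), power = powers,
             mu = powers / (2 * 80 * 9.80665))
}
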