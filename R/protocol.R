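#' Predict anaerobic power (P30) from strength or sprint outcomes
#'
#' Evaluates a P30 prediction equation per kilogram body mass and scales by
#' body mass for the absolute prediction. The legacy equation uses relative
#' isometric strength only; the updated sport-specific equations add dummy
#' variables with tennis as the reference.
#'
#' @param profile An [athlete_profile()]; supplies body mass and sport.
#' @param inputs Named list of measured predictors on their natural scales:
#'   \code{f_iso} (N) or \code{f_iso_per_kg} (N kg^-1) for strength-based
#'   equations, \code{sprint_v_mean} (m s^-1) for the sprint equation.
#' @param equation A [prediction_equation()] or its registry name (default
#'   \code{"p30_sprint"}, the recommended equation).
#' @return List with \code{per_kg} (W kg^-1), \code{watts} (W) and
#'   \code{equation}.
#' @export
#' @examples
#' pro <- athlete_profile(67, 13, "male", 26, "tennis")
#' predict_p30(pro, list(f_iso = 262), "p30_strength_legacy")
predict_p30 <- function(profile, inputs, equation = "p30_sprint") {
  eq <- resolve_equation(equation, "p30_per_kg")
  evaluate_equation(eq, profile, inputs)
}

#' Predict aerobic power (PO_peak) from P30, strength or sprint outcomes
#'
#' As [predict_p30()] but for the GXT design response. The recommended
#' equation predicts from measured P30 per kg and sport; the legacy equation
#' from P30 per kg alone.
#'
#' @inheritParams predict_p30
#' @param inputs Named list with \code{p30} (W) or \code{p30_per_kg}
#'   (W kg^-1), or \code{f_iso}/\code{f_iso_per_kg}, or \code{sprint_v_mean},
#'   depending on the equation.
#' @param equation Default \code{"popeak_wingate"} (recommended).
#' @return List with \code{per_kg}, \code{watts}, \code{equation}.
#' @export
predict_po_peak <- function(profile, inputs, equation = "popeak_wingate") {
  eq <- resolve_equation(equation, "po_peak_per_kg")
  evaluate_equation(eq, profile, inputs)
}

resolve_equation <- function(equation, response) {
  eq <- if (is.character(equation)) prediction_equation(equation) else equation
  if (!inherits(eq, "prediction_equation")) {
    stop("equation must be a prediction_equation or a registry name",
         call. = FALSE)
  }
  if (!identical(eq$response, response)) {
    stop("equation '", eq$name, "' predicts ", eq$response, ", not ",
         response, call. = FALSE)
  }
  eq
}

evaluate_equation <- function(eq, profile, inputs) {
  stopifnot(inherits(profile, "athlete_profile"))
  dummies <- sport_dummies(profile$sport)
  values <- c(
    f_iso_per_kg = resolve_per_kg(inputs, "f_iso", profile$mass_user),
    sprint_v_mean = if (!is.null(inputs$sprint_v_mean))
      as.numeric(inputs$sprint_v_mean) else NA_real_,
    p30_per_kg = resolve_per_kg(inputs, "p30", profile$mass_user),
    dummies
  )
  needed <- names(eq$coefficients)
  if (anyNA(values[needed])) {
    stop("equation '", eq$name, "' needs predictor(s) ",
         paste(needed[is.na(values[needed])], collapse = ", "),
         " which are missing from `inputs`", call. = FALSE)
  }
  per_kg <- eq$intercept + sum(eq$coefficients * values[needed])
  list(per_kg = per_kg, watts = per_kg * profile$mass_user, equation = eq$name)
}

# Accept either `<what>_per_kg` directly or absolute `<what>` divided by mass.
resolve_per_kg <- function(inputs, what, mass) {
  per_kg_name <- paste0(what, "_per_kg")
  if (!is.null(inputs[[per_kg_name]])) return(as.numeric(inputs[[per_kg_name]]))
  if (!is.null(inputs[[what]])) return(as.numeric(inputs[[what]]) / mass)
  NA_real_
}

#' Convert rim velocity to wheel velocity (and back)
#'
#' The handrim and the tire are rigidly coupled, so their linear velocities
#' scale with their radii: v_wheel = v_rim * r_w / r_r.
#'
#' @param v_rim Rim velocity, m s^-1.
#' @param geometry A [wheel_geometry()].
#' @return Wheel velocity, m s^-1.
#' @export
rim_to_wheel_velocity <- function(v_rim, geometry) {
  stopifnot(inherits(geometry, "wheel_geometry"))
  v_rim * geometry$wheel_radius / geometry$rim_radius
}

#' @rdname rim_to_wheel_velocity
#' @param v_wheel Wheel velocity, m s^-1.
#' @export
wheel_to_rim_velocity <- function(v_wheel, geometry) {
  stopifnot(inherits(geometry, "wheel_geometry"))
  v_wheel * geometry$rim_radius / geometry$wheel_radius
}

#' Rolling-resistance coefficient that dissipates a target power
#'
#' On the ergometer the braking force is mu times the supported weight, so a
#' target mean power P at wheel velocity v requires mu = P / (v * m_total * g).
#' mu is dimensionless (force over weight); g = 9.80665 m s^-2.
#'
#' @param power Target power, W (> 0).
#' @param v_wheel Wheel velocity at which the power should be dissipated,
#'   m s^-1 (> 0).
#' @param m_total Total moving mass (athlete + wheelchair), kg (> 0).
#' @return mu, dimensionless.
#' @export
#' @examples
#' resistance_coefficient(120, 2.3846, 80)
resistance_coefficient <- function(power, v_wheel, m_total) {
  if (!is.numeric(power) || any(power <= 0)) {
    stop("power must be > 0", call. = FALSE)
  }
  if (!is.numeric(v_wheel) || v_wheel <= 0) {
    stop("v_wheel must be > 0", call. = FALSE)
  }
  if (!is.numeric(m_total) || m_total <= 0) {
    stop("m_total must be > 0", call. = FALSE)
  }
  power / (v_wheel * m_total * ergo_constants()$g)
}

#' Power dissipated by a rolling-resistance setting at a given velocity
#'
#' Inverse of [resistance_coefficient()]: P = mu * m_total * g * v_wheel.
#'
#' @param mu Rolling-resistance coefficient.
#' @param v_wheel Wheel velocity, m s^-1.
#' @param m_total Total moving mass, kg.
#' @return Power, W.
#' @export
dissipated_power <- function(mu, v_wheel, m_total) {
  mu * m_total * ergo_constants()$g * v_wheel
}

#' Design the individualized Wingate resistance
#'
#' Predicts P30 from the strength or sprint outcome and computes the
#' resistance coefficient that dissipates exactly that power at a mean rim
#' velocity of 2.0 m s^-1 (converted to the wheel frame through the athlete's
#' geometry).
#'
#' @param profile An [athlete_profile()].
#' @param geometry A [wheel_geometry()].
#' @param inputs Measured predictors; see [predict_p30()].
#' @param equation P30 equation name or object (default \code{"p30_sprint"}).
#' @param design_rim_velocity Design mean rim velocity, m s^-1 (default 2.0).
#' @return A \code{wingate_plan}: \code{p30_pred} (W), \code{p30_pred_per_kg},
#'   \code{wingate_mu}, \code{design_rim_velocity}, \code{design_wheel_velocity},
#'   \code{m_total}, \code{equation}.
#' @export
design_wingate <- function(profile, geometry, inputs,
                           equation = "p30_sprint",
                           design_rim_velocity =
                             ergo_constants()$wingate_design_rim_velocity) {
  pred <- predict_p30(profile, inputs, equation)
  if (pred$watts <= 0) {
    stop("predicted P30 is not positive (", round(pred$watts, 2),
         " W); cannot design a resistance", call. = FALSE)
  }
  v_wheel <- rim_to_wheel_velocity(design_rim_velocity, geometry)
  m_tot <- total_mass(profile)
  structure(
    list(p30_pred = pred$watts,
         p30_pred_per_kg = pred$per_kg,
         wingate_mu = resistance_coefficient(pred$watts, v_wheel, m_tot),
         design_rim_velocity = design_rim_velocity,
         design_wheel_velocity = v_wheel,
         m_total = m_tot,
         equation = pred$equation),
    class = "wingate_plan"
  )
}

#' Design the individualized GXT staircase
#'
#' Predicts PO_peak from measured P30 (or another supported predictor), sets
#' the first stage to 20% of the prediction and increments each subsequent
#' minute by 10% of the difference between start load and prediction (i.e.
#' 8% of the prediction), so that the predicted PO_peak is reached around
#' minute 10 (stage power first equals the prediction at stage 11). Each
#' stage's mu is the coefficient dissipating the stage power at the athlete's
#' self-chosen velocity.
#'
#' @param profile An [athlete_profile()].
#' @param inputs Measured predictors; see [predict_po_peak()].
#' @param chosen_velocity Self-chosen comfortable velocity (wheel frame),
#'   m s^-1.
#' @param equation PO_peak equation name or object (default
#'   \code{"popeak_wingate"}).
#' @param n_stages Number of stages to tabulate (default 15).
#' @return A \code{gxt_plan}: \code{po_peak_pred} (W),
#'   \code{po_peak_pred_per_kg}, \code{gxt_target_velocity}, \code{m_total},
#'   \code{equation} and \code{stages}, a data frame (\code{index},
#'   \code{power}, \code{mu}).
#' @export
design_gxt <- function(profile, inputs, chosen_velocity,
                       equation = "popeak_wingate", n_stages = 15L) {
  if (!is.numeric(chosen_velocity) || chosen_velocity <= 0) {
    stop("chosen_velocity must be > 0", call. = FALSE)
  }
  pred <- predict_po_peak(profile, inputs, equation)
  if (pred$watts <= 0) {
    stop("predicted PO_peak is not positive (", round(pred$watts, 2),
         " W); cannot design a staircase", call. = FALSE)
  }
  k <- ergo_constants()
  start <- k$gxt_start_fraction * pred$watts
  increment <- k$gxt_increment_fraction * (pred$watts - start)
  idx <- seq_len(n_stages)
  power <- start + (idx - 1L) * increment
  m_tot <- total_mass(profile)
  stages <- data.frame(
    index = idx,
    power = power,
    mu = vapply(power, resistance_coefficient, numeric(1),
                v_wheel = chosen_velocity, m_total = m_tot)
  )
  structure(
    list(po_peak_pred = pred$watts,
         po_peak_pred_per_kg = pred$per_kg,
         gxt_target_velocity = chosen_velocity,
         m_total = m_tot,
         equation = pred$equation,
         stages = stages),
    class = "gxt_plan"
  )
}

#' Assemble a full protocol plan
#'
#' Combines the Wingate resistance design and the GXT staircase into one
#' protocol plan object for reporting/serialization.
#'
#' @param wingate A \code{wingate_plan} from [design_wingate()] (or NULL).
#' @param gxt A \code{gxt_plan} from [design_gxt()] (or NULL).
#' @return A \code{protocol_plan} list.
#' @export
protocol_plan <- function(wingate = NULL, gxt = NULL) {
  structure(list(wingate = wingate, gxt = gxt), class = "protocol_plan")
}

#' @export
print.wingate_plan <- function(x, ...) {
  cat(sprintf(
    "<wingate_plan> P30_pred = %.1f W (%.2f W/kg, %s)\n  mu = %.4f at rim velocity %.1f m/s (wheel %.3f m/s), m_total = %.1f kg\n",
    x$p30_pred, x$p30_pred_per_kg, x$equation, x$wingate_mu,
    x$design_rim_velocity, x$design_wheel_velocity, x$m_total))
  invisible(x)
}

#' @export
print.gxt_plan <- function(x, ...) {
  cat(sprintf(
    "<gxt_plan> PO_peak_pred = %.1f W (%.2f W/kg, %s), target velocity %.2f m/s\n",
    x$po_peak_pred, x$po_peak_pred_per_kg, x$equation, x$gxt_target_velocity))
  st <- utils::head(x$stages, 12)
  cat(paste(sprintf("  stage %2d: %6.1f W  mu = %.4f",
                    st$index, st$power, st$mu), collapse = "\n"), "\n")
  if (nrow(x$stages) > 12) cat("  ...\n")
  invisible(x)
}

#' @export
print.protocol_plan <- function(x, ...) {
  if (!is.null(x$wingate)) print(x$wingate)
  if (!is.null(x$gxt)) print(x$gxt)
  invisible(x)
}
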