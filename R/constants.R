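#' Protocol constants registry
#'
#' All numeric constants of the test battery live in this one registry so that
#' legacy versus updated settings are switchable and auditable: validity
#' thresholds, protocol design rules and physical constants. Values can be
#' overridden per call site but default to the published protocol.
#'
#' @return Named list of constants:
#' \describe{
#'   \item{g}{standard gravity, m s^-2 (9.80665)}
#'   \item{sample_rate}{ergometer sampling frequency, Hz (100)}
#'   \item{filter_cutoff, filter_order}{Butterworth low-pass settings (10 Hz, 4)}
#'   \item{iso_window}{rolling window for F_iso, s (3)}
#'   \item{sprint_duration}{sprint analysis window, s (10)}
#'   \item{sprint_mu}{standardized sprint rolling-resistance coefficient (0.012)}
#'   \item{wingate_duration, wingate_p5_window}{WAnT windows, s (30, 5)}
#'   \item{wingate_design_rim_velocity}{target mean rim velocity for WAnT
#'     resistance design, m s^-1 (2.0)}
#'   \item{wingate_vmax_rim_limit}{validity limit on peak rim velocity,
#'     m s^-1 (3.0)}
#'   \item{gxt_stage_duration}{GXT stage length, s (60)}
#'   \item{gxt_start_fraction, gxt_increment_fraction}{staircase rules: start at
#'     20% of predicted PO_peak, increase by 10% of (predicted - start) each
#'     minute (0.20, 0.10)}
#'   \item{gxt_window}{rolling window for PO_peak / gas outcomes, s (30)}
#'   \item{gxt_duration_valid}{valid test duration range, min (c(8, 12))}
#'   \item{gxt_termination_margin}{velocity drop that terminates the GXT,
#'     m s^-1 below target (0.28)}
#'   \item{gxt_termination_dwell}{how long the velocity must stay below the
#'     margin, s (3); persistence is a package design choice}
#'   \item{rer_criterion, hr_criterion_fraction, hr_max_intercept,
#'     rpe_criterion}{secondary maximality criteria: RER >= 1.10,
#'     HR >= 0.95 * (200 - age), overall RPE >= 8}
#'   \item{deviation_tolerance}{pred-vs-meas deviation boundaries (0.20)}
#'   \item{start_threshold}{fraction of peak summed power used to trim
#'     pre-start idle in sprint/WAnT traces (0.02)}
#' }
#' @export
#' @examples
#' ergo_constants()$wingate_vmax_rim_limit
ergo_constants <- function() {
  list(
    g = 9.80665,
    sample_rate = 100,
    filter_cutoff = 10,
    filter_order = 4,
    iso_window = 3,
    sprint_duration = 10,
    sprint_mu = 0.012,
    wingate_duration = 30,
    wingate_p5_window = 5,
    wingate_design_rim_velocity = 2.0,
    wingate_vmax_rim_limit = 3.0,
    gxt_stage_duration = 60,
    gxt_start_fraction = 0.20,
    gxt_increment_fraction = 0.10,
    gxt_window = 30,
    gxt_duration_valid = c(8, 12),
    gxt_termination_margin = 0.28,
    gxt_termination_dwell = 3,
    rer_criterion = 1.10,
    hr_criterion_fraction = 0.95,
    hr_max_intercept = 200,
    rpe_criterion = 8,
    deviation_tolerance = 0.20,
    start_threshold = 0.02
  )
}

#' Prediction equations for anaerobic (P30) and aerobic (PO_peak) power
#'
#' The registry holds the legacy equations (strength -> P30, P30 -> PO_peak)
#' and the updated sport-specific equations fitted on the wheelchair-athlete
#' cohort. All equations operate per kilogram body mass; sport enters as three
#' dummy variables with tennis as the reference category.
#'
#' Available equations (response, predictors):
#' \itemize{
#'   \item \code{p30_strength_legacy}: P30/kg = 0.51 F_iso/kg - 0.18 (R² 0.75)
#'   \item \code{p30_strength}: P30/kg = 0.11 + 0.50 F_iso/kg + 0.70 racing
#'     - 0.22 basketball - 0.22 rugby (R² 0.74)
#'   \item \code{p30_sprint}: P30/kg = -1.19 + 1.02 v_mean - 0.59 racing
#'     - 0.26 basketball - 0.15 rugby (R² 0.84) — recommended
#'   \item \code{popeak_wingate_legacy}: PO_peak/kg = 0.67 P30/kg + 0.11 (R² 0.81)
#'   \item \code{popeak_strength}: PO_peak/kg = 0.47 + 0.27 F_iso/kg
#'     - 0.01 racing - 0.10 basketball - 0.45 rugby (R² 0.71)
#'   \item \code{popeak_sprint}: PO_peak/kg = 0.38 + 0.38 v_mean - 0.62 racing
#'     - 0.20 basketball - 0.52 rugby (R² 0.64)
#'   \item \code{popeak_wingate}: PO_peak/kg = 0.56 + 0.47 P30/kg - 0.35 racing
#'     - 0.01 basketball - 0.37 rugby (R² 0.78) — recommended
#' }
#'
#' @param name Equation label; see Details. If missing, the whole registry is
#'   returned.
#' @return A \code{prediction_equation} object (list with \code{name},
#'   \code{response}, \code{intercept}, \code{coefficients}, \code{r_squared}),
#'   or a named list of all of them.
#' @export
#' @examples
#' prediction_equation("p30_sprint")
prediction_equation <- function(name) {
  reg <- list(
    p30_strength_legacy = new_prediction_equation(
      "p30_strength_legacy", "p30_per_kg",
      intercept = -0.18, coefficients = c(f_iso_per_kg = 0.51),
      r_squared = 0.75
    ),
    p30_strength = new_prediction_equation(
      "p30_strength", "p30_per_kg",
      intercept = 0.11,
      coefficients = c(f_iso_per_kg = 0.50, racing = 0.70,
                       basketball = -0.22, rugby = -0.22),
      r_squared = 0.74
    ),
    p30_sprint = new_prediction_equation(
      "p30_sprint", "p30_per_kg",
      intercept = -1.19,
      coefficients = c(sprint_v_mean = 1.02, racing = -0.59,
                       basketball = -0.26, rugby = -0.15),
      r_squared = 0.84
    ),
    popeak_wingate_legacy = new_prediction_equation(
      "popeak_wingate_legacy", "po_peak_per_kg",
      intercept = 0.11, coefficients = c(p30_per_kg = 0.67),
      r_squared = 0.81
    ),
    popeak_strength = new_prediction_equation(
      "popeak_strength", "po_peak_per_kg",
      intercept = 0.47,
      coefficients = c(f_iso_per_kg = 0.27, racing = -0.01,
                       basketball = -0.10, rugby = -0.45),
      r_squared = 0.71
    ),
    popeak_sprint = new_prediction_equation(
      "popeak_sprint", "po_peak_per_kg",
      intercept = 0.38,
      coefficients = c(sprint_v_mean = 0.38, racing = -0.62,
                       basketball = -0.20, rugby = -0.52),
      r_squared = 0.64
    ),
    popeak_wingate = new_prediction_equation(
      "popeak_wingate", "po_peak_per_kg",
      intercept = 0.56,
      coefficients = c(p30_per_kg = 0.47, racing = -0.35,
                       basketball = -0.01, rugby = -0.37),
      r_squared = 0.78
    )
  )
  if (missing(name)) {
    return(reg)
  }
  if (!name %in% names(reg)) {
    stop("unknown prediction equation '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}

#' Construct a prediction equation object
#'
#' @param name Label of the equation.
#' @param response Response label (per-kg scale), e.g. \code{"p30_per_kg"}.
#' @param intercept Intercept, W kg^-1.
#' @param coefficients Named numeric vector of predictor weights. Allowed
#'   predictor names: \code{f_iso_per_kg}, \code{sprint_v_mean},
#'   \code{p30_per_kg} and the sport dummies \code{racing}, \code{basketball},
#'   \code{rugby} (tennis is the reference).
#' @param r_squared Explained variance of the fit, in \[0, 1\].
#' @return A \code{prediction_equation} object.
#' @export
new_prediction_equation <- function(name, response, intercept, coefficients,
                                    r_squared = NA_real_) {
  allowed <- c("f_iso_per_kg", "sprint_v_mean", "p30_per_kg",
               "racing", "basketball", "rugby")
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients), length(names(coefficients)) ==
              length(coefficients))
  bad <- setdiff(names(coefficients), allowed)
  if (length(bad)) {
    stop("unknown predictor(s) in equation '", name, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(name = name, response = response, intercept = intercept,
         coefficients = coefficients, r_squared = r_squared),
    class = "prediction_equation"
  )
}

#' @export
print.prediction_equation <- function(x, ...) {
  terms <- sprintf("%+.3g x %s", x$coefficients, names(x$coefficients))
  cat("<prediction_equation> ", x$name, "\n  ", x$response, " = ",
      format(x$intercept), " ", paste(terms, collapse = " "),
      if (!is.na(x$r_squared)) sprintf("   (R^2 = %.2f)", x$r_squared),
      "\n", sep = "")
  invisible(x)
}

# Sport levels used throughout; tennis is the dummy reference.
SPORTS <- c("rugby", "basketball", "tennis", "racing")
SPORT_DUMMIES <- c("racing", "basketball", "rugby")
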