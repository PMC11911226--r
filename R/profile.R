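#' Athlete profile
#'
#' Demographic and equipment covariates that drive normalization (per-kg
#' outcomes), resistance design (total moving mass) and the regression
#' covariates.
#'
#' @param mass_user Body mass, kg (> 0).
#' @param mass_wheelchair Wheelchair mass, kg (> 0).
#' @param sex \code{"male"} or \code{"female"}.
#' @param age Age, years (> 0).
#' @param sport One of \code{"rugby"}, \code{"basketball"}, \code{"tennis"},
#'   \code{"racing"}.
#' @param time_since_injury Years since injury/onset (optional).
#' @param sport_experience Years of practice in the sport (optional).
#' @param training_hours_per_week Weekly training volume, h (optional).
#' @param lesion_above_T5 Logical; spinal lesion above T5 implies impaired
#'   sympathetic cardiac drive, so heart-rate-based maximality criteria are
#'   not applied.
#' @return An \code{athlete_profile} object.
#' @export
#' @examples
#' athlete_profile(67, 13, "male", 26, "tennis")
athlete_profile <- function(mass_user, mass_wheelchair, sex, age, sport,
                            time_since_injury = NA_real_,
                            sport_experience = NA_real_,
                            training_hours_per_week = NA_real_,
                            lesion_above_T5 = FALSE) {
  if (!is.numeric(mass_user) || mass_user <= 0) {
    stop("mass_user must be > 0", call. = FALSE)
  }
  if (!is.numeric(mass_wheelchair) || mass_wheelchair <= 0) {
    stop("mass_wheelchair must be > 0", call. = FALSE)
  }
  if (!is.numeric(age) || age <= 0) stop("age must be > 0", call. = FALSE)
  sex <- match.arg(sex, c("male", "female"))
  sport <- match.arg(sport, SPORTS)
  stopifnot(is.logical(lesion_above_T5), length(lesion_above_T5) == 1L)
  structure(
    list(mass_user = mass_user, mass_wheelchair = mass_wheelchair,
         sex = sex, age = age, sport = sport,
         time_since_injury = time_since_injury,
         sport_experience = sport_experience,
         training_hours_per_week = training_hours_per_week,
         lesion_above_T5 = lesion_above_T5),
    class = "athlete_profile"
  )
}

#' @export
print.athlete_profile <- function(x, ...) {
  cat(sprintf("<athlete_profile> %s %s, %g yr, %g kg (+%g kg chair)%s\n",
              x$sex, x$sport, x$age, x$mass_user, x$mass_wheelchair,
              if (isTRUE(x$lesion_above_T5)) ", lesion above T5" else ""))
  invisible(x)
}

#' Total moving mass (athlete + wheelchair), kg
#' @param profile An [athlete_profile()].
#' @return Numeric scalar, kg.
#' @export
total_mass <- function(profile) {
  stopifnot(inherits(profile, "athlete_profile"))
  profile$mass_user + profile$mass_wheelchair
}

# Sport dummy row (tennis reference), named numeric of length 3.
sport_dummies <- function(sport) {
  sport <- match.arg(sport, SPORTS)
  out <- c(racing = 0, basketball = 0, rugby = 0)
  if (sport %in% names(out)) out[sport] <- 1
  out
}
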