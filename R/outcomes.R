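#' Analyze the isometric strength test
#'
#' Maximal isometric strength F_iso is the highest 3-s rolling mean of the
#' left/right-averaged tangential rim force, taken over all trials. A
#' saturation flag marks trials whose force sits against its own ceiling for
#' most of the best window, the signature of an athlete surpassing the
#' ergometer force limit; the flag never invalidates the result by itself.
#'
#' @param trials A single [ergo_trace()] or list of them (typically 3 x 5 s).
#' @param profile An [athlete_profile()]; supplies body mass for the per-kg
#'   outcome.
#' @param window Rolling window, s (default 3).
#' @param saturation_tol Relative closeness to the channel maximum that counts
#'   as "at the ceiling" (default 0.005).
#' @param saturation_fraction Fraction of the best window that must sit at the
#'   ceiling to raise the flag (default 0.5).
#' @return An \code{isometric_result}: \code{f_iso} (N), \code{f_iso_per_kg}
#'   (N kg^-1), \code{saturation_flag}, \code{trial_maxima}.
#' @export
analyze_isometric <- function(trials, profile,
                              window = ergo_constants()$iso_window,
                              saturation_tol = 0.005,
                              saturation_fraction = 0.5) {
  trials <- as_trace_list(trials)
  stopifnot(length(trials) >= 1L, inherits(profile, "athlete_profile"))
  trial_maxima <- numeric(length(trials))
  saturation <- logical(length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (trace_duration(tr) < window) {
      stop("isometric trial ", i, " is shorter (", round(trace_duration(tr), 2),
           " s) than the ", window, " s analysis window", call. = FALSE)
    }
    f <- force_trace(tr)$combined
    best <- rolling_max(f, window, tr$sample_rate)
    trial_maxima[i] <- best$max
    win <- f[seq(best$start, best$start + best$width - 1L)]
    ceiling_level <- max(f)
    if (ceiling_level > 0) {
      at_ceiling <- mean(win >= ceiling_level * (1 - saturation_tol))
      saturation[i] <- at_ceiling > saturation_fraction
    }
  }
  f_iso <- max(trial_maxima)
  structure(
    list(f_iso = f_iso,
         f_iso_per_kg = f_iso / profile$mass_user,
         saturation_flag = saturation[which.max(trial_maxima)],
         trial_maxima = trial_maxima),
    class = "isometric_result"
  )
}

#' Analyze the 10-s sprint test
#'
#' Each trial is trimmed of pre-start idle (first sample where summed power
#' exceeds \code{start_threshold} of its trace maximum), outcomes are computed
#' over the first 10 s, and the trial with the highest single-sample peak
#' velocity is returned.
#'
#' @param trials A single [ergo_trace()] or a list (typically 2 repetitions).
#' @param duration Analysis window, s (default 10).
#' @param start_threshold Idle-trim threshold as a fraction of peak summed
#'   power (default 0.02); set to 0 to disable trimming.
#' @return A \code{sprint_result}: \code{po_mean}, \code{po_max} (W, summed
#'   over arms), \code{v_mean}, \code{v_max} (m s^-1, mean of sides),
#'   \code{trial} (index of the selected repetition).
#' @export
analyze_sprint <- function(trials,
                           duration = ergo_constants()$sprint_duration,
                           start_threshold = ergo_constants()$start_threshold) {
  trials <- as_trace_list(trials)
  stopifnot(length(trials) >= 1L)
  per_trial <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    pw <- power_trace(tr)
    i0 <- start_index(pw$total, start_threshold)
    n_win <- floor(duration * tr$sample_rate)
    if (i0 + n_win - 1L > length(tr)) {
      stop("sprint trial ", i, " has less than ", duration,
           " s of data after the detected start", call. = FALSE)
    }
    idx <- seq(i0, i0 + n_win - 1L)
    per_trial[[i]] <- list(
      po_mean = mean(pw$total[idx]), po_max = max(pw$total[idx]),
      v_mean = mean(pw$velocity[idx]), v_max = max(pw$velocity[idx])
    )
  }
  best <- which.max(vapply(per_trial, `[[`, numeric(1), "v_max"))
  structure(c(per_trial[[best]], list(trial = best)), class = "sprint_result")
}

#' Analyze the 30-s Wingate anaerobic test
#'
#' After idle trimming, computes P30 (mean summed power over 30 s), P5
#' (highest 5-s rolling mean), PO_max (single-sample peak) and the peak rim
#' velocity v_max-rim (mean-side wheel velocity scaled by r_r / r_w). The test
#' is valid when v_max-rim stays strictly below 3.0 m s^-1.
#'
#' @param trace An [ergo_trace()] covering at least 30 s of propulsion.
#' @param duration Analysis window, s (default 30).
#' @param p5_window Rolling window for P5, s (default 5).
#' @param vmax_rim_limit Validity limit on peak rim velocity, m s^-1
#'   (default 3.0; exactly 3.0 is invalid per the strict inequality).
#' @param start_threshold Idle-trim threshold (see [analyze_sprint()]).
#' @return A \code{wingate_result}: \code{p30}, \code{p5}, \code{po_max} (W),
#'   \code{v_max_rim} (m s^-1), \code{valid}.
#' @export
analyze_wingate <- function(trace,
                            duration = ergo_constants()$wingate_duration,
                            p5_window = ergo_constants()$wingate_p5_window,
                            vmax_rim_limit = ergo_constants()$wingate_vmax_rim_limit,
                            start_threshold = ergo_constants()$start_threshold) {
  stopifnot(inherits(trace, "ergo_trace"))
  pw <- power_trace(trace)
  i0 <- start_index(pw$total, start_threshold)
  n_win <- floor(duration * trace$sample_rate)
  if (i0 + n_win - 1L > length(trace)) {
    stop("Wingate trace has less than ", duration,
         " s of data after the detected start", call. = FALSE)
  }
  idx <- seq(i0, i0 + n_win - 1L)
  total <- pw$total[idx]
  ratio <- trace$geometry$rim_radius / trace$geometry$wheel_radius
  v_rim <- pw$velocity[idx] * ratio
  p30 <- mean(total)
  p5 <- rolling_max(total, p5_window, trace$sample_rate)$max
  structure(
    list(p30 = p30, p5 = p5, po_max = max(total),
         v_max_rim = max(v_rim),
         valid = max(v_rim) < vmax_rim_limit),
    class = "wingate_result"
  )
}

#' Detect GXT termination from the velocity trace
#'
#' The test terminates at the first time the mean-side wheel velocity stays
#' below (target - margin) continuously for \code{dwell} seconds; the reported
#' time is the start of that excursion. If the velocity never does so, the end
#' of the trace is returned.
#'
#' @param trace An [ergo_trace()].
#' @param target_velocity Target (self-chosen) velocity, m s^-1.
#' @param margin Allowed drop below target before termination, m s^-1
#'   (default 0.28).
#' @param dwell Required persistence below the threshold, s (default 3).
#' @return Termination time, s (trace time base).
#' @export
detect_termination <- function(trace, target_velocity,
                               margin = ergo_constants()$gxt_termination_margin,
                               dwell = ergo_constants()$gxt_termination_dwell) {
  stopifnot(inherits(trace, "ergo_trace"))
  if (target_velocity <= 0) {
    stop("target_velocity must be > 0", call. = FALSE)
  }
  v <- (trace$velocity_left + trace$velocity_right) / 2
  below <- v < target_velocity - margin
  need <- max(1L, as.integer(ceiling(dwell * trace$sample_rate)))
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= need)
  if (length(hit)) {
    return(trace$time[starts[hit[1L]]])
  }
  trace$time[length(trace$time)]
}

#' Evaluate the secondary maximality criteria of the GXT
#'
#' The three criteria are RER_peak >= 1.10, HR_peak >= 95% of predicted
#' maximal heart rate (200 - age), and overall RPE >= 8. The test counts as a
#' maximal aerobic effort when at least two are met. For athletes with a
#' lesion above T5 the heart-rate criterion is not applicable (impaired
#' sympathetic cardiac drive) and both remaining criteria must be met.
#'
#' @param rer_peak Peak 30-s respiratory exchange ratio.
#' @param hr_peak Peak heart rate, beats min^-1 (may be NA).
#' @param rpe_overall Overall RPE (mean of peripheral and central), 1-10.
#' @param age Age, years.
#' @param lesion_above_T5 Logical; excludes the HR criterion when TRUE.
#' @return List with \code{met} (logical) and \code{detail}, a data frame with
#'   one row per criterion (\code{criterion}, \code{threshold}, \code{value},
#'   \code{applicable}, \code{satisfied}).
#' @export
#' @examples
#' check_secondary_criteria(1.15, 190, 9, age = 26, lesion_above_T5 = FALSE)
check_secondary_criteria <- function(rer_peak, hr_peak, rpe_overall, age,
                                     lesion_above_T5 = FALSE) {
  if (!is.numeric(age) || age <= 0) stop("age must be > 0", call. = FALSE)
  k <- ergo_constants()
  hr_cutoff <- k$hr_criterion_fraction * (k$hr_max_intercept - age)
  hr_applicable <- !isTRUE(lesion_above_T5)
  detail <- data.frame(
    criterion = c("rer", "hr", "rpe"),
    threshold = c(k$rer_criterion, hr_cutoff, k$rpe_criterion),
    value = c(rer_peak, if (is.null(hr_peak)) NA_real_ else hr_peak,
              rpe_overall),
    applicable = c(TRUE, hr_applicable, TRUE)
  )
  detail$satisfied <- !is.na(detail$value) & detail$value >= detail$threshold
  detail$satisfied[!detail$applicable] <- NA
  applicable <- detail[detail$applicable, ]
  met <- if (hr_applicable) {
    sum(applicable$satisfied, na.rm = TRUE) >= 2L
  } else {
    all(applicable$satisfied, na.rm = FALSE) %in% TRUE
  }
  list(met = met, detail = detail)
}

#' Analyze the graded exercise test
#'
#' Duration runs from the start of the trace to the detected termination.
#' PO_peak is the highest 30-s rolling mean of summed power over windows fully
#' inside the final 1-min block that was entered; if the final partial block
#' offers less than 30 s, the last completed stage is used instead. Gas
#' outcomes are the highest 30-s rolling means of the breath records (VO2
#' normalized to body mass); HR_peak is the single-sample maximum.
#'
#' @param trace An [ergo_trace()] covering the session from stage 1 onward.
#' @param stages Stage table as produced by [design_gxt()] (data frame with
#'   \code{index}, \code{power}, \code{mu}).
#' @param target_velocity Self-chosen target velocity (wheel frame), m s^-1.
#' @param profile An [athlete_profile()].
#' @param breaths Optional [breath_records()]; gas outcomes are NA if absent.
#' @param rpe_peripheral,rpe_central RPE sub-scores (1-10), optional.
#' @param stage_duration Stage length, s (default 60).
#' @param window Rolling window for PO_peak and gas outcomes, s (default 30).
#' @return A \code{gxt_result}: \code{po_peak} (W), \code{duration} (min),
#'   \code{vo2peak} (mL min^-1 kg^-1), \code{rer_peak}, \code{hr_peak},
#'   \code{rpe_overall}, \code{duration_valid}, \code{secondary_criteria_met},
#'   \code{secondary_detail}, \code{termination_time} (s), \code{final_stage}.
#' @export
analyze_gxt <- function(trace, stages, target_velocity, profile,
                        breaths = NULL,
                        rpe_peripheral = NA_real_, rpe_central = NA_real_,
                        stage_duration = ergo_constants()$gxt_stage_duration,
                        window = ergo_constants()$gxt_window) {
  stopifnot(inherits(trace, "ergo_trace"),
            inherits(profile, "athlete_profile"))
  if (is.null(stages) || nrow(stages) < 1L) {
    stop("stage table is empty", call. = FALSE)
  }
  if (trace_duration(trace) < stage_duration) {
    stop("GXT trace does not cover one full stage", call. = FALSE)
  }
  term <- detect_termination(trace, target_velocity)
  duration_min <- term / 60

  # final 1-min block that was entered (termination exactly on a boundary
  # means the next stage was never entered)
  entered <- ceiling(term / stage_duration)
  entered <- max(1L, min(entered, nrow(stages)))
  pw <- power_trace(trace)
  block <- block_window(trace, pw$total, entered, term, stage_duration, window)
  if (is.null(block) && entered > 1L) {
    block <- block_window(trace, pw$total, entered - 1L,
                          entered * stage_duration, stage_duration, window)
  }
  if (is.null(block)) {
    stop("no admissible ", window, " s window inside the final block; ",
         "stage timing and trace are inconsistent", call. = FALSE)
  }
  po_peak <- block$max

  vo2peak <- rer_peak <- hr_peak <- NA_real_
  if (!is.null(breaths) && nrow(breaths) > 0) {
    use <- breaths[breaths$time <= term, , drop = FALSE]
    if (nrow(use) > 0) {
      vo2peak <- timed_rolling_max(use$time, use$vo2, window) /
        profile$mass_user
      rer_peak <- timed_rolling_max(use$time, use$rer, window)
      hr_peak <- max(use$hr)
    }
  }
  rpe_overall <- mean(c(rpe_peripheral, rpe_central))
  bounds <- ergo_constants()$gxt_duration_valid
  sec <- check_secondary_criteria(rer_peak, hr_peak, rpe_overall,
                                  age = profile$age,
                                  lesion_above_T5 = profile$lesion_above_T5)
  structure(
    list(po_peak = po_peak,
         duration = duration_min,
         vo2peak = vo2peak, rer_peak = rer_peak, hr_peak = hr_peak,
         rpe_overall = rpe_overall,
         duration_valid = duration_min >= bounds[1] & duration_min <= bounds[2],
         secondary_criteria_met = sec$met,
         secondary_detail = sec$detail,
         termination_time = term,
         final_stage = entered),
    class = "gxt_result"
  )
}

# Max `window`-s rolling mean of `x` restricted to windows fully inside the
# block [ (stage-1)*stage_duration, min(term, stage*stage_duration) ).
block_window <- function(trace, x, stage, term, stage_duration, window) {
  t0 <- (stage - 1L) * stage_duration
  t1 <- min(term, stage * stage_duration)
  if (t1 - t0 < window) return(NULL)
  sel <- trace$time >= t0 & trace$time < t1
  if (sum(sel) < window * trace$sample_rate) return(NULL)
  rolling_max(x[sel], window, trace$sample_rate)
}

# Rolling mean over a time-based window for irregular samples (breath data):
# windows are anchored at each record and must fit inside the record span.
timed_rolling_max <- function(time, x, window) {
  span <- time[length(time)] - time[1L]
  if (span < window) return(max(x))
  best <- -Inf
  for (i in seq_along(time)) {
    if (time[i] + window > time[length(time)] + 1e-9) break
    sel <- time >= time[i] & time < time[i] + window
    if (any(sel)) best <- max(best, mean(x[sel]))
  }
  best
}

# First sample where the summed power exceeds `threshold` of the trace max;
# trims the pre-start idle of stand-still tests.
start_index <- function(total_power, threshold) {
  if (threshold <= 0) return(1L)
  peak <- max(total_power)
  if (peak <= 0) return(1L)
  i <- which(total_power > threshold * peak)
  if (length(i)) i[1L] else 1L
}

as_trace_list <- function(trials) {
  if (inherits(trials, "ergo_trace")) trials <- list(trials)
  stopifnot(is.list(trials),
            all(vapply(trials, inherits, logical(1), "ergo_trace")))
  trials
}

#' Flatten test results into a single record
#'
#' Collects whichever of the four test results are present into a one-row
#' data frame mirroring the standard outcome table (F_iso, PO_mean, PO_max,
#' v_mean, v_max, P30, P5, v_max_rim, PO_peak, duration, VO2peak, validity
#' flags). Absent tests yield NA columns.
#'
#' @param isometric,sprint,wingate,gxt Results from the respective analyzers
#'   (or NULL).
#' @return A one-row data frame.
#' @export
result_record <- function(isometric = NULL, sprint = NULL, wingate = NULL,
                          gxt = NULL) {
  pick <- function(obj, field) {
    if (is.null(obj)) NA_real_ else as.numeric(obj[[field]])
  }
  pickl <- function(obj, field) {
    if (is.null(obj)) NA else isTRUE(obj[[field]])
  }
  data.frame(
    f_iso = pick(isometric, "f_iso"),
    f_iso_per_kg = pick(isometric, "f_iso_per_kg"),
    iso_saturation = pickl(isometric, "saturation_flag"),
    po_mean = pick(sprint, "po_mean"),
    po_max_sprint = pick(sprint, "po_max"),
    v_mean = pick(sprint, "v_mean"),
    v_max = pick(sprint, "v_max"),
    p30 = pick(wingate, "p30"),
    p5 = pick(wingate, "p5"),
    po_max_wingate = pick(wingate, "po_max"),
    v_max_rim = pick(wingate, "v_max_rim"),
    wingate_valid = pickl(wingate, "valid"),
    po_peak = pick(gxt, "po_peak"),
    duration = pick(gxt, "duration"),
    vo2peak = pick(gxt, "vo2peak"),
    rer_peak = pick(gxt, "rer_peak"),
    hr_peak = pick(gxt, "hr_peak"),
    rpe_overall = pick(gxt, "rpe_overall"),
    gxt_duration_valid = pickl(gxt, "duration_valid"),
    gxt_secondary_met = pickl(gxt, "secondary_criteria_met")
  )
}

#' @export
print.isometric_result <- function(x, ...) {
  cat(sprintf("<isometric_result> F_iso = %.1f N (%.2f N/kg)%s\n",
              x$f_iso, x$f_iso_per_kg,
              if (isTRUE(x$saturation_flag)) " [possible force-limit saturation]" else ""))
  invisible(x)
}

#' @export
print.sprint_result <- function(x, ...) {
  cat(sprintf(
    "<sprint_result> PO_mean = %.1f W, PO_max = %.1f W, v_mean = %.2f, v_max = %.2f m/s (trial %d)\n",
    x$po_mean, x$po_max, x$v_mean, x$v_max, x$trial))
  invisible(x)
}

#' @export
print.wingate_result <- function(x, ...) {
  cat(sprintf(
    "<wingate_result> P30 = %.1f W, P5 = %.1f W, PO_max = %.1f W, v_max-rim = %.2f m/s [%s]\n",
    x$p30, x$p5, x$po_max, x$v_max_rim,
    if (x$valid) "valid" else "INVALID"))
  invisible(x)
}

#' @export
print.gxt_result <- function(x, ...) {
  cat(sprintf(
    "<gxt_result> PO_peak = %.1f W, duration = %.2f min [%s], VO2peak = %.1f mL/min/kg, secondary criteria %s\n",
    x$po_peak, x$duration,
    if (isTRUE(x$duration_valid)) "valid" else "INVALID",
    x$vo2peak,
    if (isTRUE(x$secondary_criteria_met)) "met" else "not met"))
  invisible(x)
}
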