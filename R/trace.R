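#' Wheel geometry
#'
#' Radii of the wheel (tire contact with the roller) and of the handrim. The
#' two linear velocities of the same rotating wheel differ by the ratio of
#' these radii; forces are referred to the rim, power to the wheel.
#'
#' @param wheel_radius Wheel (tire) radius r_w, m.
#' @param rim_radius Handrim radius r_r, m; must satisfy 0 < r_r <= r_w.
#' @return A \code{wheel_geometry} object.
#' @export
#' @examples
#' wheel_geometry(0.31, 0.26)
wheel_geometry <- function(wheel_radius, rim_radius) {
  stopifnot(is.numeric(wheel_radius), is.numeric(rim_radius),
            length(wheel_radius) == 1L, length(rim_radius) == 1L)
  if (!is.finite(wheel_radius) || !is.finite(rim_radius)) {
    stop("wheel geometry radii must be finite", call. = FALSE)
  }
  if (rim_radius <= 0 || rim_radius > wheel_radius) {
    stop("wheel geometry requires 0 < rim_radius <= wheel_radius, got ",
         "rim_radius = ", rim_radius, ", wheel_radius = ", wheel_radius,
         call. = FALSE)
  }
  structure(list(wheel_radius = wheel_radius, rim_radius = rim_radius),
            class = "wheel_geometry")
}

#' @export
print.wheel_geometry <- function(x, ...) {
  cat(sprintf("<wheel_geometry> r_w = %.3f m, r_r = %.3f m\n",
              x$wheel_radius, x$rim_radius))
  invisible(x)
}

#' Ergometer session trace
#'
#' Time-aligned left/right torque (N m, at the wheel) and left/right wheel
#' velocity (m s^-1) sampled at \code{sample_rate}, plus the wheel geometry.
#' This is the raw substrate every analyzer works on.
#'
#' Time must be strictly increasing and nominally uniform; deviations of more
#' than 1% of the nominal sampling interval are rejected at construction
#' rather than resampled (failing loudly beats a silent resampling policy).
#'
#' @param time Sample times, s. Rebased to start at 0.
#' @param torque_left,torque_right Torque at the wheel per side, N m.
#' @param velocity_left,velocity_right Wheel velocity per side, m s^-1.
#' @param geometry A [wheel_geometry()].
#' @param sample_rate Sampling frequency, Hz (default 100).
#' @return An \code{ergo_trace} object (list of the validated channels).
#' @export
ergo_trace <- function(time, torque_left, torque_right,
                       velocity_left, velocity_right,
                       geometry, sample_rate = 100) {
  n <- length(time)
  chans <- list(torque_left = torque_left, torque_right = torque_right,
                velocity_left = velocity_left, velocity_right = velocity_right)
  for (nm in names(chans)) {
    if (length(chans[[nm]]) != n) {
      stop("channel '", nm, "' has length ", length(chans[[nm]]),
           " but time has length ", n, call. = FALSE)
    }
    if (anyNA(chans[[nm]])) {
      stop("channel '", nm, "' contains missing samples (row ",
           which(is.na(chans[[nm]]))[1L], ")", call. = FALSE)
    }
  }
  if (n < 2L) stop("a trace needs at least 2 samples", call. = FALSE)
  if (anyNA(time)) {
    stop("time contains missing values (row ", which(is.na(time))[1L], ")",
         call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      sample_rate <= 0) {
    stop("sample_rate must be a positive scalar", call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    stop("time must be strictly increasing; violated at row ",
         which(dt <= 0)[1L] + 1L, call. = FALSE)
  }
  nominal <- 1 / sample_rate
  jitter <- abs(dt - nominal) / nominal
  if (any(jitter > 0.01)) {
    stop("non-uniform sampling beyond 1% jitter at row ",
         which(jitter > 0.01)[1L] + 1L,
         "; resample upstream or fix the recording", call. = FALSE)
  }
  if (!inherits(geometry, "wheel_geometry")) {
    stop("geometry must be a wheel_geometry object", call. = FALSE)
  }
  structure(
    list(time = as.numeric(time) - time[1L],
         torque_left = as.numeric(torque_left),
         torque_right = as.numeric(torque_right),
         velocity_left = as.numeric(velocity_left),
         velocity_right = as.numeric(velocity_right),
         geometry = geometry,
         sample_rate = sample_rate),
    class = "ergo_trace"
  )
}

#' @export
print.ergo_trace <- function(x, ...) {
  cat(sprintf(
    "<ergo_trace> %d samples @ %g Hz (%.2f s), r_w = %.3f m, r_r = %.3f m\n",
    length(x$time), x$sample_rate, x$time[length(x$time)],
    x$geometry$wheel_radius, x$geometry$rim_radius))
  invisible(x)
}

#' @export
length.ergo_trace <- function(x) length(x$time)

#' Trace duration in seconds
#' @param trace An [ergo_trace()].
#' @return Duration from first to last sample, s.
#' @export
trace_duration <- function(trace) {
  trace$time[length(trace$time)] - trace$time[1L]
}

#' Read an ergometer trace from delimited text
#'
#' The trace dialect is UTF-8 comma-separated text with the header
#' \code{time,torque_left,torque_right,velocity_left,velocity_right}, SI
#' units, one sample per row. Geometry and sample rate either come from the
#' arguments or from a sidecar YAML/JSON config next to the file
#' (\code{<stem>.yaml} / \code{<stem>.json} with keys \code{wheel_radius},
#' \code{rim_radius}, \code{sample_rate}).
#'
#' @param path Path to the trace file.
#' @param geometry Optional [wheel_geometry()]; read from the sidecar if NULL.
#' @param sample_rate Optional sampling rate, Hz; sidecar or 100 if NULL.
#' @return A validated [ergo_trace()] with time rebased to 0.
#' @export
read_trace <- function(path, geometry = NULL, sample_rate = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path, check.names = FALSE)
  needed <- c("time", "torque_left", "torque_right",
              "velocity_left", "velocity_right")
  missing_cols <- setdiff(needed, names(dat))
  if (length(missing_cols)) {
    stop("malformed trace header in ", path, ": missing channel(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(geometry) || is.null(sample_rate)) {
    side <- read_trace_sidecar(path)
    if (is.null(geometry)) {
      if (is.null(side)) {
        stop("no geometry given and no sidecar config found for ", path,
             call. = FALSE)
      }
      geometry <- wheel_geometry(side$wheel_radius, side$rim_radius)
    }
    if (is.null(sample_rate)) {
      sample_rate <- if (!is.null(side$sample_rate)) side$sample_rate else 100
    }
  }
  ergo_trace(dat$time, dat$torque_left, dat$torque_right,
             dat$velocity_left, dat$velocity_right,
             geometry = geometry, sample_rate = sample_rate)
}

read_trace_sidecar <- function(path) {
  stem <- sub("\\.[^.]+$", "", path)
  for (ext in c(".yaml", ".yml", ".json")) {
    cand <- paste0(stem, ext)
    if (file.exists(cand)) {
      side <- if (ext == ".json") jsonlite::read_json(cand, simplifyVector = TRUE)
              else yaml::read_yaml(cand)
      return(side)
    }
  }
  NULL
}

#' Write an ergometer trace in the canonical dialect
#'
#' Serializes samples with full precision (17 significant digits) so that a
#' read/write round trip is lossless, plus a YAML sidecar carrying geometry
#' and sample rate.
#'
#' @param trace An [ergo_trace()].
#' @param path Destination file path (\code{.csv}).
#' @param sidecar Write the YAML sidecar too? Default TRUE.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path, sidecar = TRUE) {
  stopifnot(inherits(trace, "ergo_trace"))
  dat <- data.frame(
    time = format_full(trace$time),
    torque_left = format_full(trace$torque_left),
    torque_right = format_full(trace$torque_right),
    velocity_left = format_full(trace$velocity_left),
    velocity_right = format_full(trace$velocity_right)
  )
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    side <- list(wheel_radius = trace$geometry$wheel_radius,
                 rim_radius = trace$geometry$rim_radius,
                 sample_rate = trace$sample_rate)
    yaml::write_yaml(side, paste0(sub("\\.[^.]+$", "", path), ".yaml"))
  }
  invisible(path)
}

format_full <- function(x) formatC(x, format = "g", digits = 17)

#' Read breath-by-breath records
#'
#' Delimited text with header \code{time,vo2,rer,hr}: time (s), oxygen uptake
#' (mL min^-1), respiratory exchange ratio, heart rate (beats min^-1).
#'
#' @param path Path to the file.
#' @return A data frame of validated breath records.
#' @export
read_breaths <- function(path) {
  if (!file.exists(path)) stop("breath file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path)
  breath_records(dat$time, dat$vo2, dat$rer, dat$hr)
}

#' Construct validated breath records
#'
#' @param time Times, s (nondecreasing).
#' @param vo2 Oxygen uptake, mL min^-1 (>= 0).
#' @param rer Respiratory exchange ratio (> 0).
#' @param hr Heart rate, beats min^-1 (> 0).
#' @return Data frame with class \code{breath_records}.
#' @export
breath_records <- function(time, vo2, rer, hr) {
  n <- length(time)
  stopifnot(length(vo2) == n, length(rer) == n, length(hr) == n)
  if (any(vo2 < 0)) stop("vo2 must be >= 0", call. = FALSE)
  if (any(rer <= 0)) stop("rer must be > 0", call. = FALSE)
  if (any(hr <= 0)) stop("hr must be > 0", call. = FALSE)
  if (is.unsorted(time)) stop("breath times must be nondecreasing",
                              call. = FALSE)
  structure(data.frame(time = time, vo2 = vo2, rer = rer, hr = hr),
            class = c("breath_records", "data.frame"))
}

#' Zero-phase Butterworth low-pass filtering of a trace
#'
#' Each torque and velocity channel is replaced by its low-pass filtered
#' version using a Butterworth design applied forward and backward
#' (zero-phase), so peak-location outcomes are not lagged. Odd-reflection
#' padding is used at both ends so constant signals pass through with DC gain
#' exactly 1 and edge transients stay out of the retained region.
#'
#' @param trace An [ergo_trace()].
#' @param cutoff Cutoff frequency, Hz; must be below the Nyquist frequency.
#' @param order Filter order of each pass (default 4).
#' @return A filtered [ergo_trace()] of identical length.
#' @export
filter_trace <- function(trace, cutoff = 10, order = 4) {
  stopifnot(inherits(trace, "ergo_trace"))
  nyq <- trace$sample_rate / 2
  if (cutoff >= nyq) {
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  for (nm in c("torque_left", "torque_right",
               "velocity_left", "velocity_right")) {
    trace[[nm]] <- filtfilt_padded(bf, trace[[nm]])
  }
  trace
}

# Forward-backward filtering with odd-reflection padding; keeps length and
# removes the startup transients signal::filtfilt would leave at the edges.
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1L, 100L)
  if (pad > 0L) {
    head_pad <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
    tail_pad <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    xp <- c(head_pad, x, tail_pad)
  } else {
    xp <- x
  }
  yp <- signal::filtfilt(bf, xp)
  yp[seq(pad + 1L, pad + n)]
}

#' Per-side and combined rim force from torque
#'
#' Effective tangential push force at each rim: F = M / r_r. The combined
#' series is the mean of left and right, the convention used for the isometric
#' strength outcome.
#'
#' @param trace An [ergo_trace()].
#' @return List with numeric vectors \code{left}, \code{right},
#'   \code{combined} (N).
#' @export
force_trace <- function(trace) {
  stopifnot(inherits(trace, "ergo_trace"))
  r_r <- trace$geometry$rim_radius
  if (r_r <= 0) stop("rim radius must be positive", call. = FALSE)
  left <- trace$torque_left / r_r
  right <- trace$torque_right / r_r
  list(left = left, right = right, combined = (left + right) / 2)
}

#' Per-side and summed power from torque and wheel velocity
#'
#' PO = M v_w / r_w per side; total power is the sum of both arms (the
#' convention used for all power outcomes), while the combined velocity used
#' elsewhere is the mean of the sides.
#'
#' @param trace An [ergo_trace()].
#' @return List with numeric vectors \code{left}, \code{right}, \code{total}
#'   (W) and \code{velocity} (mean-side wheel velocity, m s^-1).
#' @export
power_trace <- function(trace) {
  stopifnot(inherits(trace, "ergo_trace"))
  r_w <- trace$geometry$wheel_radius
  if (r_w <= 0) stop("wheel radius must be positive", call. = FALSE)
  left <- trace$torque_left * trace$velocity_left / r_w
  right <- trace$torque_right * trace$velocity_right / r_w
  list(left = left, right = right, total = left + right,
       velocity = (trace$velocity_left + trace$velocity_right) / 2)
}

#' Rolling mean over a time window
#'
#' Arithmetic mean over a sliding window of \code{round(window * sample_rate)}
#' samples (ties round half up). Only fully populated windows are returned, so
#' the result has \code{n - w + 1} values; its \code{"starts"} attribute gives
#' the index of each window's first sample.
#'
#' @param x Numeric series.
#' @param window Window length, s.
#' @param sample_rate Sampling rate of \code{x}, Hz.
#' @return Numeric vector of window means, one per admissible window start.
#' @export
#' @examples
#' rolling_mean(c(0, 0, 1, 1), window = 2, sample_rate = 1)
rolling_mean <- function(x, window, sample_rate) {
  w <- window_samples(window, sample_rate)
  n <- length(x)
  if (w > n) {
    stop("window (", window, " s = ", w, " samples) exceeds series length (",
         n, " samples)", call. = FALSE)
  }
  out <- as.numeric(zoo::rollmean(x, k = w, align = "left"))
  attr(out, "starts") <- seq_len(n - w + 1L)
  attr(out, "width") <- w
  out
}

# Window length in samples; ties round half up for determinism.
window_samples <- function(window, sample_rate) {
  w <- as.integer(floor(window * sample_rate + 0.5))
  if (w < 1L) stop("window must cover at least one sample", call. = FALSE)
  w
}

#' Maximum rolling mean and its window
#'
#' @param x Numeric series.
#' @param window Window length, s.
#' @param sample_rate Sampling rate, Hz.
#' @return List with \code{max}, \code{start} (index of the best window's first
#'   sample) and \code{width} (samples).
#' @export
rolling_max <- function(x, window, sample_rate) {
  rm <- rolling_mean(x, window, sample_rate)
  i <- which.max(rm)
  list(max = rm[i], start = attr(rm, "starts")[i], width = attr(rm, "width"))
}
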