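# Torque-time series processing: container, gravity correction,
# repetition segmentation, interval variability, and the per-set summary
# quantities (peak torque, total work, mean power).
#
# Conventions used throughout the package:
#   * angle: degrees, 0 = full knee extension, increasing into flexion;
#   * torque: newton-meters, knee-extension torque positive, flexion
#     torque negative;
#   * work: torque integrated over angular displacement (radians), so a
#     resisted motion in the working direction accumulates positive work.

#' Construct a torque-time series
#'
#' A `torque_series` is a data frame with one row per dynamometer sample
#' and columns `time_s`, `torque_nm`, `angle_deg`, `velocity_dps`. Time
#' must be strictly increasing; the nominal sample rate (default 100 Hz
#' on the dynamometer used for the protocol) is stored as an attribute
#' and checked against the observed spacing.
#'
#' @param time_s numeric vector, seconds, strictly increasing, non-negative.
#' @param torque_nm numeric vector, newton-meters (extension positive).
#' @param angle_deg numeric vector, degrees (0 = full extension).
#' @param velocity_dps numeric vector, degrees per second (signed). If
#'   `NULL`, a finite-difference estimate from `angle_deg` is used.
#' @param sample_rate nominal sampling rate in Hz. If `NULL`, inferred
#'   from the median sample spacing.
#' @return An object of class `torque_series` (a data frame).
#' @examples
#' t <- seq(0, 1.5, by = 0.01)
#' ts <- torque_series(t, 100 * sin(pi * t / 1.5), 90 * t / 1.5)
#' total_work(ts)
#' @export
torque_series <- function(time_s, torque_nm, angle_deg,
                          velocity_dps = NULL, sample_rate = NULL) {
  n <- length(time_s)
  if (n == 0L) {
    ep_stop("torque series must contain at least one sample", "ep_malformed_input")
  }
  if (length(torque_nm) != n || length(angle_deg) != n) {
    ep_stop("time, torque and angle must have equal length", "ep_malformed_input")
  }
  if (any(!is.finite(time_s)) || any(time_s < 0)) {
    ep_stop("sample times must be finite and non-negative", "ep_malformed_input")
  }
  if (n > 1L && any(diff(time_s) <= 0)) {
    ep_stop("sample times must be strictly increasing", "ep_malformed_input")
  }
  if (is.null(velocity_dps)) {
    velocity_dps <- if (n > 1L) c(diff(angle_deg) / diff(time_s), 0) else 0
  }
  if (is.null(sample_rate)) {
    sample_rate <- if (n > 1L) 1 / stats::median(diff(time_s)) else NA_real_
  }
  if (n > 1L && is.finite(sample_rate)) {
    dt <- diff(time_s)
    if (max(abs(dt - 1 / sample_rate)) > 0.01 / sample_rate + 1e-9) {
      ep_warn("sample spacing deviates from nominal 1/sample_rate by more than 1%",
              "ep_irregular_sampling")
    }
  }
  out <- data.frame(time_s = as.numeric(time_s),
                    torque_nm = as.numeric(torque_nm),
                    angle_deg = as.numeric(angle_deg),
                    velocity_dps = as.numeric(velocity_dps))
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("torque_series", "data.frame")
  out
}

#' @export
print.torque_series <- function(x, ...) {
  cat(sprintf("<torque_series> %d samples, %.3f-%.3f s, nominal %.0f Hz\n",
              nrow(x), x$time_s[1L], x$time_s[nrow(x)],
              attr(x, "sample_rate")))
  cat(sprintf("  peak |torque| %.1f N m, angle range %.1f-%.1f deg\n",
              max(abs(x$torque_nm)), min(x$angle_deg), max(x$angle_deg)))
  invisible(x)
}

#' @export
plot.torque_series <- function(x, ...) {
  graphics::plot(x$time_s, x$torque_nm, type = "l",
                 xlab = "time (s)", ylab = "torque (N m)", ...)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}

#' Limb gravity calibration
#'
#' Stores the gravitational torque of the relaxed limb measured at a
#' reference angle (terminal extension in the protocol), plus the
#' baseline calibration it is compared against. A calibration drifting
#' more than 10% from baseline must be re-measured; [gravity_recheck()]
#' reports that condition and [gravity_correct()] surfaces it as a
#' warning.
#'
#' @param limb_gravity_torque newton-meters, >= 0, measured with the
#'   relaxed limb at `angle_reference`.
#' @param baseline_value newton-meters, the session-baseline calibration
#'   (optional; defaults to `limb_gravity_torque`).
#' @param angle_reference degrees, limb angle at which the calibration
#'   was taken (default 0 = terminal extension).
#' @return An object of class `gravity_calibration`.
#' @export
gravity_calibration <- function(limb_gravity_torque, baseline_value = NULL,
                                angle_reference = 0) {
  if (!is_num1(limb_gravity_torque) || limb_gravity_torque < 0) {
    ep_stop("limb_gravity_torque must be a single non-negative number",
            "ep_invalid_input")
  }
  if (is.null(baseline_value)) baseline_value <- limb_gravity_torque
  if (!is_num1(baseline_value) || baseline_value < 0) {
    ep_stop("baseline_value must be a single non-negative number",
            "ep_invalid_input")
  }
  structure(list(limb_gravity_torque = limb_gravity_torque,
                 baseline_value = baseline_value,
                 angle_reference = angle_reference),
            class = "gravity_calibration")
}

#' Does a gravity calibration need rechecking?
#'
#' @param cal a [gravity_calibration()].
#' @param tolerance relative drift above which recalibration is required
#'   (default 0.10).
#' @return `TRUE` if the current calibration differs from baseline by
#'   more than `tolerance` (relative), `FALSE` otherwise.
#' @export
gravity_recheck <- function(cal, tolerance = 0.10) {
  stopifnot(inherits(cal, "gravity_calibration"))
  if (cal$baseline_value == 0) return(cal$limb_gravity_torque != 0)
  abs(cal$limb_gravity_torque - cal$baseline_value) / cal$baseline_value > tolerance
}

#' Gravity-correct a torque series
#'
#' Adds back the gravitational torque of the limb, modeled from a
#' single-point calibration at `cal$angle_reference` and scaled with the
#' cosine of the angular offset from that reference:
#' `torque + g * cos(angle - angle_reference)`. A zero calibration
#' leaves the series unchanged. If the calibration drifted more than 10%
#' from its baseline, a warning of class `ep_gravity_recheck` is raised
#' (the correction is still applied).
#'
#' @param series a [torque_series()].
#' @param cal a [gravity_calibration()]; missing calibration is an error
#'   of class `ep_uncalibrated`.
#' @return The corrected `torque_series`.
#' @export
gravity_correct <- function(series, cal) {
  stopifnot(inherits(series, "torque_series"))
  if (missing(cal) || is.null(cal)) {
    ep_stop("gravity correction requires a calibration", "ep_uncalibrated")
  }
  if (!inherits(cal, "gravity_calibration")) {
    ep_stop("cal must be a gravity_calibration object", "ep_uncalibrated")
  }
  if (gravity_recheck(cal)) {
    ep_warn(sprintf(
      "gravity calibration drifted %.0f%% from baseline (>10%%): recalibrate",
      100 * abs(cal$limb_gravity_torque - cal$baseline_value) / cal$baseline_value),
      "ep_gravity_recheck")
  }
  g <- cal$limb_gravity_torque * cos(deg2rad(series$angle_deg - cal$angle_reference))
  out <- series
  out$torque_nm <- series$torque_nm + g
  out
}

#' Segment a torque series into repetitions
#'
#' Threshold-crossing segmentation on a lightly smoothed copy of the
#' torque channel: contiguous runs where the smoothed torque exceeds
#' `min_peak_fraction` of its series-wide maximum magnitude become
#' extension segments (positive torque) or flexion segments (negative
#' torque). The moving-average smoothing (default 0.1 s window) keeps
#' broadband sample noise from crossing the threshold between
#' repetitions; peak torque is read from the raw signal within each
#' segment. Same-direction segments whose peaks are closer in time than
#' `min_peak_distance` are merged (the protocol's reciprocal motion
#' cannot produce two genuine peaks that close together).
#'
#' @param series a [torque_series()] with at least one sample.
#' @param min_peak_fraction fraction of the series max absolute torque
#'   a sample must exceed to belong to a repetition (default 0.10,
#'   matching the dynamometer's engagement fraction).
#' @param min_peak_distance seconds; minimum spacing between peaks of
#'   the same direction (default 0.5).
#' @param debounce seconds; same-direction runs separated by a
#'   sub-threshold gap shorter than this are rejoined (default 0.15),
#'   so noise flicker at a burst edge cannot split a repetition.
#' @param min_duration seconds; segments shorter than this after
#'   merging are discarded as impulsive noise (default 0.1 - a genuine
#'   repetition at the protocol's velocities lasts far longer).
#' @param smooth_window seconds; moving-average window used for the
#'   threshold mask (default 0.1; 0 disables smoothing).
#' @return A data frame with one row per segment and columns
#'   `start_index`, `end_index`, `direction` ("extension"/"flexion"),
#'   `peak_torque` (positive magnitude, N m) and `peak_time` (s).
#'   An all-zero (or sub-threshold) series yields zero rows.
#' @export
segment_repetitions <- function(series, min_peak_fraction = 0.10,
                                min_peak_distance = 0.5, debounce = 0.15,
                                min_duration = 0.1, smooth_window = 0.1) {
  stopifnot(inherits(series, "torque_series"))
  if (!is_num1(min_peak_fraction) || min_peak_fraction <= 0 || min_peak_fraction >= 1) {
    ep_stop("min_peak_fraction must lie in (0, 1)", "ep_invalid_input")
  }
  empty <- data.frame(start_index = integer(), end_index = integer(),
                      direction = character(), peak_torque = numeric(),
                      peak_time = numeric(), stringsAsFactors = FALSE)
  tau <- series$torque_nm
  n <- length(tau)
  rate <- attr(series, "sample_rate")
  k <- if (is.finite(rate) && smooth_window > 0)
    max(1L, round(smooth_window * rate)) else 1L
  sm <- if (k > 1L) {
    p <- k %/% 2L
    padded <- c(rep(tau[1L], p), tau, rep(tau[n], p))
    as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2))[(p + 1L):(p + n)]
  } else tau
  sm[is.na(sm)] <- tau[is.na(sm)]
  peak_abs <- max(abs(sm))
  if (peak_abs == 0) return(empty)
  thr <- min_peak_fraction * peak_abs

  runs_for <- function(mask, direction) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) return(empty)
    segs <- lapply(keep, function(j) {
      i0 <- starts[j]; i1 <- ends[j]
      rel <- which.max(abs(sm[i0:i1])) # smoothed argmax: noise-stable
      pk <- i0 + rel - 1L
      data.frame(start_index = i0, end_index = i1, direction = direction,
                 peak_torque = abs(tau[pk]), peak_time = series$time_s[pk],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, segs)
  }

  merge_close <- function(segs) {
    if (nrow(segs) < 2L) return(segs)
    out <- segs[1L, , drop = FALSE]
    for (i in seq_len(nrow(segs))[-1L]) {
      last <- nrow(out)
      gap <- series$time_s[segs$start_index[i]] -
        series$time_s[out$end_index[last]]
      if (gap < debounce ||
          segs$peak_time[i] - out$peak_time[last] < min_peak_distance) {
        out$end_index[last] <- segs$end_index[i]
        if (segs$peak_torque[i] > out$peak_torque[last]) {
          out$peak_torque[last] <- segs$peak_torque[i]
          out$peak_time[last] <- segs$peak_time[i]
        }
      } else {
        out <- rbind(out, segs[i, , drop = FALSE])
      }
    }
    out
  }

  ext <- merge_close(runs_for(sm >= thr, "extension"))
  flx <- merge_close(runs_for(sm <= -thr, "flexion"))
  segs <- rbind(ext, flx)
  if (!nrow(segs)) return(empty)
  dur <- series$time_s[segs$end_index] - series$time_s[segs$start_index]
  segs <- segs[dur >= min_duration, , drop = FALSE]
  if (!nrow(segs)) return(empty)
  segs <- segs[order(segs$start_index), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Summary statistics of repetition intervals
#'
#' The repetition interval is the time between the peak-torque instants
#' of consecutive knee-extension repetitions; its coefficient of
#' variation is the motor-performance variability measure tracked
#' across the familiarization phase. SD uses the sample (n-1)
#' denominator; `cv_percent = 100 * sd / mean` is kept at full precision
#' (the print method rounds to whole percent for display).
#'
#' @param segments a segment data frame from [segment_repetitions()],
#'   or a numeric vector of intervals in seconds (used directly).
#' @param direction which movement direction defines a repetition
#'   (default "extension").
#' @return An object of class `repetition_stats`: a list with
#'   `intervals`, `mean_interval`, `sd_interval`, `cv_percent`,
#'   `n_repetitions`.
#' @export
repetition_interval_stats <- function(segments, direction = "extension") {
  if (is.numeric(segments)) {
    intervals <- as.numeric(segments)
    n_rep <- length(intervals) + 1L
  } else {
    ext <- segments[segments$direction == direction, , drop = FALSE]
    if (nrow(ext) < 2L) {
      ep_stop("need at least 2 repetitions to compute intervals",
              "ep_insufficient_data")
    }
    intervals <- diff(sort(ext$peak_time))
    n_rep <- nrow(ext)
  }
  if (length(intervals) < 1L) {
    ep_stop("need at least 2 repetitions to compute intervals",
            "ep_insufficient_data")
  }
  m <- mean(intervals)
  s <- if (length(intervals) > 1L) stats::sd(intervals) else 0
  cv <- if (m > 0) 100 * s / m else NA_real_
  structure(list(intervals = intervals, mean_interval = m, sd_interval = s,
                 cv_percent = cv, n_repetitions = n_rep),
            class = "repetition_stats")
}

#' @export
print.repetition_stats <- function(x, ...) {
  cat(sprintf("repetition intervals: n = %d, mean %.2f s, SD %.2f s, CV = %.0f%%\n",
              length(x$intervals), x$mean_interval, x$sd_interval, x$cv_percent))
  invisible(x)
}

#' Per-session interval variability with selectable pooling
#'
#' The protocol's variability figures were taken from the intra-session
#' set with the lowest variability; some users prefer pooling all
#' within-set intervals. Both modes are exposed.
#'
#' @param segment_list list of segment data frames, one per exercise set.
#' @param pooling `"best_set"` (minimum-CV set, the protocol's choice) or
#'   `"pooled"` (all within-set intervals combined).
#' @return A `repetition_stats` object.
#' @export
session_interval_stats <- function(segment_list,
                                   pooling = c("best_set", "pooled")) {
  pooling <- match.arg(pooling)
  per_set <- lapply(segment_list, function(s) {
    tryCatch(repetition_interval_stats(s), error = function(e) NULL)
  })
  per_set <- Filter(Negate(is.null), per_set)
  if (!length(per_set)) {
    ep_stop("no set has >= 2 repetitions", "ep_insufficient_data")
  }
  if (pooling == "best_set") {
    per_set[[which.min(vapply(per_set, `[[`, numeric(1), "cv_percent"))]]
  } else {
    repetition_interval_stats(unlist(lapply(per_set, `[[`, "intervals")))
  }
}

#' Peak torque from a five-repetition strength test
#'
#' The protocol's criterion strength measure: the arithmetic mean of the
#' three highest peak-torque values from a five-repetition maximal test.
#'
#' @param peaks numeric vector of exactly 5 positive peak torques (N m).
#' @return Mean of the three largest values (N m).
#' @examples
#' peak_torque_five_rep(c(100, 110, 120, 90, 95)) # 110
#' @export
peak_torque_five_rep <- function(peaks) {
  if (!is.numeric(peaks) || length(peaks) != 5L) {
    ep_stop("strength-test protocol requires exactly 5 peak torque values",
            "ep_invalid_protocol")
  }
  if (any(!is.finite(peaks)) || any(peaks <= 0)) {
    ep_stop("peak torque values must be positive", "ep_invalid_protocol")
  }
  mean(sort(peaks, decreasing = TRUE)[1:3])
}

#' Total work from a torque series
#'
#' Work is torque integrated over angular displacement, `W = integral of
#' tau d(theta)` with theta in radians, evaluated with the trapezoidal
#' rule over samples. With the package's sign conventions (extension
#' torque positive / angle increasing into flexion during eccentric
#' extension, and the mirror for flexion) resisted motion accumulates
#' positive work in both directions, so the combined value is the total
#' mechanical work of the set.
#'
#' @param series a [torque_series()] with at least 2 samples.
#' @param by_direction if `TRUE`, return a named vector with the
#'   extension, flexion, and combined contributions.
#' @return Joules (scalar, or named length-3 vector).
#' @examples
#' t <- seq(0, 1.5, by = 0.01)
#' ts <- torque_series(t, rep(100, length(t)), seq(0, 90, length.out = length(t)))
#' total_work(ts) # 100 * pi/2 = 157.08 J
#' @export
total_work <- function(series, by_direction = FALSE) {
  stopifnot(inherits(series, "torque_series"))
  n <- nrow(series)
  if (n < 2L) {
    ep_stop("total work requires at least 2 samples", "ep_insufficient_data")
  }
  tau_mid <- (series$torque_nm[-1L] + series$torque_nm[-n]) / 2
  dth <- deg2rad(diff(series$angle_deg))
  w <- tau_mid * dth
  ext <- sum(w[tau_mid >= 0])
  flx <- sum(w[tau_mid < 0])
  if (by_direction) {
    c(extension = ext, flexion = flx, combined = ext + flx)
  } else {
    ext + flx
  }
}

#' Mean power
#'
#' Work divided by active movement time. For constant torque at constant
#' angular velocity this equals `tau * omega` (omega in rad/s), so at a
#' fixed torque profile mean power scales exactly with the velocity
#' ratio.
#'
#' @param work joules.
#' @param active_duration seconds of active motion, > 0.
#' @return Watts.
#' @examples
#' mean_power(157.08, 1.5) # 104.72 W: 100 N m over 90 deg at 60 deg/s
#' @export
mean_power <- function(work, active_duration) {
  if (!is_num1(active_duration) || active_duration <= 0) {
    ep_stop("active_duration must be a positive number", "ep_invalid_input")
  }
  if (!is_num1(work)) ep_stop("work must be a single number", "ep_invalid_input")
  work / active_duration
}
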