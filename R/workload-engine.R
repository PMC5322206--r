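# The exercise-prescription rule engine: eccentric peak-torque
# estimation, visual torque-target bands, intra-session fatigue
# classification, the +/-5% workload-adjustment rule, the dynamometer
# safety limit / engagement threshold, and the pain stoppage criterion.

#' Estimate eccentric peak torque from a concentric test
#'
#' Initial workload assignment: the eccentric peak torque of untrained
#' individuals is estimated as a fixed multiple of the measured
#' concentric peak torque. The default cofactor of 1.35 is a deliberately
#' conservative value for clinical populations (eccentric strength
#' typically runs some 20-100% above concentric).
#'
#' @param concentric_peak newton-meters, >= 0.
#' @param cofactor eccentric/concentric ratio (default 1.35).
#' @return Estimated eccentric peak torque (N m).
#' @examples
#' estimate_ecc_peak_torque(200) # 270
#' @export
estimate_ecc_peak_torque <- function(concentric_peak, cofactor = 1.35) {
  if (!is.numeric(concentric_peak) || any(!is.finite(concentric_peak)) ||
      any(concentric_peak < 0)) {
    ep_stop("concentric peak torque must be non-negative", "ep_invalid_input")
  }
  if (!is_num1(cofactor) || cofactor <= 0) {
    ep_stop("cofactor must be a positive number", "ep_invalid_input")
  }
  concentric_peak * cofactor
}

#' Engagement threshold of the reactive eccentric mode
#'
#' The dynamometer's reactive eccentric mode only drives the limb while
#' the participant exerts at least 10% of the assigned torque limit.
#'
#' @param limit torque limit in N m, > 0.
#' @return Threshold torque (N m), `0.10 * limit`.
#' @examples
#' engagement_threshold(225) # 22.5
#' @export
engagement_threshold <- function(limit) {
  if (!is.numeric(limit) || any(!is.finite(limit)) || any(limit <= 0)) {
    ep_stop("torque limit must be positive", "ep_invalid_input")
  }
  0.10 * limit
}

#' Workload target for one session
#'
#' Bundles the prescribed target torque with the angular velocity, the
#' dynamometer safety torque limit (at most 50 N m above the target, so
#' the safety mechanism does not impede performance within acceptable
#' workload bands), and the derived engagement threshold.
#'
#' @param target_torque prescribed workload (N m), > 0.
#' @param velocity angular velocity (deg/s), default 60.
#' @param percent_of_ecc_peak the target as percent of estimated
#'   eccentric peak torque (informational).
#' @param torque_limit safety limit (N m); default `target_torque +
#'   headroom`. Must satisfy `target <= limit <= target + 50`.
#' @param headroom N m above target used for the default limit
#'   (default 50, the maximum).
#' @return An object of class `workload_target`.
#' @export
workload_target <- function(target_torque, velocity = 60,
                            percent_of_ecc_peak = NA_real_,
                            torque_limit = NULL, headroom = 50) {
  if (!is_num1(target_torque) || target_torque <= 0) {
    ep_stop("target torque must be positive", "ep_invalid_input")
  }
  if (!is_num1(headroom) || headroom < 0 || headroom > 50) {
    ep_stop("safety headroom must lie in [0, 50] N m", "ep_invalid_input")
  }
  if (is.null(torque_limit)) torque_limit <- target_torque + headroom
  if (!is_num1(torque_limit) || torque_limit < target_torque ||
      torque_limit > target_torque + 50) {
    ep_stop("torque limit must lie between target and target + 50 N m",
            "ep_invalid_input")
  }
  structure(list(target_torque = target_torque,
                 percent_of_ecc_peak = percent_of_ecc_peak,
                 velocity = velocity,
                 torque_limit = torque_limit,
                 engagement_threshold = engagement_threshold(torque_limit)),
            class = "workload_target")
}

#' @export
print.workload_target <- function(x, ...) {
  cat(sprintf("<workload_target> %.1f N m at %g deg/s (limit %.1f, engage >= %.1f N m)\n",
              x$target_torque, x$velocity, x$torque_limit, x$engagement_threshold))
  invisible(x)
}

#' Visual torque-target compliance bands
#'
#' Line A is the designated workload, line B the lower-bound 10%
#' tolerance for acceptable repetition peak torque, and line C marks
#' peaks falling 25% below the workload (the fatigue criterion line).
#'
#' @param target designated workload (N m), > 0.
#' @return An object of class `compliance_bands` with `line_a`,
#'   `line_b` (0.90 target), `line_c` (0.75 target).
#' @examples
#' make_bands(200) # 200 / 180 / 150
#' @export
make_bands <- function(target) {
  if (!is_num1(target) || target <= 0) {
    ep_stop("band target must be positive", "ep_invalid_input")
  }
  structure(list(line_a = target, line_b = 0.90 * target, line_c = 0.75 * target),
            class = "compliance_bands")
}

#' Classify intra-session fatigue from repetition peaks
#'
#' Decision criteria, applied per set over the repetition peak torques:
#' \itemize{
#'   \item \strong{excessive} - any run of at least 3 consecutive
#'     (cued) repetition peaks strictly below line C (more than 25%
#'     below target for more than 2 consecutive repetitions);
#'   \item \strong{moderate} - otherwise, any repetition peak strictly
#'     below line B (a 10-25% decline);
#'   \item \strong{compliant} - all peaks at or above line B (absent or
#'     minimal, <10%, decline).
#' }
#' Peaks exactly on a band line take the better class, matching the
#' strict ">" wording of the criteria. Verbal cueing is modeled as an
#' optional per-repetition flag: only cued repetitions can contribute to
#' an excessive run (default: all cued).
#'
#' @param rep_peaks_per_set list of numeric vectors, one per set, of
#'   per-repetition peak torques (N m).
#' @param bands a [make_bands()] object.
#' @param cued optional list matching `rep_peaks_per_set` of logical
#'   vectors marking repetitions performed after verbal cueing.
#' @param excessive_run run length defining excessive fatigue
#'   (default 3 = "more than 2 consecutive").
#' @return One of `"compliant"`, `"moderate"`, `"excessive"`.
#' @export
classify_session <- function(rep_peaks_per_set, bands, cued = NULL,
                             excessive_run = 3L) {
  stopifnot(inherits(bands, "compliance_bands"))
  if (!is.list(rep_peaks_per_set) || !length(rep_peaks_per_set) ||
      !all(vapply(rep_peaks_per_set, function(p) is.numeric(p) && length(p) > 0,
                  logical(1)))) {
    ep_stop("need at least one set with at least one repetition peak",
            "ep_insufficient_data")
  }
  if (is.null(cued)) {
    cued <- lapply(rep_peaks_per_set, function(p) rep(TRUE, length(p)))
  }
  any_moderate <- FALSE
  for (i in seq_along(rep_peaks_per_set)) {
    p <- rep_peaks_per_set[[i]]
    ck <- cued[[i]]
    below_c <- (p < bands$line_c) & ck
    r <- rle(below_c)
    if (any(r$values & r$lengths >= excessive_run)) return("excessive")
    if (any(p < bands$line_b)) any_moderate <- TRUE
  }
  if (any_moderate) "moderate" else "compliant"
}

#' Workload adjustment for the next session
#'
#' The progression rule applied after each exercise session from the
#' first incremental slot of the plan onward: a compliant session earns
#' a 5% increase in the target workload, moderate fatigue holds the
#' workload stable, and excessive fatigue reduces it by 5%. The default
#' mode compounds multiplicatively on the current target; an additive
#' mode stepping by 5 percentage points of the estimated eccentric peak
#' is available. The next target is rounded to the nearest 0.1 N m.
#'
#' @param current current target: a [workload_target()] or a torque in N m.
#' @param cls fatigue class from [classify_session()].
#' @param mode `"multiplicative"` (default) or `"additive_points"`.
#' @param ecc_peak estimated eccentric peak torque (N m); required for
#'   the additive mode.
#' @return An object of class `adjustment_decision`: list with
#'   `multiplier` (1.05 / 1.00 / 0.95), `rationale` (the class),
#'   `current_target_torque`, `next_target_torque`.
#' @examples
#' adjust_workload(100, "compliant")$next_target_torque # 105
#' @export
adjust_workload <- function(current, cls,
                            mode = c("multiplicative", "additive_points"),
                            ecc_peak = NULL) {
  mode <- match.arg(mode)
  tgt <- if (inherits(current, "workload_target")) current$target_torque else current
  if (!is_num1(tgt) || tgt <= 0) {
    ep_stop("current target torque must be positive", "ep_invalid_input")
  }
  cls <- match.arg(cls, c("compliant", "moderate", "excessive"))
  mult <- c(compliant = 1.05, moderate = 1.00, excessive = 0.95)[[cls]]
  nxt <- if (mode == "multiplicative") {
    mult * tgt
  } else {
    if (!is_num1(ecc_peak) || ecc_peak <= 0) {
      ep_stop("additive_points mode requires ecc_peak", "ep_invalid_input")
    }
    tgt + (mult - 1) * ecc_peak
  }
  structure(list(multiplier = mult, rationale = cls,
                 current_target_torque = tgt,
                 next_target_torque = round(nxt, 1)),
            class = "adjustment_decision")
}

#' @export
print.adjustment_decision <- function(x, ...) {
  cat(sprintf("<adjustment_decision> %s: x%.2f, %.1f -> %.1f N m\n",
              x$rationale, x$multiplier, x$current_target_torque,
              x$next_target_torque))
  invisible(x)
}

#' Pain-based exercise stoppage check
#'
#' Exercise stops outright when the pre-session visual analog scale
#' (VAS, 0-10) pain score exceeds 8. A large rise over the participant's
#' baseline that stays at or below 8 is flagged for clinician review
#' (a large proportional increase over a low baseline may still merit
#' cessation); the flag delta is configurable.
#'
#' @param vas current VAS score in \[0, 10\].
#' @param baseline_vas baseline VAS score in \[0, 10\].
#' @param flag_delta rise over baseline that triggers a review flag
#'   (default 4).
#' @return One of `"stop"`, `"flag"`, `"continue"`.
#' @examples
#' stoppage_check(9, 3) # "stop"
#' stoppage_check(7, 1) # "flag"
#' @export
stoppage_check <- function(vas, baseline_vas, flag_delta = 4) {
  if (!is_num1(vas) || vas < 0 || vas > 10 ||
      !is_num1(baseline_vas) || baseline_vas < 0 || baseline_vas > 10) {
    ep_stop("VAS scores must lie in [0, 10]", "ep_invalid_input")
  }
  if (vas > 8) return("stop")
  if (vas - baseline_vas >= flag_delta) return("flag")
  "continue"
}
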