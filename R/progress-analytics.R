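# Progression analytics: indexing of the per-session total-work series,
# rolling OLS slope windows over consecutive microcycles, plateau and
# decline detection, and the velocity-condition comparison.

#' Validate / construct a progress ledger
#'
#' A progress ledger is a data frame with one row per session, ordered,
#' with at least `session_id` and `total_work_j`; the closed-loop
#' simulator and the CSV reader also fill `microcycle`, `phase`,
#' `peak_torque_nm`, `mean_power_w`, `velocity_mix`, `target_percent`,
#' `vas`.
#'
#' @param df a data frame of session records.
#' @return The data frame with class `progress_ledger` prepended.
#' @export
progress_ledger <- function(df) {
  if (!is.data.frame(df)) ep_stop("ledger must be a data frame", "ep_invalid_input")
  need <- c("session_id", "total_work_j")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    ep_stop(paste("ledger missing column(s):", paste(miss, collapse = ", ")),
            "ep_invalid_input")
  }
  if (anyDuplicated(df$session_id)) {
    ep_stop("duplicate session ids in ledger", "ep_integrity_error")
  }
  if (!inherits(df, "progress_ledger")) class(df) <- c("progress_ledger", class(df))
  df
}

#' Index a total-work series to a baseline session
#'
#' Expresses each session's total work as a percentage of the work
#' attained at the baseline session (the start of the 5% workload
#' increments in the protocol), so the baseline session reads 100%.
#'
#' @param ledger a [progress_ledger()] (or data frame with
#'   `session_id`, `total_work_j`).
#' @param baseline session id to index against (default: first row).
#' @return An object of class `indexed_series`: data frame with
#'   `session_id` and `value` (percent of baseline), with the baseline
#'   id stored as an attribute.
#' @examples
#' led <- data.frame(session_id = c("P1", "P2"), total_work_j = c(200, 570))
#' index_total_work(led, "P1")$value # 100, 285
#' @export
index_total_work <- function(ledger, baseline = NULL) {
  ledger <- progress_ledger(as.data.frame(ledger))
  if (is.null(baseline)) baseline <- ledger$session_id[1L]
  i <- match(baseline, ledger$session_id)
  if (is.na(i)) ep_stop("baseline session not found in ledger", "ep_invalid_baseline")
  w0 <- ledger$total_work_j[i]
  if (!is.finite(w0) || w0 <= 0) {
    ep_stop("baseline total work must be positive", "ep_invalid_baseline")
  }
  out <- data.frame(session_id = ledger$session_id,
                    value = 100 * ledger$total_work_j / w0)
  attr(out, "baseline_session") <- baseline
  class(out) <- c("indexed_series", "data.frame")
  out
}

#' Rolling slope windows over an indexed work series
#'
#' Ordinary least-squares slopes of the indexed total-work values over
#' sliding windows of `window` sessions (default 4 = two consecutive
#' microcycles), advanced by `step` sessions (default 2 = one
#' microcycle, giving the serial overlapping analysis). Within each
#' window the regressor is the session ordinal 1..window, so slopes are
#' in indexed-percent per session. Labels: `decline` if slope < 0,
#' `plateau` if 0 <= slope < `plateau_threshold`, else `progressing`.
#'
#' @param series an [index_total_work()] result, or a numeric vector of
#'   indexed values.
#' @param window sessions per window (default 4).
#' @param step sessions between window starts (default 2).
#' @param plateau_threshold slope (indexed-%/session) below which a
#'   non-negative window counts as a plateau (default 10).
#' @return An object of class `slope_windows`: data frame with
#'   `window`, `start_session`, `end_session`, `slope`, `label`.
#' @export
rolling_slopes <- function(series, window = 4L, step = 2L,
                           plateau_threshold = 10) {
  if (inherits(series, "indexed_series")) {
    vals <- series$value
    ids <- series$session_id
  } else {
    vals <- as.numeric(series)
    ids <- as.character(seq_along(vals))
  }
  n <- length(vals)
  if (n < window) {
    ep_stop("series shorter than one slope window", "ep_insufficient_data")
  }
  starts <- seq(1L, n - window + 1L, by = step)
  x <- seq_len(window)
  slopes <- vapply(starts, function(i) {
    unname(stats::coef(stats::lm(vals[i:(i + window - 1L)] ~ x))[2L])
  }, numeric(1))
  label <- ifelse(slopes < 0, "decline",
                  ifelse(slopes < plateau_threshold, "plateau", "progressing"))
  out <- data.frame(window = seq_along(starts),
                    start_session = ids[starts],
                    end_session = ids[starts + window - 1L],
                    slope = slopes, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "plateau_threshold") <- plateau_threshold
  class(out) <- c("slope_windows", "data.frame")
  out
}

#' Detect training plateaus and declines from slope windows
#'
#' A plateau span is a maximal run of at least `min_run` consecutive
#' windows whose slope is non-negative but below the plateau threshold
#' (consecutive slope values < 10 indicate a training plateau); any
#' window with a negative slope marks a period of decreased exercise
#' capacity.
#'
#' @param slopes a [rolling_slopes()] result.
#' @param min_run consecutive sub-threshold windows required for a
#'   plateau span (default 2).
#' @return An object of class `progress_events`: list with `plateaus`
#'   (data frame `start_window`, `end_window`) and `declines` (data
#'   frame `window`, `slope`).
#' @export
detect_events <- function(slopes, min_run = 2L) {
  stopifnot(inherits(slopes, "slope_windows"))
  if (!nrow(slopes)) ep_stop("need at least one slope window", "ep_insufficient_data")
  flat <- slopes$label == "plateau"
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  plateaus <- data.frame(start_window = starts[keep], end_window = ends[keep])
  dec <- which(slopes$slope < 0)
  declines <- data.frame(window = dec, slope = slopes$slope[dec])
  structure(list(plateaus = plateaus, declines = declines),
            class = "progress_events")
}

#' @export
print.progress_events <- function(x, ...) {
  if (nrow(x$plateaus)) {
    for (i in seq_len(nrow(x$plateaus))) {
      cat(sprintf("plateau: windows %d-%d\n", x$plateaus$start_window[i],
                  x$plateaus$end_window[i]))
    }
  }
  if (nrow(x$declines)) {
    for (i in seq_len(nrow(x$declines))) {
      cat(sprintf("decline: window %d (slope %.2f)\n", x$declines$window[i],
                  x$declines$slope[i]))
    }
  }
  if (!nrow(x$plateaus) && !nrow(x$declines)) cat("no plateau or decline detected\n")
  invisible(x)
}

#' Compare muscle performance across angular-velocity conditions
#'
#' For paired observations at 60 and 90 deg/s under the same torque
#' target, computes each pair's percent change in peak torque and mean
#' power relative to its own 60 deg/s value (the 60 deg/s condition is
#' 100%). The summary is the mean of the per-pair percent changes -
#' each participant indexed to their own reference - with the percent
#' change of the group means also reported for comparison.
#'
#' @param data data frame with columns `pair_id`, `velocity` (60 or
#'   90), `peak_torque_nm`, `mean_power_w`; exactly one row per pair
#'   and velocity.
#' @return An object of class `velocity_comparison`: list with `pairs`
#'   (per-pair percent changes), `mean_torque_delta_percent`,
#'   `mean_power_delta_percent`, `torque_delta_of_means`,
#'   `power_delta_of_means`.
#' @export
velocity_condition_comparison <- function(data) {
  need <- c("pair_id", "velocity", "peak_torque_nm", "mean_power_w")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    ep_stop(paste("missing column(s):", paste(miss, collapse = ", ")),
            "ep_pairing_failure")
  }
  lo <- data[data$velocity == 60, , drop = FALSE]
  hi <- data[data$velocity == 90, , drop = FALSE]
  ids <- sort(unique(data$pair_id))
  if (anyDuplicated(lo$pair_id) || anyDuplicated(hi$pair_id) ||
      !setequal(lo$pair_id, ids) || !setequal(hi$pair_id, ids)) {
    ep_stop("each pair_id needs exactly one 60 and one 90 deg/s row",
            "ep_pairing_failure")
  }
  lo <- lo[match(ids, lo$pair_id), ]
  hi <- hi[match(ids, hi$pair_id), ]
  pairs <- data.frame(
    pair_id = ids,
    torque_delta_percent = 100 * (hi$peak_torque_nm / lo$peak_torque_nm - 1),
    power_delta_percent = 100 * (hi$mean_power_w / lo$mean_power_w - 1))
  structure(list(
    pairs = pairs,
    mean_torque_delta_percent = mean(pairs$torque_delta_percent),
    mean_power_delta_percent = mean(pairs$power_delta_percent),
    torque_delta_of_means = 100 * (mean(hi$peak_torque_nm) / mean(lo$peak_torque_nm) - 1),
    power_delta_of_means = 100 * (mean(hi$mean_power_w) / mean(lo$mean_power_w) - 1)),
    class = "velocity_comparison")
}

#' @export
print.velocity_comparison <- function(x, ...) {
  cat(sprintf("90 vs 60 deg/s (n = %d pairs): peak torque %+.1f%%, mean power %+.1f%%\n",
              nrow(x$pairs), x$mean_torque_delta_percent, x$mean_power_delta_percent))
  cat(sprintf("  (percent change of means: torque %+.1f%%, power %+.1f%%)\n",
              x$torque_delta_of_means, x$power_delta_of_means))
  invisible(x)
}

#' Full progression analysis of a session ledger
#'
#' Convenience wrapper chaining [index_total_work()],
#' [rolling_slopes()] and [detect_events()] over a ledger, restricted
#' by default to the progression-phase sessions when a `phase` column
#' is present.
#'
#' @param ledger a [progress_ledger()] or compatible data frame.
#' @param baseline baseline session id (default: first progression
#'   session, or first row).
#' @param window,step,plateau_threshold passed to [rolling_slopes()].
#' @return An object of class `ecc_progression`: list with `ledger`,
#'   `indexed`, `slopes`, `events`, `baseline`.
#' @export
progression_analysis <- function(ledger, baseline = NULL, window = 4L,
                                 step = 2L, plateau_threshold = 10) {
  ledger <- progress_ledger(as.data.frame(ledger))
  sub <- if ("phase" %in% names(ledger) && any(ledger$phase == "progression")) {
    ledger[ledger$phase == "progression", , drop = FALSE]
  } else ledger
  indexed <- index_total_work(sub, baseline)
  slopes <- rolling_slopes(indexed, window = window, step = step,
                           plateau_threshold = plateau_threshold)
  events <- detect_events(slopes)
  structure(list(ledger = ledger, indexed = indexed, slopes = slopes,
                 events = events,
                 baseline = attr(indexed, "baseline_session")),
            class = "ecc_progression")
}

#' @export
print.ecc_progression <- function(x, ...) {
  n <- nrow(x$indexed)
  cat(sprintf("<ecc_progression> %d sessions indexed to %s: %.0f%% -> %.0f%%\n",
              n, x$baseline, x$indexed$value[1L], x$indexed$value[n]))
  cat(sprintf("  slope windows: %d (range %.1f to %.1f indexed-%%/session)\n",
              nrow(x$slopes), min(x$slopes$slope), max(x$slopes$slope)))
  print(x$events)
  invisible(x)
}

#' @export
summary.ecc_progression <- function(object, ...) {
  s <- object$slopes$slope
  cat(sprintf("indexed total work: start %.0f%%, end %.0f%% (increase %.0f%%)\n",
              object$indexed$value[1L], object$indexed$value[nrow(object$indexed)],
              object$indexed$value[nrow(object$indexed)] - object$indexed$value[1L]))
  cat(sprintf("slopes: mean %.1f, SD %.1f, range %.1f to %.1f\n",
              mean(s), stats::sd(s), min(s), max(s)))
  cat(sprintf("plateau spans: %d; decline windows: %d\n",
              nrow(object$events$plateaus), nrow(object$events$declines)))
  invisible(object)
}

#' @export
plot.ecc_progression <- function(x, ...) {
  n <- nrow(x$indexed)
  graphics::plot(seq_len(n), x$indexed$value, type = "b", pch = 16,
                 xlab = "progression session", ylab = "total work (% of baseline)",
                 ...)
  graphics::abline(h = 100, col = "grey70", lty = 2)
  if (nrow(x$events$declines)) {
    # mark sessions starting a declining window
    w <- x$events$declines$window
    starts <- match(x$slopes$start_session[w], x$indexed$session_id)
    graphics::points(starts, x$indexed$value[starts], col = "red", pch = 4, cex = 1.5)
  }
  invisible(x)
}
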