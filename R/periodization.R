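# Macrocycle construction and scheduling: the initial 12-microcycle
# plan, the revised 14-microcycle plan with active-recovery periods,
# calendar scheduling of two weekly sessions, and the plan-state
# machine that issues per-session prescriptions (fixed targets for
# microcycles 1-4, the +/-5% adjustment chain thereafter).
#
# A microcycle is one week holding two non-consecutive training
# sessions. Set notation such as "60 deg/s, 3 x 10" means 3 sets of 10
# repetitions at 60 deg/s; mixed microcycles order the slower sets
# first.

new_microcycle <- function(index, phase, mesocycle, sets, target_mode,
                           target_percent = NA_real_) {
  list(index = index, phase = phase, mesocycle = mesocycle,
       sets = sets, target_mode = target_mode, target_percent = target_percent)
}

set_block <- function(velocity, sets, reps = 10L, rest_after = 60) {
  data.frame(velocity_dps = velocity, sets = as.integer(sets),
             reps = as.integer(reps), rest_after_s = rest_after)
}

default_plan_config <- function(config = list()) {
  cfg <- list(sessions_per_week = 2L, min_rest_days = 1L,
              familiarization_targets = c(40, 50),
              recovery_policy = "light")
  cfg[names(config)] <- config
  if (!is.numeric(cfg$sessions_per_week) || cfg$sessions_per_week < 1) {
    ep_stop("sessions_per_week must be >= 1", "ep_invalid_config")
  }
  if (!is.numeric(cfg$min_rest_days) || cfg$min_rest_days < 0) {
    ep_stop("min_rest_days must be >= 0", "ep_invalid_config")
  }
  if (!is.numeric(cfg$familiarization_targets) ||
      length(cfg$familiarization_targets) != 2L ||
      any(cfg$familiarization_targets <= 0)) {
    ep_stop("familiarization_targets must be two positive percentages",
            "ep_invalid_config")
  }
  if (!cfg$recovery_policy %in% c("light", "rest")) {
    ep_stop("recovery_policy must be 'light' or 'rest'", "ep_invalid_config")
  }
  cfg
}

#' Build the initial eccentric training macrocycle
#'
#' Twelve weekly microcycles, two sessions each (24 training sessions):
#' a familiarization week at 45 deg/s and a low 40-50% target, two
#' acclimatization weeks at 60 deg/s (50%, 60%), then the progression
#' phase from microcycle 4 (fixed 70% target) with per-session +/-5%
#' workload adjustment from microcycle 5 onward. Volume rises from
#' 3 x 10 to 4 x 10 at microcycle 6; movement velocity transitions from
#' 60 to 90 deg/s across microcycles 7-9 (mixed 3+1, 2+2, 1+3 sets,
#' slower sets first) and the final three microcycles are all at
#' 90 deg/s. Mesocycle 1 is microcycles 1-3; mesocycle 2 the rest.
#'
#' All targets are percentages of the estimated eccentric peak torque.
#'
#' @param config optional named list overriding `sessions_per_week`
#'   (2), `min_rest_days` (1), `familiarization_targets` (c(40, 50)),
#'   `recovery_policy` ("light" or "rest"; only relevant after recovery
#'   insertion).
#' @return An object of class `ecc_plan`.
#' @examples
#' plan <- build_initial_macrocycle()
#' length(plan$microcycles) # 12
#' @export
build_initial_macrocycle <- function(config = list()) {
  cfg <- default_plan_config(config)
  m <- list(
    new_microcycle(1L, "familiarization", "1", set_block(45, 3),
                   "fixed", cfg$familiarization_targets),
    new_microcycle(2L, "acclimatization", "1", set_block(60, 3), "fixed", 50),
    new_microcycle(3L, "acclimatization", "1", set_block(60, 3), "fixed", 60),
    new_microcycle(4L, "progression", "2", set_block(60, 3), "fixed", 70),
    new_microcycle(5L, "progression", "2", set_block(60, 3), "adjust"),
    new_microcycle(6L, "progression", "2", set_block(60, 4), "adjust"),
    new_microcycle(7L, "progression", "2",
                   rbind(set_block(60, 3), set_block(90, 1)), "adjust"),
    new_microcycle(8L, "progression", "2",
                   rbind(set_block(60, 2), set_block(90, 2)), "adjust"),
    new_microcycle(9L, "progression", "2",
                   rbind(set_block(60, 1), set_block(90, 3)), "adjust"),
    new_microcycle(10L, "progression", "2", set_block(90, 4), "adjust"),
    new_microcycle(11L, "progression", "2", set_block(90, 4), "adjust"),
    new_microcycle(12L, "progression", "2", set_block(90, 4), "adjust")
  )
  structure(list(model = "initial", microcycles = m,
                 sessions_per_week = as.integer(cfg$sessions_per_week),
                 min_rest_days = as.integer(cfg$min_rest_days),
                 recovery_policy = cfg$recovery_policy,
                 familiarization_targets = cfg$familiarization_targets),
            class = "ecc_plan")
}

#' Insert active-recovery periods into a training plan
#'
#' Revises an initial-style plan by inserting an active-recovery
#' microcycle after each block of progression-phase microcycles. The
#' progression phase is partitioned into blocks of `block_length`
#' (default 4) consecutive microcycles, with any remainder shorter than
#' a block absorbed into the final block; a recovery microcycle follows
#' each block. Applied to the default initial plan (9 progression
#' microcycles) this yields blocks 4-7 and 8-12 and hence recovery at
#' positions 8 and 14 - the revised macrocycle topology. The operation
#' is idempotent: a plan already containing recovery microcycles is
#' returned unchanged, as is a plan with no progression microcycles.
#'
#' @param plan an `ecc_plan`.
#' @param events optional [detect_events()] report; informational (the
#'   placement rule itself is structural - see the methods vignette).
#' @param block_length progressive microcycles per loading block
#'   (default 4).
#' @return A revised `ecc_plan`.
#' @export
recommend_recovery <- function(plan, events = NULL, block_length = 4L) {
  stopifnot(inherits(plan, "ecc_plan"))
  phases <- vapply(plan$microcycles, `[[`, character(1), "phase")
  if (any(phases == "active_recovery")) return(plan)
  prog <- which(phases == "progression")
  if (!length(prog)) return(plan)

  n <- length(prog)
  n_blocks <- max(1L, n %/% block_length)
  sizes <- rep(block_length, n_blocks)
  sizes[n_blocks] <- n - block_length * (n_blocks - 1L)
  block_ends <- prog[cumsum(sizes)]

  out <- list()
  meso_prog <- 0L
  for (i in seq_along(plan$microcycles)) {
    mc <- plan$microcycles[[i]]
    if (mc$phase == "progression" && i == prog[1L]) meso_prog <- 1L
    if (mc$phase == "progression") {
      mc$mesocycle <- if (n_blocks > 1L) paste0("2", LETTERS[meso_prog]) else "2"
    }
    out[[length(out) + 1L]] <- mc
    if (i %in% block_ends) {
      out[[length(out) + 1L]] <- new_microcycle(
        NA_integer_, "active_recovery",
        if (n_blocks > 1L) paste0("2", LETTERS[meso_prog]) else "2",
        set_block(60, 2), "recovery")
      meso_prog <- meso_prog + 1L
    }
  }
  for (i in seq_along(out)) out[[i]]$index <- i
  plan$microcycles <- out
  plan$model <- "revised"
  plan
}

#' Build the revised eccentric training macrocycle
#'
#' The revised model: the initial plan's 12 training microcycles with an
#' active-recovery microcycle after every loading block - 14 microcycles
#' in total, recovery at positions 8 and 14. Mesocycle 1 remains
#' microcycles 1-3; mesocycle 2A spans microcycles 4-8 (four progressive
#' weeks plus recovery) and 2B microcycles 9-14. Active-recovery content
#' follows the plan's `recovery_policy`: `"light"` schedules two light
#' sessions (2 x 10 at 60 deg/s, half the current target); `"rest"`
#' schedules none.
#'
#' @inheritParams build_initial_macrocycle
#' @return An object of class `ecc_plan` with 14 microcycles.
#' @export
build_revised_macrocycle <- function(config = list()) {
  recommend_recovery(build_initial_macrocycle(config))
}

#' @export
print.ecc_plan <- function(x, ...) {
  phases <- vapply(x$microcycles, `[[`, character(1), "phase")
  cat(sprintf("<ecc_plan> %s macrocycle: %d microcycles (%d training, %d recovery), %d sessions/week\n",
              x$model, length(phases), sum(phases != "active_recovery"),
              sum(phases == "active_recovery"), x$sessions_per_week))
  for (mc in x$microcycles) {
    sets <- paste(sprintf("%g deg/s %dx%d", mc$sets$velocity_dps,
                          mc$sets$sets, mc$sets$reps), collapse = "; ")
    tgt <- switch(mc$target_mode,
                  fixed = paste0(paste(mc$target_percent, collapse = "/"), "%"),
                  adjust = "+/-5%", recovery = "recovery")
    cat(sprintf("  micro %2d [%s, meso %s] %s @ %s\n", mc$index,
                substr(mc$phase, 1, 5), mc$mesocycle, sets, tgt))
  }
  invisible(x)
}

#' @export
summary.ecc_plan <- function(object, ...) {
  sp <- session_prescriptions(object)
  phases <- vapply(sp, `[[`, character(1), "phase")
  cat(sprintf("%s macrocycle: %d scheduled sessions (%d training), reps/session %s\n",
              object$model, length(sp), sum(phases != "active_recovery"),
              paste(unique(vapply(sp, function(s) sum(s$sets$sets * s$sets$reps),
                                  numeric(1))), collapse = "/")))
  invisible(object)
}

#' Expand a plan into per-session prescriptions
#'
#' Each training microcycle holds two sessions; an active-recovery
#' microcycle holds two light sessions under the `"light"` policy and
#' none under `"rest"`. Fixed-target microcycles carry their percentage
#' (the familiarization week uses its two session targets in order);
#' adjustment-slot sessions carry `NA` until resolved by
#' [next_prescription()] or the closed loop.
#'
#' @param plan an `ecc_plan`.
#' @return A list of `session_prescription` objects: lists with
#'   `microcycle_index`, `session_in_microcycle`, `phase`, `mesocycle`,
#'   `sets` (one row per set, slower velocities first), `target_mode`,
#'   `target_percent`.
#' @export
session_prescriptions <- function(plan) {
  stopifnot(inherits(plan, "ecc_plan"))
  out <- list()
  for (mc in plan$microcycles) {
    if (mc$phase == "active_recovery" && plan$recovery_policy == "rest") next
    n_sess <- plan$sessions_per_week
    for (s in seq_len(n_sess)) {
      tgt <- if (mc$target_mode == "fixed") {
        if (length(mc$target_percent) >= s) mc$target_percent[s] else
          mc$target_percent[length(mc$target_percent)]
      } else NA_real_
      sets <- mc$sets[order(mc$sets$velocity_dps), , drop = FALSE]
      sets <- sets[rep(seq_len(nrow(sets)), sets$sets), , drop = FALSE]
      sets$sets <- NULL
      rownames(sets) <- NULL
      out[[length(out) + 1L]] <- structure(
        list(microcycle_index = mc$index, session_in_microcycle = s,
             phase = mc$phase, mesocycle = mc$mesocycle, sets = sets,
             target_mode = mc$target_mode, target_percent = tgt),
        class = "session_prescription")
    }
  }
  out
}

#' Schedule plan sessions onto calendar dates
#'
#' Each microcycle maps to one 7-day week starting at `start_date`.
#' Sessions within a week are placed at evenly spaced day offsets
#' (days 1 and 4 for the default two sessions), which guarantees at
#' least `min_rest_days` full rest days between any two consecutive
#' sessions, including across week boundaries. Infeasible combinations
#' of `sessions_per_week` and `min_rest_days` raise an error of class
#' `ep_scheduling_failure`.
#'
#' @param plan an `ecc_plan`.
#' @param start_date a `Date` or "YYYY-MM-DD" string: date of the first
#'   session.
#' @return A data frame with columns `date`, `microcycle`,
#'   `session_in_microcycle`, `phase`, `is_training`, `velocity_mix`,
#'   `target_percent`.
#' @examples
#' sched <- schedule_sessions(build_initial_macrocycle(), "2020-01-06")
#' sum(sched$is_training) # 24
#' @export
schedule_sessions <- function(plan, start_date) {
  stopifnot(inherits(plan, "ecc_plan"))
  start_date <- as.Date(start_date)
  s <- plan$sessions_per_week
  r <- plan$min_rest_days
  offs <- floor(7 * (seq_len(s) - 1L) / s)
  gaps <- c(diff(offs), 7 - offs[s])
  if (s > 1L && any(gaps < r + 1)) {
    ep_stop(sprintf("%d sessions/week with %d rest day(s) between sessions does not fit a 7-day week",
                    s, r), "ep_scheduling_failure")
  }
  sp <- session_prescriptions(plan)
  if (!length(sp)) {
    return(data.frame(date = as.Date(character()), microcycle = integer(),
                      session_in_microcycle = integer(), phase = character(),
                      is_training = logical(), velocity_mix = character(),
                      target_percent = numeric()))
  }
  rows <- lapply(sp, function(p) {
    data.frame(
      date = start_date + (p$microcycle_index - 1L) * 7L +
        offs[p$session_in_microcycle],
      microcycle = p$microcycle_index,
      session_in_microcycle = p$session_in_microcycle,
      phase = p$phase,
      is_training = p$phase != "active_recovery",
      velocity_mix = paste(sprintf("%gx%g", p$sets$velocity_dps, p$sets$reps),
                           collapse = "+"),
      target_percent = p$target_percent)
  })
  out <- do.call(rbind, rows)
  out[order(out$date), , drop = FALSE]
}

#' Initialize plan-state for sequential prescription
#'
#' @param plan an `ecc_plan`.
#' @param ecc_peak optional estimated eccentric peak torque (N m); when
#'   supplied, issued prescriptions also carry an absolute
#'   `target_torque`.
#' @return An object of class `ecc_plan_state`.
#' @seealso [next_prescription()]
#' @export
plan_state <- function(plan, ecc_peak = NULL) {
  structure(list(plan = plan, prescriptions = session_prescriptions(plan),
                 pos = 0L, current_percent = NA_real_, ecc_peak = ecc_peak),
            class = "ecc_plan_state")
}

#' Issue the next session prescription
#'
#' Advances the plan state by one session. Fixed-target microcycles
#' (1-4) use their scheduled percentages and reset the adjustment
#' chain's seed; adjustment-slot sessions (microcycle 5 onward) apply
#' the multiplier of `last_outcome` - the decision taken after the
#' previous training session - to the current target, so the chain
#' seeds from the attained 70% target of microcycle 4. Active-recovery
#' sessions prescribe half the current target and do not consume or
#' alter the chain. Advancing past the end of the plan raises an error
#' of class `ep_plan_exhausted`.
#'
#' @param state an `ecc_plan_state` from [plan_state()].
#' @param last_outcome an `adjustment_decision` from the previous
#'   training session, or `NULL`.
#' @return A list with `prescription` (a `session_prescription` whose
#'   `target_percent` is resolved) and the updated `state`.
#' @export
next_prescription <- function(state, last_outcome = NULL) {
  stopifnot(inherits(state, "ecc_plan_state"))
  pos <- state$pos + 1L
  if (pos > length(state$prescriptions)) {
    ep_stop("plan exhausted: no further sessions", "ep_plan_exhausted")
  }
  p <- state$prescriptions[[pos]]
  if (p$target_mode == "fixed") {
    state$current_percent <- p$target_percent
  } else if (p$target_mode == "adjust") {
    if (!is.null(last_outcome)) {
      stopifnot(inherits(last_outcome, "adjustment_decision"))
      state$current_percent <- state$current_percent * last_outcome$multiplier
    }
    p$target_percent <- state$current_percent
  } else { # recovery: light sessions at half the current target
    p$target_percent <- 0.5 * state$current_percent
  }
  if (!is.null(state$ecc_peak)) {
    p$target_torque <- p$target_percent / 100 * state$ecc_peak
  }
  state$pos <- pos
  list(prescription = p, state = state)
}
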