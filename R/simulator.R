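# Virtual-participant simulator: generates synthetic torque-time series
# and full closed-loop training histories with the statistical structure
# the prescription method assumes, so every other module can be
# exercised without clinical data.
#
# The generative model (see the methods vignette for rationale):
#   * each repetition's peak torque tracks min(target, current capacity),
#     times a mild velocity gain, times multiplicative lognormal noise
#     whose CV decays exponentially across sessions (motor learning);
#   * repetition timing varies through a lognormal pause between
#     repetitions, scaled so the peak-to-peak interval CV matches the
#     same decaying CV;
#   * intra-session fatigue is work-proportional (a fixed fraction of
#     capacity lost per joule), with partial exponential-style recovery
#     toward the session-start capacity during inter-set rest;
#   * capacity adapts upward by a small fraction after each compliant
#     session; VAS pain follows a bounded random walk.

#' Construct a virtual participant
#'
#' Parameters are chosen to emulate the population the protocol was
#' designed for (older adults naive to eccentric exercise): repetition
#' variability decaying from CV 68% toward a 12% floor across
#' familiarization, a mild +7% torque gain per 30 deg/s above 60, and a
#' low-grade baseline pain score of 2.9/10. Fatigue, recovery and
#' adaptation rates have no published per-session calibration data and
#' default to illustrative mild values.
#'
#' @param concentric_peak measured concentric peak torque (N m).
#' @param ecc_con_ratio cofactor used for the eccentric estimate
#'   (default 1.35; plausible range roughly 1.2-2.0).
#' @param capacity true current eccentric ceiling (N m); default
#'   `1.6 * concentric_peak` (a true ratio above the deliberately
#'   conservative estimator).
#' @param fatigue_rate fraction of capacity lost per joule of set work.
#' @param recovery_rate fraction of the intra-session capacity deficit
#'   restored during each inter-set rest.
#' @param variability_cv0 target-tracking / interval CV at session 1
#'   (fraction, default 0.68).
#' @param variability_cv_floor asymptotic CV (default 0.12).
#' @param variability_half_life sessions for the CV excess over the
#'   floor to halve (default 0.2, reproducing the observed
#'   session-1-to-2 drop).
#' @param amplitude_cv_fraction ratio of peak-amplitude tracking CV to
#'   the interval CV (default 0.25): repetition timing is far more
#'   variable than peak torque, which the participant steers against a
#'   visual target.
#' @param adaptation_rate fractional capacity gain after a compliant
#'   session.
#' @param velocity_torque_gain fractional torque change per 30 deg/s
#'   above 60 (default 0.07).
#' @param vas_baseline,vas_noise baseline pain score and random-walk
#'   step SD (VAS units).
#' @return An object of class `participant_model`.
#' @export
participant_model <- function(concentric_peak = 150,
                              ecc_con_ratio = 1.35,
                              capacity = NULL,
                              fatigue_rate = 2e-5,
                              recovery_rate = 0.8,
                              variability_cv0 = 0.68,
                              variability_cv_floor = 0.12,
                              variability_half_life = 0.2,
                              amplitude_cv_fraction = 0.25,
                              adaptation_rate = 0.01,
                              velocity_torque_gain = 0.07,
                              vas_baseline = 2.9,
                              vas_noise = 0.6) {
  if (is.null(capacity)) capacity <- 1.6 * concentric_peak
  rates <- c(fatigue_rate, recovery_rate, variability_cv0, variability_cv_floor,
             variability_half_life, amplitude_cv_fraction, adaptation_rate,
             vas_noise)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    ep_stop("all participant rates must be finite and non-negative",
            "ep_invalid_input")
  }
  if (variability_cv_floor > variability_cv0) {
    ep_stop("variability_cv_floor must not exceed variability_cv0",
            "ep_invalid_input")
  }
  if (!is_num1(capacity) || capacity <= 0 || !is_num1(concentric_peak) ||
      concentric_peak <= 0) {
    ep_stop("capacity and concentric_peak must be positive", "ep_invalid_input")
  }
  structure(list(concentric_peak = concentric_peak,
                 ecc_con_ratio = ecc_con_ratio, capacity = capacity,
                 fatigue_rate = fatigue_rate, recovery_rate = recovery_rate,
                 variability_cv0 = variability_cv0,
                 variability_cv_floor = variability_cv_floor,
                 variability_half_life = variability_half_life,
                 amplitude_cv_fraction = amplitude_cv_fraction,
                 adaptation_rate = adaptation_rate,
                 velocity_torque_gain = velocity_torque_gain,
                 vas_baseline = vas_baseline, vas_noise = vas_noise),
            class = "participant_model")
}

#' Preset participant profiles
#'
#' `"default"` is [participant_model()]'s baseline; `"fatigue_prone"`
#' loses capacity quickly within a session and recovers poorly (sessions
#' tend to classify excessive); `"responder"` adapts quickly and
#' fatigues little; `"deterministic"` removes all variability (for
#' closed-form checks of the progression chain).
#'
#' @param profile profile name (hyphens and underscores equivalent).
#' @param ... overrides passed on to [participant_model()].
#' @return A `participant_model`.
#' @export
participant_profile <- function(profile = c("default", "fatigue_prone",
                                            "responder", "deterministic"),
                                ...) {
  profile <- gsub("-", "_", profile[1L])
  profile <- match.arg(profile, c("default", "fatigue_prone", "responder",
                                  "deterministic"))
  args <- switch(profile,
    default = list(),
    fatigue_prone = list(fatigue_rate = 5e-4, recovery_rate = 0.3,
                         adaptation_rate = 0.003),
    responder = list(adaptation_rate = 0.03, fatigue_rate = 1e-5,
                     capacity = 1.8 * 150),
    deterministic = list(variability_cv0 = 0, variability_cv_floor = 0,
                         vas_noise = 0))
  do.call(participant_model, utils::modifyList(args, list(...)))
}

#' Tracking-noise CV at a given session
#'
#' Exponential decay of the variability CV across sessions:
#' `floor + (cv0 - floor) * 2^(-(s - 1) / half_life)`, so session 1 sits
#' at `cv0` and later sessions approach the floor.
#'
#' @param model a [participant_model()].
#' @param session session ordinal (1-based).
#' @return CV as a fraction.
#' @export
cv_at_session <- function(model, session) {
  stopifnot(inherits(model, "participant_model"))
  hl <- model$variability_half_life
  decay <- if (hl > 0) 2^(-(session - 1) / hl) else as.numeric(session == 1)
  model$variability_cv_floor +
    (model$variability_cv0 - model$variability_cv_floor) * decay
}

#' Simulation configuration
#'
#' @param seed integer seed (applied by [run_closed_loop()]; `NULL`
#'   leaves the RNG state untouched).
#' @param sample_rate sampling rate in Hz (default 100, the
#'   dynamometer's rate).
#' @param rom range of motion in degrees (default 90).
#' @param noise_sd_fraction within-repetition sample noise, as a
#'   fraction of the repetition's peak level (default 0.02).
#' @param rep_interval_s nominal peak-to-peak repetition interval in
#'   seconds (default 5.5, the low-variability exemplar value).
#' @param transition_gap_s pause between the extension and flexion
#'   half-cycles (seconds).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = NULL, sample_rate = 100, rom = 90,
                       noise_sd_fraction = 0.02, rep_interval_s = 5.5,
                       transition_gap_s = 0.25) {
  if (!is_num1(sample_rate) || sample_rate <= 0 || !is_num1(rom) || rom <= 0) {
    ep_stop("sample_rate and rom must be positive", "ep_invalid_input")
  }
  structure(list(seed = seed, sample_rate = sample_rate, rom = rom,
                 noise_sd_fraction = noise_sd_fraction,
                 rep_interval_s = rep_interval_s,
                 transition_gap_s = transition_gap_s),
            class = "sim_config")
}

# One repetition cycle as raw sample vectors (torque, angle, velocity),
# given the realized peak level. Extension burst, transition gap,
# flexion burst at 55% magnitude. `rom_frac` < 1 emits a partial-range
# repetition (erratic early-familiarization motion). Returns vectors
# plus bookkeeping.
sim_rep_block <- function(level, velocity, config, flagged = FALSE,
                          rom_frac = 1) {
  rate <- config$sample_rate
  rom <- config$rom * rom_frac
  n_m <- max(4L, round(rom / velocity * rate))
  u <- (seq_len(n_m) - 0.5) / n_m
  shape <- sin(pi * u)^0.6
  # narrow crest keeps the peak instant well localized under sample
  # noise (the plateau of sin^0.6 alone lets the argmax wander)
  crest <- (shape * (1 + 0.08 * exp(-((u - 0.5) / 0.08)^2))) / 1.08
  n_g <- max(1L, round(config$transition_gap_s * rate))
  if (flagged) {
    # sub-threshold effort: no motion, constant low torque
    n <- 2L * n_m + n_g
    return(list(torque = rep(level, n), angle = rep(0, n),
                vel = rep(0, n), motion_samples = 0L,
                peak = level, peak_offset = n_m %/% 2L))
  }
  noise <- function(n) stats::rnorm(n, 0, config$noise_sd_fraction * level)
  ext_t <- level * crest + noise(n_m)
  flx_t <- -0.55 * level * shape + noise(n_m)
  torque <- c(ext_t, rep(0, n_g), flx_t)
  angle <- c(rom * u, rep(rom, n_g), rom * (1 - u))
  vel <- c(rep(velocity, n_m), rep(0, n_g), rep(-velocity, n_m))
  pk <- which.max(ext_t)
  list(torque = torque, angle = angle, vel = vel,
       motion_samples = 2L * n_m, peak = ext_t[pk], peak_offset = pk)
}

#' Simulate one repetition
#'
#' Generates the torque-time curve of a single reciprocal
#' extension/flexion repetition against a workload target: torque rises
#' above the engagement threshold and tracks
#' `min(target, capacity) * velocity gain * noise`, with motion through
#' the range of motion at the target velocity. If the attempted torque
#' falls below the engagement threshold the dynamometer does not move
#' and the repetition is emitted flagged, with sub-threshold torque and
#' no motion.
#'
#' @param model a [participant_model()].
#' @param target a [workload_target()].
#' @param session_ordinal session number (drives the CV decay).
#' @param config a [sim_config()].
#' @param capacity current capacity override (N m; default
#'   `model$capacity`).
#' @param rom_frac fraction of the configured range of motion actually
#'   covered (erratic repetitions are partial; default 1).
#' @return A list with `series` (a [torque_series()] for the
#'   repetition), `peak_torque`, `work_j`, `flagged`, `capacity_after`.
#' @export
simulate_repetition <- function(model, target, session_ordinal = 1,
                                config = sim_config(), capacity = NULL,
                                rom_frac = 1) {
  stopifnot(inherits(model, "participant_model"),
            inherits(target, "workload_target"))
  if (is.null(capacity)) capacity <- model$capacity
  cv_amp <- model$amplitude_cv_fraction * cv_at_session(model, session_ordinal)
  sdlog <- sqrt(log(1 + cv_amp^2))
  mult <- if (sdlog > 0) stats::rlnorm(1, -sdlog^2 / 2, sdlog) else 1
  vgain <- 1 + model$velocity_torque_gain * (target$velocity - 60) / 30
  level <- min(target$target_torque, capacity) * vgain * mult
  flagged <- level < target$engagement_threshold
  blk <- sim_rep_block(level, target$velocity, config, flagged = flagged,
                       rom_frac = rom_frac)
  n <- length(blk$torque)
  series <- torque_series(time_s = (seq_len(n) - 1L) / config$sample_rate,
                          torque_nm = blk$torque, angle_deg = blk$angle,
                          velocity_dps = blk$vel,
                          sample_rate = config$sample_rate)
  w <- if (flagged) 0 else total_work(series)
  list(series = series, peak_torque = blk$peak, work_j = w, flagged = flagged,
       capacity_after = capacity * (1 - model$fatigue_rate * w))
}

# Draw a repetition interval (seconds) with the session's CV around the
# nominal interval: gamma-distributed, so the measured peak-to-peak CV
# tracks the generating CV without extreme skew. Short draws are
# realized as partial-range repetitions; long draws become pre-rep
# pauses.
draw_interval <- function(cv, interval_nominal) {
  if (cv <= 0) return(interval_nominal)
  shape <- 1 / cv^2
  stats::rgamma(1, shape = shape, rate = shape / interval_nominal)
}

#' Simulate one exercise session
#'
#' Runs the prescribed sets repetition by repetition. Peak-to-peak
#' repetition intervals are gamma-distributed around the nominal
#' interval with the session's decaying CV; intervals shorter than a
#' full reciprocal cycle are realized as partial-range (erratic)
#' repetitions and longer ones as pre-repetition pauses, so early
#' familiarization sessions show both quick partial reps and long
#' hesitations. Capacity falls in proportion to accumulated work within
#' each set and part of the deficit is restored during the 60 s
#' inter-set rests. Emits one torque series per set plus the
#' per-repetition peak torques in the form the fatigue classifier
#' expects.
#'
#' @param model a [participant_model()].
#' @param prescription a `session_prescription` with resolved
#'   `target_percent` (or a `target_torque` element), e.g. from
#'   [next_prescription()].
#' @param session_ordinal session number (drives the CV decay).
#' @param config a [sim_config()].
#' @param capacity session-start capacity (N m; default
#'   `model$capacity`).
#' @param ecc_peak estimated eccentric peak torque used to convert
#'   percent targets (default from the model's concentric peak and
#'   cofactor).
#' @return A list of class `session_result`: `series` (list of
#'   [torque_series()], one per set), `rep_peaks` (list of numeric
#'   vectors), `flags`, `total_work_j`, `active_time_s`,
#'   `mean_power_w`, `peak_torque_nm`, `target_torque`,
#'   `capacity_end`.
#' @export
simulate_session <- function(model, prescription, session_ordinal = 1,
                             config = sim_config(), capacity = NULL,
                             ecc_peak = NULL) {
  stopifnot(inherits(model, "participant_model"))
  if (is.null(ecc_peak)) {
    ecc_peak <- estimate_ecc_peak_torque(model$concentric_peak,
                                         model$ecc_con_ratio)
  }
  if (is.null(capacity)) capacity <- model$capacity
  tgt_torque <- prescription$target_torque
  if (is.null(tgt_torque)) {
    if (is.null(prescription$target_percent) || is.na(prescription$target_percent)) {
      ep_stop("prescription has no resolved target", "ep_invalid_input")
    }
    tgt_torque <- prescription$target_percent / 100 * ecc_peak
  }
  sets_df <- prescription$sets
  cv <- cv_at_session(model, session_ordinal)
  cap_start <- capacity
  rate <- config$sample_rate

  series_list <- list()
  peaks_list <- list()
  flags_list <- list()
  work_total <- 0
  motion_samples <- 0L

  for (si in seq_len(nrow(sets_df))) {
    v <- sets_df$velocity_dps[si]
    reps <- sets_df$reps[si]
    wt <- workload_target(tgt_torque, velocity = v,
                          percent_of_ecc_peak = prescription$target_percent)
    motion_full <- 2 * config$rom / v
    min_pause <- 0.2
    torque <- list(); angle <- list(); vel <- list()
    peaks <- numeric(reps); flags <- logical(reps)
    for (r in seq_len(reps)) {
      iv <- draw_interval(cv, config$rep_interval_s)
      avail <- iv - config$transition_gap_s - min_pause
      rom_frac <- min(1, max(0.3, avail / motion_full))
      p_dur <- max(min_pause,
                   iv - rom_frac * motion_full - config$transition_gap_s)
      n_p <- max(1L, round(p_dur * rate))
      rep_sim <- simulate_repetition(model, wt, session_ordinal, config,
                                     capacity = capacity, rom_frac = rom_frac)
      capacity <- rep_sim$capacity_after
      torque[[r]] <- c(rep(0, n_p), rep_sim$series$torque_nm)
      angle[[r]] <- c(rep(0, n_p), rep_sim$series$angle_deg)
      vel[[r]] <- c(rep(0, n_p), rep_sim$series$velocity_dps)
      peaks[r] <- rep_sim$peak_torque
      flags[r] <- rep_sim$flagged
      if (!rep_sim$flagged) motion_samples <- motion_samples +
          sum(rep_sim$series$velocity_dps != 0)
    }
    tq <- unlist(torque); an <- unlist(angle); ve <- unlist(vel)
    set_series <- torque_series((seq_along(tq) - 1L) / rate, tq, an, ve,
                                sample_rate = rate)
    series_list[[si]] <- set_series
    peaks_list[[si]] <- peaks
    flags_list[[si]] <- flags
    work_total <- work_total + total_work(set_series)
    # inter-set rest restores part of the intra-session deficit
    capacity <- capacity + model$recovery_rate * (cap_start - capacity)
  }
  active_time <- motion_samples / rate
  structure(list(series = series_list, rep_peaks = peaks_list,
                 flags = flags_list, total_work_j = work_total,
                 active_time_s = active_time,
                 mean_power_w = if (active_time > 0)
                   mean_power(work_total, active_time) else 0,
                 peak_torque_nm = max(unlist(peaks_list)),
                 target_torque = tgt_torque,
                 capacity_end = capacity),
            class = "session_result")
}

#' Run the closed training loop over a full macrocycle
#'
#' End-to-end harness: for each scheduled session the loop prescribes
#' (via the plan-state machine), simulates the session, classifies
#' intra-session fatigue against the visual torque bands, and applies
#' the workload-adjustment rule; compliant sessions raise the
#' participant's capacity by the adaptation rate. Pre-session VAS pain
#' follows a bounded random walk and sessions are truncated (recorded
#' with zero work) when the stoppage criterion triggers. Decisions from
#' active-recovery sessions do not enter the adjustment chain.
#'
#' Session ids: `B#` for the introductory mesocycle (familiarization +
#' acclimatization), `P#` for progression-phase sessions, `R#` for
#' active recovery.
#'
#' @param model a [participant_model()].
#' @param plan an `ecc_plan`.
#' @param seed integer seed; the single source of randomness.
#' @param config a [sim_config()].
#' @param mode adjustment mode passed to [adjust_workload()].
#' @return An object of class `ecc_simulation`: list with `ledger`
#'   (a [progress_ledger()]), `decisions` (data frame), `model`,
#'   `plan`, `seed`, `ecc_peak`, `capacity_trace`.
#' @examples
#' \donttest{
#' sim <- run_closed_loop(participant_model(), build_initial_macrocycle(),
#'                        seed = 42)
#' summary(progression_analysis(sim$ledger))
#' }
#' @export
run_closed_loop <- function(model, plan, seed = 1, config = sim_config(),
                            mode = "multiplicative") {
  stopifnot(inherits(model, "participant_model"), inherits(plan, "ecc_plan"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  ecc_peak <- estimate_ecc_peak_torque(model$concentric_peak,
                                       model$ecc_con_ratio)
  st <- plan_state(plan, ecc_peak)
  n_sessions <- length(st$prescriptions)
  capacity <- model$capacity
  vas <- model$vas_baseline
  last_dec <- NULL
  counters <- c(B = 0L, P = 0L, R = 0L)
  rows <- vector("list", n_sessions)
  cap_trace <- numeric(n_sessions)

  for (k in seq_len(n_sessions)) {
    np <- next_prescription(st, last_dec)
    st <- np$state
    p <- np$prescription
    kind <- switch(p$phase, active_recovery = "R", progression = "P", "B")
    counters[kind] <- counters[kind] + 1L
    sid <- paste0(kind, counters[kind])
    vmix <- paste(sprintf("%gx%g", p$sets$velocity_dps, p$sets$reps),
                  collapse = "+")
    vas <- min(10, max(0, vas + stats::rnorm(1, 0, model$vas_noise)))
    stop_status <- stoppage_check(vas, model$vas_baseline)
    if (stop_status == "stop") {
      rows[[k]] <- data.frame(
        session_id = sid, microcycle = p$microcycle_index,
        session_in_microcycle = p$session_in_microcycle, phase = p$phase,
        velocity_mix = vmix, target_percent = p$target_percent,
        target_torque_nm = p$target_percent / 100 * ecc_peak,
        total_work_j = 0, peak_torque_nm = NA_real_, mean_power_w = NA_real_,
        interval_cv = NA_real_, vas = vas, fatigue_class = NA_character_,
        multiplier = NA_real_, next_target_torque_nm = NA_real_,
        stoppage = stop_status, stringsAsFactors = FALSE)
      cap_trace[k] <- capacity
      next
    }
    sess <- simulate_session(model, p, session_ordinal = k, config = config,
                             capacity = capacity, ecc_peak = ecc_peak)
    capacity <- sess$capacity_end
    bands <- make_bands(sess$target_torque)
    cls <- classify_session(sess$rep_peaks, bands)
    dec <- adjust_workload(sess$target_torque, cls, mode = mode,
                           ecc_peak = ecc_peak)
    if (cls == "compliant") capacity <- capacity * (1 + model$adaptation_rate)
    if (p$phase != "active_recovery") last_dec <- dec
    icv <- tryCatch(
      session_interval_stats(lapply(sess$series, segment_repetitions),
                             pooling = "best_set")$cv_percent,
      error = function(e) NA_real_)
    rows[[k]] <- data.frame(
      session_id = sid, microcycle = p$microcycle_index,
      session_in_microcycle = p$session_in_microcycle, phase = p$phase,
      velocity_mix = vmix, target_percent = p$target_percent,
      target_torque_nm = sess$target_torque,
      total_work_j = sess$total_work_j, peak_torque_nm = sess$peak_torque_nm,
      mean_power_w = sess$mean_power_w, interval_cv = icv, vas = vas,
      fatigue_class = cls, multiplier = dec$multiplier,
      next_target_torque_nm = dec$next_target_torque,
      stoppage = stop_status, stringsAsFactors = FALSE)
    cap_trace[k] <- capacity
  }
  ledger <- progress_ledger(do.call(rbind, rows))
  decisions <- ledger[, c("session_id", "phase", "target_torque_nm",
                          "fatigue_class", "multiplier",
                          "next_target_torque_nm")]
  structure(list(ledger = ledger, decisions = decisions, model = model,
                 plan = plan, seed = seed, ecc_peak = ecc_peak,
                 capacity_trace = cap_trace),
            class = "ecc_simulation")
}

#' @export
print.ecc_simulation <- function(x, ...) {
  led <- x$ledger
  cat(sprintf("<ecc_simulation> %s plan, seed %s: %d sessions\n",
              x$plan$model, format(x$seed), nrow(led)))
  tab <- table(led$fatigue_class)
  cat("  fatigue classes:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  prog <- led[led$phase == "progression", , drop = FALSE]
  if (nrow(prog)) {
    cat(sprintf("  progression targets: %.1f%% -> %.1f%% of estimated eccentric peak\n",
                prog$target_percent[1L], prog$target_percent[nrow(prog)]))
  }
  invisible(x)
}

#' @export
summary.ecc_simulation <- function(object, ...) {
  print(object)
  led <- object$ledger
  cat(sprintf("  total work: %.0f J first session, %.0f J last; VAS %.1f -> %.1f\n",
              led$total_work_j[1L], led$total_work_j[nrow(led)],
              led$vas[1L], led$vas[nrow(led)]))
  invisible(object)
}

#' Simulate a training history from a plan
#'
#' `simulate()` method for `ecc_plan`: runs [run_closed_loop()] `nsim`
#' times with consecutive seeds.
#'
#' @param object an `ecc_plan`.
#' @param nsim number of simulated histories.
#' @param seed base seed (history i uses `seed + i - 1`).
#' @param model a [participant_model()].
#' @param ... passed to [run_closed_loop()].
#' @return An `ecc_simulation`, or a list of them when `nsim > 1`.
#' @export
simulate.ecc_plan <- function(object, nsim = 1, seed = 1,
                              model = participant_model(), ...) {
  sims <- lapply(seq_len(nsim), function(i) {
    run_closed_loop(model, object, seed = seed + i - 1, ...)
  })
  if (nsim == 1) sims[[1L]] else sims
}

#' Estimate the variability half-life from per-session CVs
#'
#' Fits the exponential decay model `cv(s) = floor + (cv0 - floor) *
#' 2^(-(s-1)/half_life)` by ordinary least squares on
#' `log(cv - floor)`. Sessions whose measured CV sits within
#' `min_excess` of the floor are dropped: their excess is of the order
#' of the CV estimation error itself, so they carry no decay
#' information but explode on the log scale.
#'
#' @param session session ordinals (1-based).
#' @param cv measured CVs, as fractions or percentages (values above
#'   1.5 are taken to be percentages).
#' @param cv_floor the asymptotic CV (fraction).
#' @param min_excess smallest CV excess over the floor considered
#'   informative (fraction, default 0.03).
#' @return List with `half_life` (sessions) and `cv0` (implied
#'   session-1 CV, fraction).
#' @export
estimate_variability_half_life <- function(session, cv, cv_floor = 0.12,
                                           min_excess = 0.03) {
  cv <- as.numeric(cv)
  if (any(cv > 1.5, na.rm = TRUE)) cv <- cv / 100
  keep <- is.finite(cv) & (cv > cv_floor + min_excess)
  if (sum(keep) < 2L) {
    ep_stop("need at least 2 sessions with CV above the floor",
            "ep_insufficient_data")
  }
  y <- log(cv[keep] - cv_floor)
  x <- session[keep] - 1
  b <- unname(stats::coef(stats::lm(y ~ x)))
  if (b[2L] >= 0) {
    ep_stop("measured CVs do not decay across sessions", "ep_insufficient_data")
  }
  list(half_life = -log(2) / b[2L], cv0 = exp(b[1L]) + cv_floor)
}
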