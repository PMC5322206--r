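# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A series of `n_reps` half-sine extension bursts with known peak times.
# `time_jitter_sd` (s) shifts each burst and `amp_jitter_sd` (fraction)
# rescales it - per-burst noise with an exactly known peak schedule -
# while `noise_sd` adds white sample noise on top. Returns the
# torque_series plus the injected peak schedule.
burst_series <- function(n_reps = 10, peak = 100, burst_dur = 1.5,
                         pause = 1.0, rate = 100, noise_sd = 0,
                         time_jitter_sd = 0, amp_jitter_sd = 0,
                         rom = 90) {
  n_b <- round(burst_dur * rate)
  n_p <- round(pause * rate)
  u <- (seq_len(n_b) - 0.5) / n_b
  torque <- rep(0, n_reps * (n_b + n_p))
  angle <- rep(rom, length(torque))
  peak_times <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    start <- (r - 1) * (n_b + n_p)
    shift <- if (time_jitter_sd > 0)
      round(rnorm(1, 0, time_jitter_sd * rate)) else 0L
    shift <- max(min(shift, n_p %/% 2L), -min(start, n_p %/% 2L))
    amp <- peak * (1 + if (amp_jitter_sd > 0) rnorm(1, 0, amp_jitter_sd) else 0)
    idx <- start + shift + seq_len(n_b)
    torque[idx] <- amp * sin(pi * u)
    angle[idx] <- rom * u
    peak_times[r] <- (idx[which.max(sin(pi * u))] - 1) / rate
  }
  if (noise_sd > 0) torque <- torque + rnorm(length(torque), 0, noise_sd)
  ts <- torque_series(time_s = (seq_along(torque) - 1) / rate,
                      torque_nm = torque, angle_deg = angle,
                      velocity_dps = rep(0, length(torque)),
                      sample_rate = rate)
  list(series = ts, peak_times = peak_times, peak = peak)
}

# Segments data frame with prescribed extension peak-to-peak intervals.
segments_with_intervals <- function(intervals) {
  pt <- cumsum(c(1, intervals))
  data.frame(start_index = seq_along(pt), end_index = seq_along(pt) + 1L,
             direction = "extension", peak_torque = 100, peak_time = pt)
}

# Brute-force fatigue classifier used as the independent oracle.
classify_oracle <- function(peaks, target) {
  below_c <- peaks < 0.75 * target
  max_run <- 0
  run <- 0
  for (b in below_c) {
    run <- if (b) run + 1 else 0
    max_run <- max(max_run, run)
  }
  if (max_run >= 3) return("excessive")
  if (any(peaks < 0.90 * target)) return("moderate")
  "compliant"
}

# Closed-form OLS slope oracle.
ols_slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# A 4-set 30-rep prescription used by simulator statistics tests.
bulk_prescription <- function(reps = 30, sets = 4, velocity = 60,
                              target_percent = 60) {
  list(sets = data.frame(velocity_dps = velocity, reps = reps,
                         rest_after_s = 60)[rep(1, sets), ],
       target_percent = target_percent, phase = "progression")
}
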