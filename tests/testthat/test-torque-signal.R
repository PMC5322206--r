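test_that("gravity correction follows the single-point cosine model", {
  t <- seq(0, 1, by = 0.01)
  ts <- torque_series(t, rep(100, length(t)), rep(30, length(t)))

  # zero calibration torque leaves the series untouched
  out <- gravity_correct(ts, gravity_calibration(0))
  expect_identical(out$torque_nm, ts$torque_nm)

  # closed form at a fixed angle: tau + g * cos(angle - reference)
  g <- 7.5
  out <- gravity_correct(ts, gravity_calibration(g, angle_reference = 0))
  expect_equal(out$torque_nm, rep(100 + g * cos(30 * pi / 180), length(t)))

  # at the reference angle the full calibration torque is added
  ts0 <- torque_series(t, rep(100, length(t)), rep(0, length(t)))
  out0 <- gravity_correct(ts0, gravity_calibration(g))
  expect_equal(out0$torque_nm, rep(100 + g, length(t)))
})

test_that("calibration drift beyond 10% raises the recheck condition", {
  cal_drift <- gravity_calibration(12, baseline_value = 10) # 20% drift
  expect_true(gravity_recheck(cal_drift))
  expect_false(gravity_recheck(gravity_calibration(10.5, baseline_value = 10)))

  t <- seq(0, 0.1, by = 0.01)
  ts <- torque_series(t, rep(1, length(t)), rep(0, length(t)))
  expect_warning(gravity_correct(ts, cal_drift), class = "ep_gravity_recheck")
  expect_error(gravity_correct(ts, NULL), class = "ep_uncalibrated")
})

test_that("segmentation recovers constructed repetition bursts", {
  fix <- burst_series(n_reps = 10)
  segs <- segment_repetitions(fix$series)
  ext <- segs[segs$direction == "extension", ]
  expect_equal(nrow(ext), 10)
  expect_equal(ext$peak_torque, rep(fix$peak, 10), tolerance = 1e-4)
  expect_equal(ext$peak_time, fix$peak_times, tolerance = 1e-9)

  # all-zero torque: no repetitions, not an error
  t <- seq(0, 1, by = 0.01)
  zero <- torque_series(t, rep(0, length(t)), rep(0, length(t)))
  expect_equal(nrow(segment_repetitions(zero)), 0)

  expect_error(segment_repetitions(fix$series, min_peak_fraction = 1.2),
               class = "ep_invalid_input")
})

test_that("segmentation recovers injected peak schedules within one sample", {
  # per-burst timing and amplitude jitter with an exactly known schedule
  set.seed(101)
  for (rep_i in 1:5) {
    fix <- burst_series(n_reps = 8, peak = 120, time_jitter_sd = 0.1,
                        amp_jitter_sd = 0.08)
    segs <- segment_repetitions(fix$series)
    ext <- segs[segs$direction == "extension", ]
    expect_equal(nrow(ext), 8)
    expect_true(all(abs(ext$peak_time - fix$peak_times) <= 1 / 100 + 1e-9))
  }
  # repetition count survives white sample noise up to 10% of peak
  set.seed(202)
  for (rep_i in 1:5) {
    fix <- burst_series(n_reps = 12, peak = 100, noise_sd = 10)
    segs <- segment_repetitions(fix$series)
    expect_equal(sum(segs$direction == "extension"), 12)
  }
})

test_that("interval statistics reproduce CV = 100 * SD / mean with sample SD", {
  # identical intervals: no variability
  st <- repetition_interval_stats(segments_with_intervals(rep(3, 6)))
  expect_equal(st$sd_interval, 0)
  expect_equal(st$cv_percent, 0)

  # CV identity and scale invariance
  set.seed(7)
  iv <- rexp(20, 1 / 3)
  st <- repetition_interval_stats(iv)
  expect_equal(st$cv_percent, 100 * sd(iv) / mean(iv))
  st2 <- repetition_interval_stats(3.7 * iv)
  expect_equal(st2$cv_percent, st$cv_percent)

  one_seg <- segments_with_intervals(numeric(0))[1, ]
  expect_error(repetition_interval_stats(one_seg),
               class = "ep_insufficient_data")
})

test_that("session pooling modes select the cleanest set or pool intervals", {
  noisy <- segments_with_intervals(c(2, 6, 3, 9))
  clean <- segments_with_intervals(c(5, 5.2, 4.9, 5.1))
  best <- session_interval_stats(list(noisy, clean), pooling = "best_set")
  expect_equal(best$cv_percent,
               repetition_interval_stats(clean)$cv_percent)
  pooled <- session_interval_stats(list(noisy, clean), pooling = "pooled")
  expect_equal(length(pooled$intervals), 8)
})

test_that("five-repetition peak torque averages the three highest values", {
  expect_equal(peak_torque_five_rep(c(100, 110, 120, 90, 95)), 110)
  expect_equal(peak_torque_five_rep(rep(100, 5)), 100)
  set.seed(11)
  for (i in 1:20) {
    p <- runif(5, 50, 300)
    expect_equal(peak_torque_five_rep(p),
                 mean(sort(p, decreasing = TRUE)[1:3]))
  }
  expect_error(peak_torque_five_rep(c(1, 2, 3)), class = "ep_invalid_protocol")
  expect_error(peak_torque_five_rep(c(1, 2, 3, 4, -5)),
               class = "ep_invalid_protocol")
})

test_that("total work integrates torque over angular displacement", {
  t <- seq(0, 1.5, length.out = 151)
  const <- torque_series(t, rep(100, 151), seq(0, 90, length.out = 151))
  expect_equal(total_work(const), 100 * pi / 2, tolerance = 1e-10)

  zero <- torque_series(t, rep(0, 151), seq(0, 90, length.out = 151))
  expect_equal(total_work(zero), 0)

  # triangular profile: area is half the constant case; compare against
  # a fine-grid Riemann-sum oracle
  tri_tau <- c(seq(0, 100, length.out = 76), seq(100, 0, length.out = 76)[-1])
  tri <- torque_series(t, tri_tau, seq(0, 90, length.out = 151))
  th <- seq(0, pi / 2, length.out = 200001)
  oracle <- sum(approx(seq(0, pi / 2, length.out = 151), tri_tau, th)$y) *
    (pi / 2) / length(th)
  expect_equal(total_work(tri), 100 * pi / 4, tolerance = 1e-3)
  expect_equal(total_work(tri), oracle, tolerance = 1e-3)

  expect_error(total_work(torque_series(0, 10, 0)),
               class = "ep_insufficient_data")
})

test_that("work is invariant under time reparameterization and splits by direction", {
  # same torque-angle path traversed at different speeds
  ang <- seq(0, 90, length.out = 101)
  tau <- 80 * sin(pi * ang / 90) + 20
  slow <- torque_series(seq(0, 2, length.out = 101), tau, ang)
  fast <- torque_series(seq(0, 0.5, length.out = 101), tau, ang)
  expect_equal(total_work(slow), total_work(fast))

  # reciprocal motion: extension positive work, flexion positive work
  t2 <- seq(0, 3, length.out = 301)
  ang2 <- c(seq(0, 90, length.out = 151), seq(90, 0, length.out = 151)[-1])
  tau2 <- c(rep(100, 151), rep(-50, 150))
  rec <- suppressWarnings(torque_series(t2, tau2, ang2))
  w <- total_work(rec, by_direction = TRUE)
  expect_gt(w[["extension"]], 0)
  expect_gt(w[["flexion"]], 0)
  expect_equal(w[["combined"]], w[["extension"]] + w[["flexion"]])
})

test_that("trapezoidal work converges to the analytic integral with sample rate", {
  true_w <- 100 * 2 / pi * (pi / 2) # integral of 100 sin(pi u) over 90 deg
  err <- sapply(c(11, 51, 201, 1001), function(n) {
    u <- seq(0, 1, length.out = n)
    ts <- torque_series(u, 100 * sin(pi * u), 90 * u)
    abs(total_work(ts) - 100 * (2 / pi) * (pi / 2))
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[4], 1e-4)
})

test_that("mean power is work over active time and scales with velocity", {
  expect_equal(mean_power(157.08, 1.5), 104.72)
  # same torque profile, 90 vs 60 deg/s: exactly 1.5x the power
  w <- 100 * pi / 2
  expect_equal(mean_power(w, 1.0) / mean_power(w, 1.5), 1.5)
  expect_equal(mean_power(0, 2), 0)
  expect_error(mean_power(100, 0), class = "ep_invalid_input")
})

test_that("series constructor rejects malformed input", {
  expect_error(torque_series(c(0, 0.1, 0.05), 1:3, 1:3),
               class = "ep_malformed_input")
  expect_error(torque_series(numeric(0), numeric(0), numeric(0)),
               class = "ep_malformed_input")
  expect_error(torque_series(c(0, 0.1), 1, c(1, 2)),
               class = "ep_malformed_input")
})
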