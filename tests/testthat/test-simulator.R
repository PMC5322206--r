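test_that("noise-free repetitions track the target exactly", {
  m <- participant_profile("deterministic", capacity = 2000)
  cfg <- sim_config(noise_sd_fraction = 0)
  wt <- workload_target(150, velocity = 60)
  rep_sim <- simulate_repetition(m, wt, session_ordinal = 1, config = cfg)
  expect_equal(rep_sim$peak_torque, 150, tolerance = 1e-3)
  expect_false(rep_sim$flagged)
  # velocity gain: +7% at 90 deg/s
  wt90 <- workload_target(150, velocity = 90)
  rep90 <- simulate_repetition(m, wt90, session_ordinal = 1, config = cfg)
  expect_equal(rep90$peak_torque / rep_sim$peak_torque, 1.07, tolerance = 1e-3)
})

test_that("sub-threshold effort emits a flagged no-motion repetition", {
  m <- participant_profile("deterministic", capacity = 10)
  cfg <- sim_config(noise_sd_fraction = 0)
  wt <- workload_target(200) # engagement threshold 25 N m > capacity
  rep_sim <- simulate_repetition(m, wt, config = cfg)
  expect_true(rep_sim$flagged)
  expect_equal(rep_sim$work_j, 0)
  expect_equal(diff(range(rep_sim$series$angle_deg)), 0)
})

test_that("fatigue makes within-set peaks strictly decrease without noise", {
  m <- participant_profile("deterministic", capacity = 100,
                           fatigue_rate = 2e-4, recovery_rate = 0)
  cfg <- sim_config(noise_sd_fraction = 0)
  presc <- list(sets = data.frame(velocity_dps = 60, reps = 10,
                                  rest_after_s = 60),
                target_percent = 60, phase = "progression")
  # target torque 121.5 N m exceeds capacity, so peaks ride the
  # declining capacity
  sess <- simulate_session(m, presc, config = cfg)
  expect_true(all(diff(sess$rep_peaks[[1]]) < 0))
})

test_that("session output is consistent: counts, energy round-trip, power", {
  set.seed(31)
  m <- participant_model()
  presc <- bulk_prescription(reps = 10, sets = 3)
  sess <- simulate_session(m, presc, session_ordinal = 5)
  expect_equal(lengths(sess$rep_peaks), rep(10, 3))
  # ledgered work equals the torque-signal integral of the emitted series
  expect_equal(sess$total_work_j,
               sum(vapply(sess$series, total_work, numeric(1))))
  expect_equal(sess$mean_power_w, sess$total_work_j / sess$active_time_s)
})

test_that("closed-loop outcomes reflect the participant's fatigue profile", {
  set.seed(55)
  m_ok <- participant_model()
  presc <- bulk_prescription(reps = 10, sets = 3, target_percent = 70)
  sess <- simulate_session(m_ok, presc, session_ordinal = 10)
  bands <- make_bands(sess$target_torque)
  expect_equal(classify_session(sess$rep_peaks, bands), "compliant")

  m_tired <- participant_profile("fatigue_prone")
  sess2 <- simulate_session(m_tired, presc, session_ordinal = 10)
  expect_equal(classify_session(sess2$rep_peaks, make_bands(sess2$target_torque)),
               "excessive")
})

test_that("identical seeds give identical ledgers", {
  m <- participant_model()
  plan <- build_initial_macrocycle()
  s1 <- run_closed_loop(m, plan, seed = 17)
  s2 <- run_closed_loop(m, plan, seed = 17)
  expect_identical(s1$ledger, s2$ledger)
  s3 <- run_closed_loop(m, plan, seed = 18)
  expect_false(identical(s3$ledger$total_work_j, s1$ledger$total_work_j))
})

test_that("raising the fatigue rate never increases session work", {
  presc <- bulk_prescription(reps = 10, sets = 3, target_percent = 70)
  works <- vapply(c(0, 1e-4, 5e-4, 2e-3), function(fr) {
    m <- participant_profile("deterministic", capacity = 180,
                             fatigue_rate = fr)
    simulate_session(m, presc, config = sim_config(noise_sd_fraction = 0))$total_work_j
  }, numeric(1))
  expect_true(all(diff(works) <= 0))
})

test_that("variability CV decays from 0.68 toward the 0.12 floor", {
  m <- participant_model()
  expect_equal(cv_at_session(m, 1), 0.68)
  cvs <- cv_at_session(m, 1:10)
  expect_true(all(diff(cvs) < 0))
  expect_equal(cv_at_session(m, 50), 0.12, tolerance = 1e-6)
})

test_that("fitting the CV decay recovers the generating half-life within 20%", {
  m <- participant_model(variability_half_life = 1.5)
  cfg <- sim_config(sample_rate = 50)
  presc <- bulk_prescription(reps = 30, sets = 4)
  set.seed(1)
  cvs <- vapply(1:8, function(s) {
    mean(replicate(3, {
      sess <- simulate_session(m, presc, session_ordinal = s, config = cfg)
      session_interval_stats(lapply(sess$series, segment_repetitions),
                             pooling = "pooled")$cv_percent
    }))
  }, numeric(1))
  est <- estimate_variability_half_life(1:8, cvs,
                                        cv_floor = m$variability_cv_floor)
  expect_lt(abs(est$half_life - 1.5) / 1.5, 0.20)
})

test_that("a non-adapting fatiguing participant shows a plateau or decline", {
  m <- participant_model(adaptation_rate = 0, fatigue_rate = 1e-4,
                         capacity = 200)
  sim <- run_closed_loop(m, build_initial_macrocycle(), seed = 5)
  pa <- progression_analysis(sim$ledger)
  expect_gt(nrow(pa$events$plateaus) + nrow(pa$events$declines), 0)
})

test_that("stoppage truncates sessions when simulated pain exceeds VAS 8", {
  m <- participant_model(vas_baseline = 8, vas_noise = 2)
  sim <- run_closed_loop(m, build_initial_macrocycle(), seed = 3)
  stopped <- sim$ledger[sim$ledger$stoppage == "stop", , drop = FALSE]
  expect_gt(nrow(stopped), 0)
  expect_true(all(stopped$total_work_j == 0))
  expect_true(all(is.na(stopped$fatigue_class)))
})

test_that("simulate() on a plan wraps the closed loop", {
  sim <- simulate(build_initial_macrocycle(), seed = 9,
                  model = participant_model())
  expect_s3_class(sim, "ecc_simulation")
  expect_identical(sim$ledger,
                   run_closed_loop(participant_model(),
                                   build_initial_macrocycle(), seed = 9)$ledger)
})
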