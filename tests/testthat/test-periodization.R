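test_that("initial macrocycle matches the published 12-week structure", {
  plan <- build_initial_macrocycle()
  m <- plan$microcycles
  expect_length(m, 12)
  expect_equal(m[[1]]$sets$velocity_dps, 45)
  expect_equal(m[[1]]$phase, "familiarization")
  expect_equal(vapply(m[2:3], `[[`, character(1), "phase"),
               rep("acclimatization", 2))
  expect_equal(vapply(m[4:12], `[[`, character(1), "phase"),
               rep("progression", 9))
  # mesocycle 1 covers microcycles 1-3
  expect_equal(vapply(m[1:3], `[[`, character(1), "mesocycle"), rep("1", 3))
  # fixed targets 40-50 / 50 / 60 / 70, then adjustment slots
  expect_equal(m[[1]]$target_percent, c(40, 50))
  expect_equal(vapply(m[2:4], function(x) x$target_percent[1], numeric(1)),
               c(50, 60, 70))
  expect_equal(vapply(m[5:12], `[[`, character(1), "target_mode"),
               rep("adjust", 8))
  # volume: 3 sets to microcycle 5, 4 sets from microcycle 6
  expect_equal(vapply(m[1:5], function(x) sum(x$sets$sets), numeric(1)),
               rep(3, 5))
  expect_equal(vapply(m[6:12], function(x) sum(x$sets$sets), numeric(1)),
               rep(4, 7))
  # mixed-velocity transition 3+1 / 2+2 / 1+3, then all 90 deg/s
  expect_equal(m[[7]]$sets$sets, c(3, 1))
  expect_equal(m[[8]]$sets$sets, c(2, 2))
  expect_equal(m[[9]]$sets$sets, c(1, 3))
  expect_true(all(vapply(m[10:12], function(x) all(x$sets$velocity_dps == 90),
                         logical(1))))
  expect_error(build_initial_macrocycle(list(sessions_per_week = 0)),
               class = "ep_invalid_config")
})

test_that("per-session repetition volume is 30 then 40", {
  sp <- session_prescriptions(build_initial_macrocycle())
  reps <- vapply(sp, function(s) sum(s$sets$reps), numeric(1))
  micro <- vapply(sp, `[[`, numeric(1), "microcycle_index")
  expect_equal(reps[micro <= 5], rep(30, 10))
  expect_equal(reps[micro >= 6], rep(40, 14))
  # mixed sessions order 60 deg/s sets before 90 deg/s sets
  for (s in sp) expect_true(!is.unsorted(s$sets$velocity_dps))
})

test_that("velocity is non-decreasing across the progression phase", {
  plan <- build_initial_macrocycle()
  frac90 <- vapply(plan$microcycles[4:12], function(m) {
    sum(m$sets$sets[m$sets$velocity_dps == 90]) / sum(m$sets$sets)
  }, numeric(1))
  expect_true(!is.unsorted(frac90))
})

test_that("revised macrocycle places active recovery at positions 8 and 14", {
  plan <- build_revised_macrocycle()
  phases <- vapply(plan$microcycles, `[[`, character(1), "phase")
  expect_length(phases, 14)
  expect_equal(which(phases == "active_recovery"), c(8L, 14L))
  expect_equal(sum(phases != "active_recovery"), 12)
  meso <- vapply(plan$microcycles, `[[`, character(1), "mesocycle")
  expect_equal(meso[4:8], rep("2A", 5))
  expect_equal(meso[9:14], rep("2B", 6))
  expect_equal(vapply(plan$microcycles, `[[`, numeric(1), "index"), 1:14)
})

test_that("recovery insertion reproduces the revised topology and is idempotent", {
  initial <- build_initial_macrocycle()
  revised <- recommend_recovery(initial)
  phases <- vapply(revised$microcycles, `[[`, character(1), "phase")
  expect_equal(which(phases == "active_recovery"), c(8L, 14L))
  # training-session count preserved
  expect_equal(sum(schedule_sessions(revised, "2020-01-06")$is_training), 24)
  # idempotent
  again <- recommend_recovery(revised)
  expect_identical(again, revised)
  # a plan with no progression microcycles is unchanged
  flat <- initial
  flat$microcycles <- flat$microcycles[1:3]
  expect_identical(recommend_recovery(flat), flat)
})

test_that("scheduling yields 24 training sessions with rest days for any start date", {
  plan <- build_initial_macrocycle()
  sched <- schedule_sessions(plan, "2020-01-06")
  expect_equal(nrow(sched), 24)
  expect_true(all(sched$is_training))
  expect_lte(as.numeric(max(sched$date) - min(sched$date)), 12 * 7 - 1)
  # property: rest-day constraint holds across 366 start dates
  dates <- as.Date("2020-01-01") + 0:365
  ok <- vapply(dates, function(d) {
    s <- schedule_sessions(plan, d)
    min(diff(as.numeric(s$date))) >= plan$min_rest_days + 1
  }, logical(1))
  expect_true(all(ok))
  expect_error(
    schedule_sessions(build_initial_macrocycle(list(sessions_per_week = 4)),
                      "2020-01-06"),
    class = "ep_scheduling_failure")
})

test_that("revised plan schedules recovery sessions per policy", {
  light <- schedule_sessions(build_revised_macrocycle(), "2020-01-06")
  expect_equal(sum(light$is_training), 24)
  expect_equal(sum(!light$is_training), 4) # two light sessions x two weeks
  rest <- schedule_sessions(
    build_revised_macrocycle(list(recovery_policy = "rest")), "2020-01-06")
  expect_equal(nrow(rest), 24)
})

test_that("prescription state machine issues fixed targets then the 5% chain", {
  plan <- build_initial_macrocycle()
  st <- plan_state(plan, ecc_peak = 200)
  targets <- numeric(0)
  dec <- NULL
  for (i in 1:24) {
    np <- next_prescription(st, dec)
    st <- np$state
    targets[i] <- np$prescription$target_percent
    dec <- adjust_workload(np$prescription$target_torque, "compliant")
  }
  # microcycle 1 sessions: 40 and 50; microcycles 2-4 fixed
  expect_equal(targets[1:2], c(40, 50))
  expect_equal(targets[3:4], c(50, 50))
  expect_equal(targets[5:6], c(60, 60))
  expect_equal(targets[7:8], c(70, 70))
  # geometric 5% chain seeded from the attained 70% of microcycle 4
  expect_equal(targets[9:24], 70 * 1.05^(1:16), tolerance = 1e-9)
  expect_error(next_prescription(st, dec), class = "ep_plan_exhausted")
})

test_that("moderate and excessive decisions hold or lower the chained target", {
  plan <- build_initial_macrocycle()
  st <- plan_state(plan, ecc_peak = 200)
  dec <- NULL
  targets <- numeric(0)
  classes <- rep(c("compliant", "excessive", "moderate"), length.out = 24)
  for (i in 1:24) {
    np <- next_prescription(st, dec)
    st <- np$state
    targets[i] <- np$prescription$target_percent
    dec <- adjust_workload(np$prescription$target_torque, classes[i])
  }
  # session 8 (fixed 70%) was excessive -> session 9 opens at 70 x 0.95;
  # session 9 moderate -> 10 holds; session 10 compliant -> 11 rises
  expect_equal(targets[9], 70 * 0.95)
  expect_equal(targets[10], targets[9])
  expect_equal(targets[11], 70 * 0.95 * 1.05)
})

test_that("recovery sessions prescribe half the current target outside the chain", {
  plan <- build_revised_macrocycle()
  st <- plan_state(plan, ecc_peak = 200)
  dec <- NULL
  targets <- numeric(0)
  is_rec <- logical(0)
  for (i in seq_along(st$prescriptions)) {
    np <- next_prescription(st, dec)
    st <- np$state
    p <- np$prescription
    targets[i] <- p$target_percent
    is_rec[i] <- p$phase == "active_recovery"
    if (!is_rec[i]) dec <- adjust_workload(p$target_torque, "moderate")
  }
  expect_equal(sum(is_rec), 4)
  # under all-moderate decisions the chain stays at 70; recovery at 35
  expect_equal(unique(targets[is_rec]), 35)
  # chain resumes unchanged after recovery
  expect_equal(targets[!is_rec][targets[!is_rec] > 60], rep(70, 18))
})
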