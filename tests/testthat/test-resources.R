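test_that("single-pathway minutes match the worked example", {
  sch <- resource_schedule()
  m <- midwife_minutes_for_pathway(8, 4, 1, oxytocin = FALSE, schedule = sch)
  expect_equal(unname(m["ve"]), 20)    # entry exam + one completed 4-h interval
  expect_equal(unname(m["vsm"]), 12)   # pre-active hours 4 and 8, stage 1, stage 2
  expect_equal(unname(m["oxytocin_setup"]), 0)
  expect_equal(sum(m), 32)

  zero <- midwife_minutes_for_pathway(0, 0, 0, FALSE, sch)
  expect_equal(sum(zero), 10)          # the entry examination still fires

  oxy <- midwife_minutes_for_pathway(8, 4, 1, oxytocin = TRUE, schedule = sch)
  expect_gt(sum(oxy), sum(m))          # 3-h VE interval + two-midwife set-up
  expect_equal(unname(oxy["oxytocin_setup"]), 20)
})

test_that("closed-form interval counts equal brute-force hour-by-hour enumeration", {
  sch <- resource_schedule()
  set.seed(42)
  for (i in 1:50) {
    pre <- round(runif(1, 0, 30), 2)
    a1 <- round(runif(1, 0, 12), 2)
    a2 <- sample(0:2, 1)
    oxy <- runif(1) < 0.5
    expect_equal(
      midwife_minutes_for_pathway(pre, a1, a2, oxy, sch),
      enumerate_pathway_minutes(pre, a1, a2, oxy, sch),
      info = sprintf("pre=%g a1=%g a2=%g oxy=%s", pre, a1, a2, oxy)
    )
  }
})

test_that("workload is linear in cohort size and monotone in every schedule parameter", {
  cv <- calibrate_strata()$dvi_parous
  mk <- function(n) run_cohort(stratum_profile("DVI", "parous", n, cv,
                                               oxytocin_prob = 0.75,
                                               oxytocin_duration_h = 14))
  w1 <- aggregate_workload(list(mk(100)))
  w2 <- aggregate_workload(list(mk(200)))
  expect_equal(w2$minutes_by_activity, 2 * w1$minutes_by_activity,
               tolerance = 1e-9)
  expect_equal(w2$shifts_total, 2 * w1$shifts_total, tolerance = 1e-9)
  expect_equal(w2$bed_hours, 2 * w1$bed_hours, tolerance = 1e-9)

  tr <- list(mk(100))
  base <- aggregate_workload(tr)$minutes_total
  # longer durations => more minutes
  for (arg in c("ve_duration_min", "vsm_duration_min",
                "oxy_setup_min_per_midwife")) {
    args <- list(); args[[arg]] <- 15
    up <- aggregate_workload(tr, do.call(resource_schedule, args))
    expect_gt(up$minutes_total, base)
  }
  # shorter intervals => more events => more minutes
  for (arg in c("ve_interval_active_h", "ve_interval_active_oxy_h",
                "vsm_interval_pre_h", "vsm_interval_stage1_h",
                "vsm_interval_stage2_h")) {
    args <- list(); args[[arg]] <- 0.5
    up <- aggregate_workload(tr, do.call(resource_schedule, args))
    expect_gt(up$minutes_total, base)
  }
})

test_that("per-activity shifts sum to the total exactly", {
  for (arm in c("DVI", "MVI")) {
    w <- aggregate_workload(base_traces()[[arm]])
    expect_equal(sum(w$shifts_by_activity), w$shifts_total)
    expect_equal(sum(w$minutes_by_activity), w$minutes_total)
  }
})

test_that("bed occupancy: unit case, rounding and additivity", {
  inflow <- numeric(30); inflow[24] <- 1   # delivery during cycle 23
  tr <- new_cohort_trace(inflow, n_women = 1)
  occ <- bed_occupancy(list(tr))
  expect_equal(occ$bed_hours, 24)          # cycles 0..23 in the suite
  expect_equal(occ$bed_days, 1)

  dvi <- base_traces()$DVI; mvi <- base_traces()$MVI
  saving_total <- bed_occupancy(dvi)$bed_hours - bed_occupancy(mvi)$bed_hours
  saving_sum <- sum(vapply(c("parous", "nulliparous"), function(p) {
    bed_occupancy(dvi[p])$bed_hours - bed_occupancy(mvi[p])$bed_hours
  }, numeric(1)))
  expect_equal(saving_total, saving_sum)
})

test_that("capacity gain arithmetic and guards", {
  expect_equal(capacity_gain(0, 25), 0)
  expect_equal(capacity_gain(100, 25), 4)
  expect_equal(capacity_gain(99.9, 25), 3)
  expect_error(capacity_gain(100, 0), class = "inductmod_config_error")
})

test_that("births-per-midwife adjustment", {
  expect_equal(births_per_midwife_adjusted(33, 0), 33)
  expect_equal(round(births_per_midwife_adjusted(33, 0.274), 1), 24.0)
  expect_equal(births_per_midwife_adjusted(30, 0.5), 15)
  expect_error(births_per_midwife_adjusted(33, 1),
               class = "inductmod_domain_error")
})

test_that("invalid schedules are rejected", {
  expect_error(resource_schedule(ve_duration_min = -1),
               class = "inductmod_config_error")
  expect_error(resource_schedule(vsm_interval_pre_h = 0),
               class = "inductmod_config_error")
})
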