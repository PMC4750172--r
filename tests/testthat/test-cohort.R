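test_that("traces conserve mass and keep cumulative delivery columns monotone", {
  for (arm in c("DVI", "MVI")) {
    for (tr in base_traces()[[arm]]) {
      n <- attr(tr, "n_women")
      loc <- tr[, c("pre_active", "active_stage1", "active_stage2",
                    "inpatient", "discharged")]
      expect_true(all(abs(rowSums(loc) - n) < 1e-9))
      expect_true(all(loc >= -1e-12))
      expect_true(all(diff(tr[, "delivered_vaginal"]) >= -1e-12))
      expect_true(all(diff(tr[, "delivered_caesarean"]) >= -1e-12))
      expect_true(all(diff(tr[, "discharged"]) >= -1e-12))
      # delivered women are exactly the inpatient + discharged occupancy
      expect_equal(unname(tr[, "delivered_vaginal"] + tr[, "delivered_caesarean"]),
                   unname(tr[, "inpatient"] + tr[, "discharged"]),
                   tolerance = 1e-9)
    }
  }
})

test_that("cumulative vaginal deliveries reproduce the calibrated curve", {
  for (key in names(calibrate_strata())) {
    cv <- calibrate_strata()[[key]]
    arm <- toupper(sub("_.*", "", key))
    parity <- sub(".*_", "", key)
    tr <- base_traces()[[arm]][[parity]]
    n <- attr(tr, "n_women")
    for (t in c(6, 12, 24, 48)) {
      expect_equal(unname(tr[t + 1, "delivered_vaginal"]) / n,
                   curve_cdf(cv, t), tolerance = 1e-9)
    }
    # residual undelivered mass at the horizon below 0.1 %
    expect_lt(abs(tr[nrow(tr), "delivered_vaginal"] / n - cv$mass), 1e-3)
  }
})

test_that("exponential curves give the closed-form geometric trace", {
  rate <- 0.1; m_vd <- 0.7; n <- 100
  pf <- exponential_profile(rate, m_vd, n)
  tr <- run_cohort(pf, horizon = 200)
  q <- 1 - exp(-rate)                      # per-cycle delivery probability
  cycles <- 0:30
  # geometric closed form: inflow_vd(t) = n * m_vd * q * (1-q)^t
  expect_equal(attr(tr, "inflow_vd")[cycles + 1],
               n * m_vd * q * (1 - q)^cycles, tolerance = 1e-12)
  expect_equal(unname(tr[cycles + 1, "delivered_vaginal"]),
               n * m_vd * (1 - (1 - q)^cycles), tolerance = 1e-12)
})

test_that("traces are additive in cohort size", {
  cv <- calibrate_strata()$dvi_parous
  mk <- function(n) run_cohort(
    stratum_profile("DVI", "parous", n, cv, oxytocin_prob = 0.75,
                    oxytocin_duration_h = 14))
  t100 <- mk(100); t41 <- mk(41); t141 <- mk(141)
  expect_equal(unclass(t141), unclass(t100) + unclass(t41), tolerance = 1e-9,
               ignore_attr = TRUE)
  # arm-level resource aggregation over separate strata equals their sum
  tra <- base_traces()$DVI
  both <- bed_occupancy(tra)
  expect_equal(both$bed_hours,
               bed_occupancy(tra["parous"])$bed_hours +
                 bed_occupancy(tra["nulliparous"])$bed_hours)
})

test_that("vanishing transition probabilities keep the cohort in pre-active labour", {
  tiny <- parametric_curve("weibull", c(shape = 2, scale = 20), mass = 1e-10)
  pf <- stratum_profile("DVI", "parous", 50, tiny,
                        cs_curve = parametric_curve("weibull",
                                                    c(shape = 2, scale = 20),
                                                    mass = 1e-10))
  expect_error(run_cohort(pf, horizon = 60),
               class = "inductmod_horizon_error")
  tr <- run_cohort(pf, horizon = 60, residual_threshold = 1)
  expect_true(all(abs(tr[, "pre_active"] - 50) < 1e-6))
  expect_lt(tr[61, "delivered_vaginal"], 1e-7)
})

test_that("effectiveness summaries: point mass, discretisation bound, error cases", {
  inflow <- numeric(40); inflow[11] <- 25    # all deliveries during cycle 10
  tr <- new_cohort_trace(inflow, n_women = 25)
  s <- effectiveness_summary(tr)
  expect_equal(s$mean_time_to_vd_h, 10.5)
  expect_equal(s$median_time_to_vd_h, 10.5)
  expect_equal(s$total_hours_to_vd, 25 * 10.5)

  # discrete trace summaries track the continuous curve within half a cycle
  cv <- calibrate_strata()$dvi_parous
  tr <- base_traces()$DVI$parous
  disc <- effectiveness_summary(tr)
  cont <- curve_summary(cv)
  expect_lt(abs(disc$mean_time_to_vd_h - cont$mean_h), 0.5)
  expect_lt(abs(disc$median_time_to_vd_h - cont$median_h), 0.5)

  empty <- new_cohort_trace(numeric(10), n_women = 5)
  expect_error(effectiveness_summary(empty),
               class = "inductmod_undefined_summary")
})

test_that("compare_arms: self-comparison is exactly zero and strata must match", {
  tra <- base_traces()$DVI
  self <- compare_arms(tra, tra)
  expect_identical(self$clinical$hours_saved, 0)
  expect_identical(self$clinical$per_induction_saving_h, 0)
  expect_equal(unname(self$clinical$prolonged_labour["DVI"]),
               unname(self$clinical$prolonged_labour["MVI"]))

  expect_error(compare_arms(tra, tra["parous"]), "mismatched strata")
  small <- run_cohort(stratum_profile("MVI", "parous", 10,
                                      calibrate_strata()$mvi_parous))
  expect_error(compare_arms(tra["parous"], list(parous = small)),
               "composition differs")
})
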