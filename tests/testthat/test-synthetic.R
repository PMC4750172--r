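base_profiles <- function() build_profiles(default_config())

test_that("the same seed reproduces a cohort byte-identically", {
  pf <- base_profiles()$dvi_parous
  a <- sample_cohort(pf, 500, seed = 11)
  b <- sample_cohort(pf, 500, seed = 11)
  expect_identical(a, b)
  c_ <- sample_cohort(pf, 500, seed = 12)
  expect_false(identical(a$time_to_delivery_h, c_$time_to_delivery_h))
  # scoped RNG: the global stream is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sample_cohort(pf, 10, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("empirical fractions match the generating curves within 3 binomial SEs", {
  pf <- base_profiles()$dvi_parous
  n <- 1e5
  coh <- sample_cohort(pf, n, seed = 2024)
  p12 <- mean(coh$outcome == "vaginal" & coh$time_to_delivery_h <= 12)
  se12 <- sqrt(0.183 * (1 - 0.183) / n)
  expect_lt(abs(p12 - 0.183), 3 * se12)
  pvag <- mean(coh$outcome == "vaginal")
  expect_lt(abs(pvag - pf$vd_curve$mass), 3 * sqrt(0.729 * 0.271 / n))
  poxy <- mean(coh$oxytocin)
  expect_lt(abs(poxy - 0.75), 3 * sqrt(0.75 * 0.25 / n))

  # exponential special case: empirical mean within 3 SEs of 1/lambda
  expo <- stratum_profile("MVI", "parous", 1,
                          parametric_curve("weibull", c(shape = 1, scale = 8),
                                           mass = 1))
  ce <- sample_cohort(expo, n, seed = 7)
  expect_lt(abs(mean(ce$time_to_delivery_h) - 8), 3 * 8 / sqrt(n))
})

test_that("uncalibrated profiles are rejected by the sampler", {
  partial <- stratum_profile("DVI", "parous", 10,
                             parametric_curve("weibull",
                                              c(shape = 2, scale = 20),
                                              mass = 0.5),
                             cs_curve = parametric_curve(
                               "weibull", c(shape = 2, scale = 20), mass = 0.1))
  expect_error(sample_cohort(partial, 10, seed = 1),
               class = "inductmod_dependency_error")
})

test_that("cumulative-incidence estimates handle degenerate strata", {
  one <- structure(
    data.frame(id = 1L, arm = "DVI", parity = "parous", outcome = "vaginal",
               time_to_delivery_h = 10, oxytocin = FALSE,
               oxytocin_duration_h = 0),
    class = c("synthetic_cohort", "data.frame"))
  km <- km_estimate(one)
  expect_equal(km$cif_vaginal, c(0, 1))
  expect_equal(km$time, c(0, 10))

  allcs <- structure(
    data.frame(id = 1:5, arm = "DVI", parity = "parous", outcome = "caesarean",
               time_to_delivery_h = c(3, 9, 14, 20, 30), oxytocin = FALSE,
               oxytocin_duration_h = 0),
    class = c("synthetic_cohort", "data.frame"))
  km <- km_estimate(allcs)
  expect_true(all(km$cif_vaginal == 0))
  expect_equal(max(km$cif_caesarean), 1)

  expect_error(km_estimate(allcs, arm = "MVI"), "no records")
})

test_that("km estimate equals a counting oracle and converges to the generating curve", {
  pf <- base_profiles()$mvi_nulliparous
  coh <- sample_cohort(pf, 500, seed = 5)
  km <- km_estimate(coh)
  # no censoring: the Aalen-Johansen estimate is the empirical sub-ecdf
  for (t in c(6, 12, 24, 40)) {
    emp <- mean(coh$outcome == "vaginal" & coh$time_to_delivery_h <= t)
    est <- km$cif_vaginal[max(which(km$time <= t))]
    expect_equal(est, emp, tolerance = 1e-12)
  }

  big <- sample_cohort(pf, 1e5, seed = 31)
  kmb <- km_estimate(big)
  grid <- seq(0.5, 72, by = 0.5)
  est <- vapply(grid, function(t) kmb$cif_vaginal[max(which(kmb$time <= t))],
                numeric(1))
  expect_lt(max(abs(est - curve_cdf(pf$vd_curve, grid))), 0.02)
})

test_that("curve refit to synthetic summary anchors recovers the generating parameters", {
  pf <- base_profiles()$dvi_parous
  coh <- sample_cohort(pf, 1e5, seed = 17)
  p12 <- mean(coh$outcome == "vaginal" & coh$time_to_delivery_h <= 12)
  p24 <- mean(coh$outcome == "vaginal" & coh$time_to_delivery_h <= 24)
  refit <- fit_curve_to_anchors(
    summary_anchors("DVI", "parous", p12, p24,
                    cs_total = 1 - pf$vd_curve$mass))
  expect_equal(unname(refit$params[["shape"]]),
               unname(pf$vd_curve$params[["shape"]]), tolerance = 0.05)
  expect_equal(unname(refit$params[["scale"]]),
               unname(pf$vd_curve$params[["scale"]]), tolerance = 0.05)
})

test_that("microsim agreement: large n agrees, small n is underpowered, wrong curve is flagged", {
  pf <- base_profiles()$mvi_parous
  tr <- run_cohort(pf)
  coh <- sample_cohort(pf, 5e4, seed = 123)
  rep <- microsim_vs_cohort(coh, tr)
  expect_true(attr(rep, "agreement"))
  expect_false(any(rep$flagged))

  tiny <- sample_cohort(pf, 10, seed = 1)
  rep10 <- microsim_vs_cohort(tiny, tr)
  expect_true(attr(rep10, "underpowered"))
  expect_true(all(is.na(rep10$flagged)))

  # constructed counterexample: cohort drawn from a visibly slower curve
  wrong <- pf
  wrong$vd_curve <- parametric_curve("weibull",
                                     c(shape = pf$vd_curve$params[["shape"]],
                                       scale = pf$vd_curve$params[["scale"]] * 1.3),
                                     mass = pf$vd_curve$mass)
  wrong$cs_curve <- parametric_curve("weibull", wrong$vd_curve$params,
                                     mass = 1 - pf$vd_curve$mass)
  bad <- sample_cohort(wrong, 5e4, seed = 123)
  repbad <- microsim_vs_cohort(bad, tr)
  expect_true(any(repbad$flagged))

  # stratum mismatch is a configuration error
  other <- sample_cohort(base_profiles()$dvi_parous, 100, seed = 1)
  expect_error(microsim_vs_cohort(other, tr),
               class = "inductmod_config_error")
})
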