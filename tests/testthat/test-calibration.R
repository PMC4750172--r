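test_that("weibull fit recovers known generating parameters", {
  gen <- parametric_curve("weibull", c(shape = 2, scale = 20), mass = 1)
  an <- summary_anchors("DVI", "parous",
                        p_vd_12h = curve_cdf(gen, 12),
                        p_vd_24h = curve_cdf(gen, 24),
                        cs_total = 0)
  fit <- fit_curve_to_anchors(an, "weibull")
  expect_equal(unname(fit$params[["shape"]]), 2, tolerance = 1e-6)
  expect_equal(unname(fit$params[["scale"]]), 20, tolerance = 1e-6)
})

test_that("calibrated curves pass through the printed anchors for every stratum and family", {
  for (an in published_anchors()) {
    for (fam in c("weibull", "log_logistic", "piecewise_exponential")) {
      cv <- fit_curve_to_anchors(an, fam)
      expect_equal(cv$mass, 1 - an$cs_total)
      expect_lt(abs(curve_cdf(cv, 12) - an$p_vd_12h), 1e-8)
      expect_lt(abs(curve_cdf(cv, 24) - an$p_vd_24h), 1e-8)
      expect_equal(curve_cdf(cv, 0), 0)
      # non-decreasing, plateaus at the sub-distribution mass
      Ft <- curve_cdf(cv, seq(0, 400, by = 0.5))
      expect_true(all(diff(Ft) >= -1e-12))
      expect_equal(curve_cdf(cv, 1e5), cv$mass, tolerance = 1e-6)
    }
  }
})

test_that("bisection solution matches the closed-form oracle for the parous DVI stratum", {
  an <- published_anchors()$dvi_parous
  oracle <- oracle_weibull_fit(an$p_vd_12h, an$p_vd_24h, an$mass)
  fit <- fit_curve_to_anchors(an, "weibull")
  expect_equal(unname(fit$params[["shape"]]), oracle$shape, tolerance = 1e-6)
  expect_equal(unname(fit$params[["scale"]]), oracle$scale, tolerance = 1e-6)
  # oracle = direct CDF re-evaluation at the anchor times
  F12 <- an$mass * (1 - exp(-(12 / oracle$scale)^oracle$shape))
  expect_equal(F12, 0.183, tolerance = 1e-10)
})

test_that("infeasible or degenerate anchors raise calibration errors", {
  expect_error(summary_anchors("DVI", "parous", 0.6, 0.5, 0.1),
               class = "inductmod_calibration_infeasible")
  expect_error(summary_anchors("DVI", "parous", 0.2, 0.9, 0.271),
               class = "inductmod_calibration_infeasible")
  expect_error(summary_anchors("DVI", "parous", 0.1, 0.2, 1.0),
               class = "inductmod_calibration_infeasible")
  # a zero first anchor leaves the fit under-determined
  an0 <- summary_anchors("DVI", "parous", 0, 0.5, 0.2)
  expect_error(fit_curve_to_anchors(an0), class = "inductmod_calibration_infeasible")
})

test_that("hourly transition probabilities follow the conditional-increment identity", {
  lambda <- 0.08
  expo <- parametric_curve("weibull", c(shape = 1, scale = 1 / lambda), mass = 1)
  p <- hourly_transition_probabilities(expo, 40)
  expect_equal(p, rep(1 - exp(-lambda), 40), tolerance = 1e-12)

  cv <- fit_curve_to_anchors(published_anchors()$dvi_parous)
  p <- hourly_transition_probabilities(cv, 120)
  # direct CDF arithmetic as oracle at t = 12
  expect_equal(p[13], (curve_cdf(cv, 13) - curve_cdf(cv, 12)) /
                        (1 - curve_cdf(cv, 12)))
  expect_true(all(p >= 0 & p < 1))
  # telescoping: mass delivered through the hourly probabilities = F(horizon)
  delivered <- 1 - prod(1 - p)
  expect_equal(delivered, curve_cdf(cv, 120), tolerance = 1e-9)
  # sub-distribution plateau: hazard dies out as F -> mass < 1
  expect_lt(p[120], 1e-6)
})

test_that("a curve that saturates before the horizon raises an absorbed-state error", {
  hot <- parametric_curve("piecewise_exponential",
                          c(break1 = 5, rate1 = 50, rate2 = 50), mass = 1)
  expect_error(hourly_transition_probabilities(hot, 24),
               class = "inductmod_numerical_error")
})

test_that("curve summaries: closed forms and among-delivered normalisation", {
  expo <- parametric_curve("weibull", c(shape = 1, scale = 10), mass = 1)
  s <- curve_summary(expo)
  expect_equal(s$median_h, 10 * log(2), tolerance = 1e-12)
  expect_equal(s$mean_h, 10, tolerance = 1e-12)

  # the same summaries are invariant to the sub-distribution mass
  sub <- parametric_curve("weibull", c(shape = 1, scale = 10), mass = 0.5)
  expect_equal(curve_summary(sub), s)

  # piecewise exponential with equal rates collapses to the exponential
  pw <- parametric_curve("piecewise_exponential",
                         c(break1 = 5, rate1 = 0.1, rate2 = 0.1), mass = 1)
  spw <- curve_summary(pw)
  expect_equal(spw$median_h, 10 * log(2), tolerance = 1e-8)
  expect_equal(spw$mean_h, 10, tolerance = 1e-6)

  expect_error(parametric_curve("weibull", c(shape = 1, scale = 10), mass = 0))
})

test_that("weibull and log-logistic fits agree at the anchors and differ between them", {
  an <- published_anchors()$mvi_nulliparous
  wb <- fit_curve_to_anchors(an, "weibull")
  ll <- fit_curve_to_anchors(an, "log_logistic")
  expect_equal(curve_cdf(wb, 12), curve_cdf(ll, 12), tolerance = 1e-8)
  expect_equal(curve_cdf(wb, 24), curve_cdf(ll, 24), tolerance = 1e-8)
  expect_gt(max(abs(curve_cdf(wb, c(6, 18, 48)) - curve_cdf(ll, c(6, 18, 48)))),
            1e-4)
})
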