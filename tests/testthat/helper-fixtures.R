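# Shared fixtures: the published per-stratum anchors and small oracles that
# are kept independent of the package's own solvers.

published_anchors <- function() {
  list(
    dvi_parous = summary_anchors("DVI", "parous", 0.183, 0.543, 0.271),
    dvi_nulliparous = summary_anchors("DVI", "nulliparous", 0.016, 0.131, 0.271),
    mvi_parous = summary_anchors("MVI", "parous", 0.356, 0.700, 0.260),
    mvi_nulliparous = summary_anchors("MVI", "nulliparous", 0.059, 0.271, 0.260)
  )
}

# closed-form two-anchor Weibull solution on the conditional scale:
# (t1/s)^k = -log(1 - g1), (t2/s)^k = -log(1 - g2) => k from the log-ratio
oracle_weibull_fit <- function(p12, p24, mass, t1 = 12, t2 = 24) {
  u1 <- -log(1 - p12 / mass)
  u2 <- -log(1 - p24 / mass)
  shape <- log(u2 / u1) / log(t2 / t1)
  scale <- t1 / u1^(1 / shape)
  list(shape = shape, scale = scale)
}

# hour-by-hour brute force for completed-interval event counts: an event
# fires at every whole multiple of `interval` elapsed within the state
enumerate_interval_events <- function(duration_h, interval_h) {
  if (duration_h < interval_h) return(0L)
  length(seq(interval_h, duration_h + 1e-9, by = interval_h))
}

enumerate_pathway_minutes <- function(pre, a1, a2, oxy, schedule) {
  ve_int <- if (oxy) schedule$ve_interval_active_oxy_h
            else schedule$ve_interval_active_h
  ve <- (1 + enumerate_interval_events(a1 + a2, ve_int)) *
    schedule$ve_duration_min
  vsm <- (enumerate_interval_events(pre, schedule$vsm_interval_pre_h) +
          enumerate_interval_events(a1, schedule$vsm_interval_stage1_h) +
          enumerate_interval_events(a2, schedule$vsm_interval_stage2_h)) *
    schedule$vsm_duration_min
  setup <- if (oxy) {
    schedule$oxy_setup_midwives * schedule$oxy_setup_min_per_midwife
  } else 0
  c(ve = ve, vsm = vsm, oxytocin_setup = setup)
}

base_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(default_config(), mode = "base")
    cache
  }
})

base_traces <- function() base_report()$traces

# single-stratum exponential profile with vaginal and caesarean masses that
# share one hourly rate; closed-form geometric dynamics
exponential_profile <- function(rate = 0.1, mass_vd = 0.7, n = 100) {
  vd <- parametric_curve("weibull", c(shape = 1, scale = 1 / rate),
                         mass = mass_vd)
  cs <- parametric_curve("weibull", c(shape = 1, scale = 1 / rate),
                         mass = 1 - mass_vd)
  stratum_profile("DVI", "parous", n, vd, cs_curve = cs,
                  oxytocin_prob = 0.5, oxytocin_duration_h = 14)
}
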