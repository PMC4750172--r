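trace_states <- c("pre_active", "active_stage1", "active_stage2",
                  "inpatient", "discharged",
                  "delivered_vaginal", "delivered_caesarean")

#' Clinical profile of one arm-by-parity stratum
#'
#' Everything the Markov engine needs for one stratum: cohort size, the
#' calibrated vaginal-delivery cumulative-incidence curve, the competing
#' caesarean curve, the oxytocin augmentation probability and duration, the
#' active-labour duration and the postnatal inpatient stay.
#'
#' @param arm,parity Stratum labels (`"DVI"`/`"MVI"`, `"parous"`/`"nulliparous"`).
#' @param n_women Number of women induced in the stratum (`>= 0`).
#' @param vd_curve Calibrated [parametric_curve()] for time to vaginal
#'   delivery (sub-distribution).
#' @param cs_curve Curve for time to caesarean section. Default `NULL`
#'   rescales the vaginal-delivery curve to the caesarean mass
#'   (`1 - vd_curve$mass`), i.e. caesareans share the timing shape of
#'   vaginal deliveries — an assumption, flagged in every report.
#' @param oxytocin_prob Probability of oxytocin augmentation, fixed at
#'   induction (cycle 0) and constant over time.
#' @param oxytocin_duration_h Mean duration of oxytocin administration in
#'   hours (reported; informs the continuous-monitoring scenario context).
#' @param inpatient_stay_h Deterministic delivery-to-discharge stay, hours.
#' @param active_labour_h Total time spent in active labour before
#'   delivery, in whole hours: the final hour is the second stage, the
#'   remainder the first stage. Women are scheduled backwards from their
#'   delivery cycle, so the calibrated delivery-time distribution is
#'   preserved exactly. Default 5 (4 h first stage + 1 h second stage).
#'
#' @return An object of class `stratum_profile`.
#' @export
stratum_profile <- function(arm, parity, n_women, vd_curve, cs_curve = NULL,
                            oxytocin_prob = 0, oxytocin_duration_h = 0,
                            inpatient_stay_h = 24, active_labour_h = 5) {
  arm <- match.arg(arm, c("DVI", "MVI"))
  parity <- match.arg(parity, c("parous", "nulliparous"))
  stopifnot(inherits(vd_curve, "parametric_curve"),
            n_women >= 0,
            oxytocin_prob >= 0, oxytocin_prob <= 1,
            oxytocin_duration_h >= 0, inpatient_stay_h >= 0,
            active_labour_h >= 1, active_labour_h == round(active_labour_h))
  if (is.null(cs_curve)) {
    cs_mass <- 1 - vd_curve$mass
    cs_curve <- if (cs_mass > 0) {
      parametric_curve(vd_curve$family, vd_curve$params, mass = cs_mass)
    } else NULL
  }
  if (!is.null(cs_curve)) {
    stopifnot(inherits(cs_curve, "parametric_curve"))
    if (vd_curve$mass + cs_curve$mass > 1 + 1e-9) {
      stop("vd_curve and cs_curve masses exceed 1")
    }
  }
  structure(
    list(arm = arm, parity = parity, n_women = n_women,
         vd_curve = vd_curve, cs_curve = cs_curve,
         oxytocin_prob = oxytocin_prob,
         oxytocin_duration_h = oxytocin_duration_h,
         inpatient_stay_h = inpatient_stay_h,
         active_labour_h = as.integer(active_labour_h)),
    class = "stratum_profile"
  )
}

#' Low-level cohort trace constructor
#'
#' Builds the state-occupancy matrix from per-cycle delivery inflows.
#' [run_cohort()] derives the inflows from calibrated curves; this
#' constructor is exposed so that traces with arbitrary delivery-time
#' distributions (e.g. a point mass) can be built directly.
#'
#' Women delivering during cycle `d` occupy the second stage of active
#' labour during cycle `d`, the first stage during the
#' `active_labour_h - 1` preceding cycles, and pre-active labour before
#' that (truncated at induction); they then spend `inpatient_stay_h` cycles
#' as inpatients before discharge. `delivered_vaginal` and
#' `delivered_caesarean` are cumulative event counters (women delivered by
#' the start of cycle `t`); the five location states partition the cohort.
#'
#' @param inflow_vd,inflow_cs Numeric vectors (length = horizon): expected
#'   number of women delivering vaginally / by caesarean during each cycle.
#' @param n_women Stratum size; must be at least the total inflow. Any
#'   remainder stays in pre-active labour for the whole horizon.
#' @param active_labour_h,inpatient_stay_h See [stratum_profile()].
#' @param oxytocin_prob Share of the stratum on oxytocin (carried as an
#'   attribute; occupancy of the oxytocin sub-cohort is this multiple of
#'   the total because transition probabilities do not depend on it).
#' @param arm,parity Optional labels.
#' @return A `cohort_trace`: matrix with one row per cycle `0..horizon` and
#'   one column per state.
#' @export
new_cohort_trace <- function(inflow_vd, inflow_cs = NULL, n_women = NULL,
                             active_labour_h = 5, inpatient_stay_h = 24,
                             oxytocin_prob = 0,
                             arm = NA_character_, parity = NA_character_) {
  horizon <- length(inflow_vd)
  if (is.null(inflow_cs)) inflow_cs <- numeric(horizon)
  stopifnot(length(inflow_cs) == horizon,
            all(inflow_vd >= -1e-12), all(inflow_cs >= -1e-12))
  inflow <- inflow_vd + inflow_cs
  if (is.null(n_women)) n_women <- sum(inflow)
  residual <- n_women - sum(inflow)
  if (residual < -1e-9) stop("inflows exceed n_women")
  active_labour_h <- as.integer(active_labour_h)
  stay <- as.integer(round(inpatient_stay_h))

  occ <- matrix(0, nrow = horizon + 1L, ncol = length(trace_states),
                dimnames = list(cycle = 0:horizon, state = trace_states))
  occ[, "pre_active"] <- residual
  for (d in seq_len(horizon) - 1L) {
    m <- inflow[d + 1L]
    if (m == 0) next
    occ[d + 1L, "active_stage2"] <- occ[d + 1L, "active_stage2"] + m
    if (d >= 1L) {
      s1 <- seq.int(max(0L, d - active_labour_h + 1L), d - 1L)
      occ[s1 + 1L, "active_stage1"] <- occ[s1 + 1L, "active_stage1"] + m
    }
    if (d - active_labour_h >= 0L) {
      pre <- seq.int(0L, d - active_labour_h)
      occ[pre + 1L, "pre_active"] <- occ[pre + 1L, "pre_active"] + m
    }
    inp <- seq.int(d + 1L, length.out = stay)
    inp <- inp[inp <= horizon]
    if (length(inp)) occ[inp + 1L, "inpatient"] <- occ[inp + 1L, "inpatient"] + m
    if (d + stay + 1L <= horizon) {
      dis <- seq.int(d + stay + 1L, horizon)
      occ[dis + 1L, "discharged"] <- occ[dis + 1L, "discharged"] + m
    }
  }
  occ[, "delivered_vaginal"] <- cumsum(c(0, inflow_vd))
  occ[, "delivered_caesarean"] <- cumsum(c(0, inflow_cs))

  structure(occ, class = c("cohort_trace", "matrix", "array"),
            n_women = n_women, horizon = horizon,
            inflow_vd = inflow_vd, inflow_cs = inflow_cs,
            oxytocin_prob = oxytocin_prob,
            active_labour_h = active_labour_h,
            inpatient_stay_h = inpatient_stay_h,
            arm = arm, parity = parity)
}

#' Propagate a stratum through the hourly Markov trace
#'
#' Cycle 0 is insert placement. At each cycle the women still at risk
#' (neither delivered vaginally nor by caesarean) transition into delivery
#' with the hourly probabilities implied by the stratum's calibrated
#' curves, conditioned on the joint risk set:
#' `p_vd(t) = (F_vd(t+1) - F_vd(t)) / (1 - F_vd(t) - F_cs(t))` and
#' analogously for caesarean. Telescoping makes the cumulative delivered
#' occupancy reproduce the calibrated curves exactly. The oxytocin
#' sub-cohort is fixed at cycle 0 with probability `oxytocin_prob` and, as
#' all other probabilities are constant over time, scales the trace
#' linearly.
#'
#' @param profile A [stratum_profile()].
#' @param horizon Number of hourly cycles (default 120).
#' @param residual_threshold Maximum tolerated share of the cohort still
#'   undelivered at the horizon (default 0.001); exceeding it raises a
#'   horizon-too-short error.
#' @return A `cohort_trace` (see [new_cohort_trace()]).
#' @export
run_cohort <- function(profile, horizon = 120, residual_threshold = 0.001) {
  stopifnot(inherits(profile, "stratum_profile"), horizon >= 1)
  horizon <- as.integer(horizon)
  tt <- 0:horizon
  Fvd <- curve_cdf(profile$vd_curve, tt)
  Fcs <- if (is.null(profile$cs_curve)) numeric(horizon + 1L)
         else curve_cdf(profile$cs_curve, tt)
  S <- pmax(1 - Fvd - Fcs, 0)
  # once the joint risk set is numerically empty no one is left to move
  alive <- S[seq_len(horizon)] > 1e-12
  p_vd <- p_cs <- numeric(horizon)
  p_vd[alive] <- diff(Fvd)[alive] / S[seq_len(horizon)][alive]
  p_cs[alive] <- diff(Fcs)[alive] / S[seq_len(horizon)][alive]
  p_vd <- pmin(pmax(p_vd, 0), 1)
  p_cs <- pmin(pmax(p_cs, 0), 1)

  # Markov propagation of the at-risk mass; telescopes back to the CDFs
  at_risk <- numeric(horizon + 1L)
  inflow_vd <- inflow_cs <- numeric(horizon)
  at_risk[1L] <- 1
  for (t in seq_len(horizon)) {
    inflow_vd[t] <- at_risk[t] * p_vd[t]
    inflow_cs[t] <- at_risk[t] * p_cs[t]
    at_risk[t + 1L] <- at_risk[t] * (1 - p_vd[t] - p_cs[t])
  }
  if (at_risk[horizon + 1L] > residual_threshold) {
    stop(errorCondition(
      sprintf(paste0("horizon too short: %.3f%% of the %s/%s cohort ",
                     "remains undelivered after %d cycles"),
              100 * at_risk[horizon + 1L], profile$arm, profile$parity, horizon),
      class = c("inductmod_horizon_error", "inductmod_error", "error")
    ))
  }

  trace <- new_cohort_trace(
    inflow_vd * profile$n_women, inflow_cs * profile$n_women,
    n_women = profile$n_women,
    active_labour_h = profile$active_labour_h,
    inpatient_stay_h = profile$inpatient_stay_h,
    oxytocin_prob = profile$oxytocin_prob,
    arm = profile$arm, parity = profile$parity
  )
  attr(trace, "profile") <- profile
  trace
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- attr(x, "n_women")
  cat(sprintf("<cohort_trace> %s/%s: %g women, %d hourly cycles\n",
              attr(x, "arm"), attr(x, "parity"), n, attr(x, "horizon")))
  cum_vd <- x[nrow(x), "delivered_vaginal"]
  cum_cs <- x[nrow(x), "delivered_caesarean"]
  cat(sprintf("  delivered at horizon: %.1f vaginal (%.1f%%), %.1f caesarean (%.1f%%)\n",
              cum_vd, 100 * cum_vd / n, cum_cs, 100 * cum_cs / n))
  invisible(x)
}

#' Clinical effectiveness summary of one trace
#'
#' Mean and median time to vaginal delivery are computed from the discrete
#' delivery-time distribution with the mid-cycle convention (a delivery
#' during cycle `t` is timed at `t + 0.5` h); the median interpolates
#' linearly within the crossing cycle. `prolonged_labour_prop` is the share
#' of the whole stratum without a vaginal delivery within 24 h (women
#' delivered by caesarean count as prolonged). `total_hours_to_vd` is the
#' per-induction mean multiplied by the stratum size, the aggregate-hours
#' convention used for arm comparisons.
#'
#' @param trace A `cohort_trace`.
#' @return An object of class `effectiveness_summary` (a list).
#' @export
effectiveness_summary <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  inflow <- attr(trace, "inflow_vd")
  n <- attr(trace, "n_women")
  total_vd <- sum(inflow)
  if (total_vd <= 0) {
    stop(errorCondition("no vaginal deliveries in trace; summary undefined",
                        class = c("inductmod_undefined_summary",
                                  "inductmod_error", "error")))
  }
  cycles <- seq_along(inflow) - 1L
  mean_h <- sum(inflow * (cycles + 0.5)) / total_vd
  cum <- cumsum(inflow)
  half <- total_vd / 2
  d <- which(cum >= half)[1L]
  below <- if (d == 1L) 0 else cum[d - 1L]
  median_h <- (d - 1L) + (half - below) / inflow[d]
  p12 <- unname(trace[min(13L, nrow(trace)), "delivered_vaginal"]) / n
  p24 <- unname(trace[min(25L, nrow(trace)), "delivered_vaginal"]) / n
  structure(
    list(mean_time_to_vd_h = mean_h,
         median_time_to_vd_h = median_h,
         p_vd_within_12 = p12,
         p_vd_within_24 = p24,
         prolonged_labour_prop = 1 - p24,
         total_hours_to_vd = mean_h * n,
         n_women = n, n_delivered_vaginal = total_vd),
    class = "effectiveness_summary"
  )
}

#' @export
print.effectiveness_summary <- function(x, ...) {
  cat("<effectiveness_summary>\n")
  cat(sprintf("  time to vaginal delivery: mean %.2f h, median %.2f h\n",
              x$mean_time_to_vd_h, x$median_time_to_vd_h))
  cat(sprintf("  vaginal delivery within 12 h: %.1f%%; within 24 h: %.1f%%\n",
              100 * x$p_vd_within_12, 100 * x$p_vd_within_24))
  cat(sprintf("  prolonged labour (>24 h): %.1f%%\n",
              100 * x$prolonged_labour_prop))
  invisible(x)
}

combine_arm <- function(traces) {
  summs <- lapply(traces, effectiveness_summary)
  n <- sum(vapply(summs, `[[`, numeric(1), "n_women"))
  tot <- sum(vapply(summs, `[[`, numeric(1), "total_hours_to_vd"))
  p12 <- sum(vapply(summs, function(s) s$p_vd_within_12 * s$n_women, numeric(1))) / n
  p24 <- sum(vapply(summs, function(s) s$p_vd_within_24 * s$n_women, numeric(1))) / n
  list(per_stratum = summs, n_women = n, total_hours_to_vd = tot,
       mean_time_to_vd_h = tot / n, p_vd_within_12 = p12, p_vd_within_24 = p24,
       prolonged_labour_prop = 1 - p24)
}

#' Compare the clinical-effectiveness block of the two arms
#'
#' Takes one trace per parity stratum for each arm (same strata and cohort
#' composition on both sides) and reports absolute and percentage
#' differences in total and per-induction hours to vaginal delivery, 12- and
#' 24-hour vaginal-delivery proportions (overall and per parity, with
#' MVI:DVI fold ratios), and prolonged-labour proportions.
#'
#' @param dvi_traces,mvi_traces Named lists of `cohort_trace` objects,
#'   one per parity (names `"parous"`, `"nulliparous"`; a single unnamed
#'   trace is also accepted).
#' @return An object of class `comparison_result` with a `clinical` block.
#' @export
compare_arms <- function(dvi_traces, mvi_traces) {
  dvi_traces <- as_trace_list(dvi_traces)
  mvi_traces <- as_trace_list(mvi_traces)
  if (!identical(sort(names(dvi_traces)), sort(names(mvi_traces)))) {
    stop("mismatched strata between arms")
  }
  mvi_traces <- mvi_traces[names(dvi_traces)]
  for (s in names(dvi_traces)) {
    if (abs(attr(dvi_traces[[s]], "n_women") -
            attr(mvi_traces[[s]], "n_women")) > 1e-9) {
      stop("cohort composition differs between arms in stratum ", s)
    }
  }
  dvi <- combine_arm(dvi_traces)
  mvi <- combine_arm(mvi_traces)

  per_parity <- lapply(names(dvi_traces), function(s) {
    d <- dvi$per_stratum[[s]]; m <- mvi$per_stratum[[s]]
    list(parity = s,
         p12_dvi = d$p_vd_within_12, p12_mvi = m$p_vd_within_12,
         fold_12h = ratio_or_na(m$p_vd_within_12, d$p_vd_within_12),
         p24_dvi = d$p_vd_within_24, p24_mvi = m$p_vd_within_24,
         fold_24h = ratio_or_na(m$p_vd_within_24, d$p_vd_within_24),
         mean_dvi_h = d$mean_time_to_vd_h, mean_mvi_h = m$mean_time_to_vd_h)
  })
  names(per_parity) <- names(dvi_traces)

  saved <- dvi$total_hours_to_vd - mvi$total_hours_to_vd
  structure(
    list(clinical = list(
      n_women = dvi$n_women,
      total_hours_to_vd = c(DVI = dvi$total_hours_to_vd,
                            MVI = mvi$total_hours_to_vd),
      hours_saved = saved,
      hours_saved_pct = 100 * saved / dvi$total_hours_to_vd,
      per_induction_hours = c(DVI = dvi$mean_time_to_vd_h,
                              MVI = mvi$mean_time_to_vd_h),
      per_induction_saving_h = dvi$mean_time_to_vd_h - mvi$mean_time_to_vd_h,
      p_vd_within_12 = c(DVI = dvi$p_vd_within_12, MVI = mvi$p_vd_within_12),
      p_vd_within_24 = c(DVI = dvi$p_vd_within_24, MVI = mvi$p_vd_within_24),
      increase_12h_pct = 100 * (mvi$p_vd_within_12 / dvi$p_vd_within_12 - 1),
      increase_24h_pct = 100 * (mvi$p_vd_within_24 / dvi$p_vd_within_24 - 1),
      prolonged_labour = c(DVI = dvi$prolonged_labour_prop,
                           MVI = mvi$prolonged_labour_prop),
      per_parity = per_parity
    )),
    class = "comparison_result"
  )
}

as_trace_list <- function(x) {
  if (inherits(x, "cohort_trace")) x <- list(x)
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "cohort_trace")))
  if (is.null(names(x)) || any(names(x) == "")) {
    names(x) <- vapply(x, attr, character(1), "parity")
  }
  x
}

ratio_or_na <- function(num, den) if (isTRUE(den > 0)) num / den else NA_real_

#' @export
print.comparison_result <- function(x, ...) {
  cl <- x$clinical
  cat("<comparison_result>\n")
  if (!is.null(cl)) {
    cat(sprintf("  hours to vaginal delivery: %.0f (DVI) vs %.0f (MVI); %.0f h saved (%.1f%%)\n",
                cl$total_hours_to_vd["DVI"], cl$total_hours_to_vd["MVI"],
                cl$hours_saved, cl$hours_saved_pct))
    cat(sprintf("  per induction: %.1f -> %.1f h (saving %.1f h)\n",
                cl$per_induction_hours["DVI"], cl$per_induction_hours["MVI"],
                cl$per_induction_saving_h))
    cat(sprintf("  vaginal delivery within 12 h: %.1f%% -> %.1f%% (+%.0f%%); within 24 h: %.1f%% -> %.1f%% (+%.0f%%)\n",
                100 * cl$p_vd_within_12["DVI"], 100 * cl$p_vd_within_12["MVI"],
                cl$increase_12h_pct,
                100 * cl$p_vd_within_24["DVI"], 100 * cl$p_vd_within_24["MVI"],
                cl$increase_24h_pct))
    cat(sprintf("  prolonged labour (>24 h): %.0f%% (DVI) vs %.0f%% (MVI)\n",
                100 * cl$prolonged_labour["DVI"], 100 * cl$prolonged_labour["MVI"]))
  }
  if (!is.null(x$resources)) {
    rs <- x$resources
    cat(sprintf("  midwife shifts: %.1f (DVI) vs %.1f (MVI); %.1f saved (%.1f%%)\n",
                rs$shifts["DVI"], rs$shifts["MVI"],
                rs$shifts_saved, rs$shifts_saved_pct))
    cat(sprintf("  bed hours: %.0f vs %.0f; %.0f saved (%.0f bed days, %.1f%%)\n",
                rs$bed_hours["DVI"], rs$bed_hours["MVI"], rs$bed_hours_saved,
                rs$bed_days_saved, rs$bed_hours_saved_pct))
    cat(sprintf("  additional inductions accommodated: %d; births per midwife: %.1f -> %.1f\n",
                rs$additional_inductions, rs$births_per_midwife_current,
                rs$births_per_midwife_adjusted))
  }
  invisible(x)
}
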