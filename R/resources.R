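#' Care-schedule parameters (Southmead labour-ward pattern)
#'
#' Durations and frequencies of the midwife-led care events the model
#' costs in time: vaginal examinations (VE), vital-signs monitoring (VSM)
#' and oxytocin drip set-up. Defaults are the hospital's reported practice:
#' a 10-minute VE once in pre-active labour and every 4 h of active labour
#' (every 3 h when oxytocin runs); 3-minute VSM every 4 h in pre-active
#' labour and the first stage and hourly in the second stage; a 10-minute
#' oxytocin set-up performed by two midwives.
#'
#' @param ve_duration_min Duration of a vaginal examination, minutes.
#' @param ve_interval_active_h VE interval during active labour without
#'   oxytocin, hours.
#' @param ve_interval_active_oxy_h VE interval during active labour with
#'   oxytocin, hours.
#' @param vsm_duration_min Duration of one vital-signs check, minutes.
#' @param vsm_interval_pre_h,vsm_interval_stage1_h,vsm_interval_stage2_h
#'   VSM intervals (hours) in pre-active labour, first and second stage.
#' @param oxy_setup_min_per_midwife Minutes per midwife to set up an
#'   oxytocin drip.
#' @param oxy_setup_midwives Number of midwives required for the set-up.
#' @return An object of class `resource_schedule`.
#' @export
resource_schedule <- function(ve_duration_min = 10,
                              ve_interval_active_h = 4,
                              ve_interval_active_oxy_h = 3,
                              vsm_duration_min = 3,
                              vsm_interval_pre_h = 4,
                              vsm_interval_stage1_h = 4,
                              vsm_interval_stage2_h = 1,
                              oxy_setup_min_per_midwife = 10,
                              oxy_setup_midwives = 2) {
  vals <- c(ve_duration_min, ve_interval_active_h, ve_interval_active_oxy_h,
            vsm_duration_min, vsm_interval_pre_h, vsm_interval_stage1_h,
            vsm_interval_stage2_h, oxy_setup_min_per_midwife,
            oxy_setup_midwives)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop(errorCondition("all schedule durations and intervals must be positive",
                        class = c("inductmod_config_error",
                                  "inductmod_error", "error")))
  }
  structure(list(ve_duration_min = ve_duration_min,
                 ve_interval_active_h = ve_interval_active_h,
                 ve_interval_active_oxy_h = ve_interval_active_oxy_h,
                 vsm_duration_min = vsm_duration_min,
                 vsm_interval_pre_h = vsm_interval_pre_h,
                 vsm_interval_stage1_h = vsm_interval_stage1_h,
                 vsm_interval_stage2_h = vsm_interval_stage2_h,
                 oxy_setup_min_per_midwife = oxy_setup_min_per_midwife,
                 oxy_setup_midwives = oxy_setup_midwives),
            class = "resource_schedule")
}

#' Staffing assumptions
#'
#' @param shift_length_h Midwife shift length in hours. Not reported by the
#'   hospital; the 8-hour default is the value that reconciles the oxytocin
#'   set-up workload with the reported annual set-up shift counts, and every
#'   report echoes the value used.
#' @param current_births_per_midwife Reported annual births-per-midwife
#'   ratio (default 33.0).
#' @param recommended_ratio Recommended births-per-midwife ratio
#'   (default 29.5).
#' @return An object of class `staffing_model`.
#' @export
staffing_model <- function(shift_length_h = 8,
                           current_births_per_midwife = 33.0,
                           recommended_ratio = 29.5) {
  stopifnot(shift_length_h > 0, current_births_per_midwife > 0,
            recommended_ratio > 0)
  structure(list(shift_length_h = shift_length_h,
                 current_births_per_midwife = current_births_per_midwife,
                 recommended_ratio = recommended_ratio),
            class = "staffing_model")
}

#' Midwife minutes for a single labour pathway
#'
#' Closed-form care-event accounting for one woman with known state
#' durations. Under the default completed-interval convention a scheduled
#' event fires at each whole multiple of its interval elapsed within the
#' state (and the single pre-active VE fires at state entry), so a 9-hour
#' pre-active phase yields VSM checks at hours 4 and 8. The
#' `"expected_rate"` convention replaces the floor counts with
#' `duration / interval`, the continuous-rate form the cohort-level
#' aggregation uses.
#'
#' @param pre_active_h,active1_h,active2_h Hours spent in pre-active
#'   labour and the first/second stage of active labour (`>= 0`).
#' @param oxytocin Logical: does the woman receive oxytocin augmentation?
#' @param schedule A [resource_schedule()].
#' @param convention `"completed_interval"` (default) or `"expected_rate"`.
#' @return Named numeric vector of minutes: `ve`, `vsm`, `oxytocin_setup`.
#' @export
midwife_minutes_for_pathway <- function(pre_active_h, active1_h, active2_h,
                                        oxytocin = FALSE,
                                        schedule = resource_schedule(),
                                        convention = c("completed_interval",
                                                       "expected_rate")) {
  stopifnot(inherits(schedule, "resource_schedule"),
            pre_active_h >= 0, active1_h >= 0, active2_h >= 0)
  convention <- match.arg(convention)
  count <- if (convention == "completed_interval") {
    function(h, interval) floor(h / interval + 1e-9)
  } else {
    function(h, interval) h / interval
  }
  ve_interval <- if (oxytocin) schedule$ve_interval_active_oxy_h
                 else schedule$ve_interval_active_h
  ve_events <- 1 + count(active1_h + active2_h, ve_interval)
  vsm_events <- count(pre_active_h, schedule$vsm_interval_pre_h) +
    count(active1_h, schedule$vsm_interval_stage1_h) +
    count(active2_h, schedule$vsm_interval_stage2_h)
  setup <- if (oxytocin) {
    schedule$oxy_setup_midwives * schedule$oxy_setup_min_per_midwife
  } else 0
  c(ve = ve_events * schedule$ve_duration_min,
    vsm = vsm_events * schedule$vsm_duration_min,
    oxytocin_setup = setup)
}

suite_occupancy_hours <- function(trace) {
  sum(trace[, c("pre_active", "active_stage1", "active_stage2")])
}

#' Aggregate midwife workload over cohort traces
#'
#' Integrates the expected care-event minutes over the state occupancy of
#' one arm's traces: one entry vaginal examination per woman plus
#' examinations at the continuous rate `1/interval` per active-labour hour
#' (the with-oxytocin interval for the oxytocin sub-cohort), vital-signs
#' monitoring at `1/interval` per hour of pre-active labour and each active
#' stage, and a two-midwife set-up per oxytocin recipient. Minutes are
#' converted to shifts with the staffing model's shift length.
#'
#' @param traces List of `cohort_trace` objects (one arm).
#' @param schedule A [resource_schedule()].
#' @param staffing A [staffing_model()].
#' @param monitoring_share_override Optional share in `[0, 1]` of women
#'   monitored on the with-oxytocin schedule, overriding each stratum's
#'   oxytocin probability (used by the continuous-monitoring scenario);
#'   oxytocin set-up counts still use the true oxytocin probability.
#' @return An object of class `resource_result`: minutes and shifts by
#'   activity (`ve`, `vsm`, `oxytocin_setup`), totals, and labour-suite
#'   `bed_hours`/`bed_days`.
#' @export
aggregate_workload <- function(traces, schedule = resource_schedule(),
                               staffing = staffing_model(),
                               monitoring_share_override = NULL) {
  traces <- as_trace_list(traces)
  stopifnot(inherits(schedule, "resource_schedule"),
            inherits(staffing, "staffing_model"))
  if (!is.null(monitoring_share_override)) {
    stopifnot(monitoring_share_override >= 0, monitoring_share_override <= 1)
  }
  minutes <- c(ve = 0, vsm = 0, oxytocin_setup = 0)
  n_total <- 0
  for (tr in traces) {
    n <- attr(tr, "n_women")
    oxy <- attr(tr, "oxytocin_prob")
    mon <- if (is.null(monitoring_share_override)) oxy
           else monitoring_share_override
    occ_pre <- sum(tr[, "pre_active"])
    occ_a1 <- sum(tr[, "active_stage1"])
    occ_a2 <- sum(tr[, "active_stage2"])
    occ_active <- occ_a1 + occ_a2
    ve_events <- n +                       # entry examination, every woman
      occ_active * (mon / schedule$ve_interval_active_oxy_h +
                    (1 - mon) / schedule$ve_interval_active_h)
    vsm_events <- occ_pre / schedule$vsm_interval_pre_h +
      occ_a1 / schedule$vsm_interval_stage1_h +
      occ_a2 / schedule$vsm_interval_stage2_h
    minutes["ve"] <- minutes["ve"] + ve_events * schedule$ve_duration_min
    minutes["vsm"] <- minutes["vsm"] + vsm_events * schedule$vsm_duration_min
    minutes["oxytocin_setup"] <- minutes["oxytocin_setup"] +
      n * oxy * schedule$oxy_setup_midwives * schedule$oxy_setup_min_per_midwife
    n_total <- n_total + n
  }
  shift_min <- staffing$shift_length_h * 60
  bed <- bed_occupancy(traces)
  structure(
    list(minutes_by_activity = minutes,
         minutes_total = sum(minutes),
         shifts_by_activity = minutes / shift_min,
         shifts_total = sum(minutes) / shift_min,
         bed_hours = bed$bed_hours,
         bed_days = bed$bed_days,
         n_women = n_total,
         shift_length_h = staffing$shift_length_h),
    class = "resource_result"
  )
}

#' @export
print.resource_result <- function(x, ...) {
  cat(sprintf("<resource_result> %g women, %g-h shifts\n", x$n_women,
              x$shift_length_h))
  cat(sprintf("  shifts: VE %.1f, VSM %.1f, oxytocin set-up %.1f, total %.1f\n",
              x$shifts_by_activity["ve"], x$shifts_by_activity["vsm"],
              x$shifts_by_activity["oxytocin_setup"], x$shifts_total))
  cat(sprintf("  labour-suite occupancy: %.0f bed hours (%d bed days)\n",
              x$bed_hours, x$bed_days))
  invisible(x)
}

#' Labour-suite bed occupancy
#'
#' Bed hours are the expected woman-hours spent in the labour and delivery
#' suite (induction through delivery: pre-active labour plus both active
#' stages); the postnatal inpatient stay is excluded. Bed days are hours
#' divided by 24, rounded to the nearest integer.
#'
#' @param traces List of `cohort_trace` objects.
#' @return A list with `bed_hours` and `bed_days`.
#' @export
bed_occupancy <- function(traces) {
  traces <- as_trace_list(traces)
  bed_hours <- sum(vapply(traces, suite_occupancy_hours, numeric(1)))
  list(bed_hours = bed_hours, bed_days = round(bed_hours / 24))
}

#' Additional inductions accommodated by freed bed hours
#'
#' @param bed_hours_saved Labour-suite bed hours freed per year (`> 0`
#'   allowed to be 0).
#' @param mean_bed_hours_per_mvi_induction Mean suite occupancy of one
#'   MVI induction, hours (`> 0`).
#' @return `floor(bed_hours_saved / mean_bed_hours_per_mvi_induction)`.
#' @export
capacity_gain <- function(bed_hours_saved, mean_bed_hours_per_mvi_induction) {
  if (!isTRUE(mean_bed_hours_per_mvi_induction > 0)) {
    stop(errorCondition("mean bed hours per induction must be positive",
                        class = c("inductmod_config_error",
                                  "inductmod_error", "error")))
  }
  stopifnot(bed_hours_saved >= 0)
  floor(bed_hours_saved / mean_bed_hours_per_mvi_induction)
}

#' Adjusted births-per-midwife ratio
#'
#' Applies a fractional reduction in labour-suite occupancy to the current
#' births-per-midwife ratio multiplicatively: with the same staff managing
#' the same births in less occupied time, the effective ratio falls to
#' `current_ratio * (1 - fractional_occupancy_reduction)`.
#'
#' @param current_ratio Current annual births per midwife (`> 0`).
#' @param fractional_occupancy_reduction In `[0, 1)`.
#' @return The adjusted ratio (full precision; reports round to 1 decimal).
#' @export
births_per_midwife_adjusted <- function(current_ratio,
                                        fractional_occupancy_reduction) {
  stopifnot(current_ratio > 0)
  if (fractional_occupancy_reduction < 0 ||
      fractional_occupancy_reduction >= 1) {
    stop(errorCondition("occupancy reduction must lie in [0, 1)",
                        class = c("inductmod_domain_error",
                                  "inductmod_error", "error")))
  }
  current_ratio * (1 - fractional_occupancy_reduction)
}

#' Resource-use comparison of the two arms
#'
#' @param dvi_workload,mvi_workload [aggregate_workload()] results for the
#'   two arms (same cohort composition).
#' @param staffing A [staffing_model()].
#' @return A list (the `resources` block of a comparison): shifts by
#'   activity and totals per arm, shift and bed savings, additional
#'   inductions accommodated, and the adjusted births-per-midwife ratio.
#' @export
compare_resource_use <- function(dvi_workload, mvi_workload,
                                 staffing = staffing_model()) {
  stopifnot(inherits(dvi_workload, "resource_result"),
            inherits(mvi_workload, "resource_result"))
  if (abs(dvi_workload$n_women - mvi_workload$n_women) > 1e-9) {
    stop("arm cohort sizes differ")
  }
  shifts_saved <- dvi_workload$shifts_total - mvi_workload$shifts_total
  bed_saved <- dvi_workload$bed_hours - mvi_workload$bed_hours
  occupancy_reduction <- bed_saved / dvi_workload$bed_hours
  mvi_bed_per_induction <- mvi_workload$bed_hours / mvi_workload$n_women
  list(
    shifts = c(DVI = dvi_workload$shifts_total,
               MVI = mvi_workload$shifts_total),
    shifts_by_activity = rbind(DVI = dvi_workload$shifts_by_activity,
                               MVI = mvi_workload$shifts_by_activity),
    shifts_saved = shifts_saved,
    shifts_saved_pct = 100 * shifts_saved / dvi_workload$shifts_total,
    bed_hours = c(DVI = dvi_workload$bed_hours, MVI = mvi_workload$bed_hours),
    bed_hours_saved = bed_saved,
    bed_days_saved = round(bed_saved / 24),
    bed_hours_saved_pct = 100 * occupancy_reduction,
    mean_bed_hours_per_mvi_induction = mvi_bed_per_induction,
    additional_inductions = capacity_gain(max(bed_saved, 0),
                                          mvi_bed_per_induction),
    occupancy_reduction = occupancy_reduction,
    births_per_midwife_current = staffing$current_births_per_midwife,
    births_per_midwife_adjusted = births_per_midwife_adjusted(
      staffing$current_births_per_midwife, max(occupancy_reduction, 0)),
    shift_length_h = staffing$shift_length_h
  )
}
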