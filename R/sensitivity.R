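dsa_parameters <- c("ve_duration", "vsm_duration", "oxytocin_setup_duration",
                    "ve_frequency")

#' Perturb a care schedule by multiplicative factors
#'
#' `ve_duration`, `vsm_duration` and `oxytocin_setup_duration` scale the
#' respective event durations; `ve_frequency` scales the vaginal-examination
#' interval lengths (both the with- and without-oxytocin intervals), so a
#' factor of 0.5 means examinations twice as often.
#'
#' @param schedule A [resource_schedule()].
#' @param factors Named numeric vector (names among
#'   `ve_duration`, `vsm_duration`, `oxytocin_setup_duration`,
#'   `ve_frequency`), all `> 0`.
#' @return A perturbed [resource_schedule()].
#' @export
perturb_schedule <- function(schedule, factors) {
  stopifnot(inherits(schedule, "resource_schedule"))
  if (length(factors)) {
    stopifnot(!is.null(names(factors)), all(names(factors) %in% dsa_parameters),
              all(factors > 0))
  }
  f <- function(nm) if (nm %in% names(factors)) factors[[nm]] else 1
  resource_schedule(
    ve_duration_min = schedule$ve_duration_min * f("ve_duration"),
    ve_interval_active_h = schedule$ve_interval_active_h * f("ve_frequency"),
    ve_interval_active_oxy_h =
      schedule$ve_interval_active_oxy_h * f("ve_frequency"),
    vsm_duration_min = schedule$vsm_duration_min * f("vsm_duration"),
    vsm_interval_pre_h = schedule$vsm_interval_pre_h,
    vsm_interval_stage1_h = schedule$vsm_interval_stage1_h,
    vsm_interval_stage2_h = schedule$vsm_interval_stage2_h,
    oxy_setup_min_per_midwife =
      schedule$oxy_setup_min_per_midwife * f("oxytocin_setup_duration"),
    oxy_setup_midwives = schedule$oxy_setup_midwives
  )
}

#' Deterministic sensitivity analysis over care-schedule parameters
#'
#' Re-runs the workload aggregation over perturbed schedules with the
#' clinical traces held fixed (only care-process parameters vary, never
#' efficacy). The grid contains the base case (all factors 1), every
#' one-way perturbation from `factors`, and — when `corners = TRUE` — every
#' multi-way corner combining the smallest and largest factor across all
#' selected parameters (including the all-low and all-high corners).
#'
#' @param dvi_traces,mvi_traces Traces per arm (lists of `cohort_trace`).
#' @param schedule Base [resource_schedule()].
#' @param staffing A [staffing_model()].
#' @param parameters Subset of
#'   `c("ve_duration", "vsm_duration", "oxytocin_setup_duration",
#'   "ve_frequency")`.
#' @param factors Multiplicative factor set; default `c(0.5, 1, 1.5)`
#'   (±50 %).
#' @param corners Include the multi-way corners (default `TRUE`).
#' @return A `sensitivity_grid`: long-format data.frame (mode, one factor
#'   column per parameter, shifts per arm, shift and bed-hour savings,
#'   delta versus base) with `best_case`/`worst_case` attributes (rows
#'   maximising/minimising the shift saving).
#' @export
run_dsa <- function(dvi_traces, mvi_traces,
                    schedule = resource_schedule(),
                    staffing = staffing_model(),
                    parameters = dsa_parameters,
                    factors = c(0.5, 1, 1.5),
                    corners = TRUE) {
  parameters <- match.arg(parameters, dsa_parameters, several.ok = TRUE)
  stopifnot(all(factors > 0))
  if (!any(abs(factors - 1) < 1e-12)) factors <- sort(c(1, factors))

  configs <- list(list(mode = "base",
                       factors = stats::setNames(rep(1, length(parameters)),
                                                 parameters)))
  for (p in parameters) {
    for (f in factors[abs(factors - 1) > 1e-12]) {
      fv <- stats::setNames(rep(1, length(parameters)), parameters)
      fv[p] <- f
      configs[[length(configs) + 1L]] <- list(mode = "one_way", factors = fv)
    }
  }
  if (corners && length(parameters) > 1) {
    lohi <- c(min(factors), max(factors))
    grid <- do.call(expand.grid, stats::setNames(
      rep(list(lohi), length(parameters)), parameters))
    for (i in seq_len(nrow(grid))) {
      fv <- stats::setNames(as.numeric(grid[i, ]), parameters)
      configs[[length(configs) + 1L]] <- list(mode = "multi_way", factors = fv)
    }
  }

  rows <- lapply(configs, function(cfg) {
    sch <- perturb_schedule(schedule, cfg$factors)
    dvi <- aggregate_workload(dvi_traces, sch, staffing)
    mvi <- aggregate_workload(mvi_traces, sch, staffing)
    cbind(data.frame(mode = cfg$mode, stringsAsFactors = FALSE),
          as.data.frame(as.list(cfg$factors)),
          data.frame(shifts_dvi = dvi$shifts_total,
                     shifts_mvi = mvi$shifts_total,
                     shifts_saved = dvi$shifts_total - mvi$shifts_total,
                     bed_hours_saved = dvi$bed_hours - mvi$bed_hours))
  })
  grid <- do.call(rbind, rows)
  base_saved <- grid$shifts_saved[grid$mode == "base"][1]
  grid$delta_shifts_saved <- grid$shifts_saved - base_saved
  structure(grid,
            class = c("sensitivity_grid", "data.frame"),
            best_case = grid[which.max(grid$shifts_saved), , drop = FALSE],
            worst_case = grid[which.min(grid$shifts_saved), , drop = FALSE])
}

#' Continuous-monitoring scenario
#'
#' Assumes continuous monitoring of (by default) every MVI woman entails
#' staff involvement equivalent to monitoring women on oxytocin: the whole
#' arm is examined on the with-oxytocin schedule, while oxytocin set-up
#' counts keep the true oxytocin probability. The DVI arm is unchanged
#' unless `apply_to = "both"` (a symmetry control).
#'
#' @param dvi_traces,mvi_traces Traces per arm.
#' @param schedule A [resource_schedule()].
#' @param staffing A [staffing_model()].
#' @param apply_to `"mvi"` (default) or `"both"`.
#' @return A `comparison_result` with `clinical` and `resources` blocks and
#'   a `scenario` attribute.
#' @export
scenario_continuous_monitoring <- function(dvi_traces, mvi_traces,
                                           schedule = resource_schedule(),
                                           staffing = staffing_model(),
                                           apply_to = c("mvi", "both")) {
  apply_to <- match.arg(apply_to)
  dvi_share <- if (apply_to == "both") 1 else NULL
  dvi <- aggregate_workload(dvi_traces, schedule, staffing,
                            monitoring_share_override = dvi_share)
  mvi <- aggregate_workload(mvi_traces, schedule, staffing,
                            monitoring_share_override = 1)
  res <- compare_arms(dvi_traces, mvi_traces)
  res$resources <- compare_resource_use(dvi, mvi, staffing)
  attr(res, "scenario") <- "continuous_monitoring"
  res
}
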