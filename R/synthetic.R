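#' Sample an individual-level synthetic cohort
#'
#' Draws per-woman event records with the statistical structure the cohort
#' model assumes, standing in for unpublished individual-level trial data:
#' the delivery mode is drawn from the stratum's sub-distribution masses,
#' the delivery time by inverse-CDF sampling from the normalised
#' sub-distribution of the corresponding curve (so the micro-simulation
#' matches the calibrated curves exactly), and the oxytocin flag is
#' Bernoulli with the stratum's probability. All draws run inside a scoped
#' RNG seeded with `seed`; the global RNG state is untouched.
#'
#' @param profiles A [stratum_profile()] or list of them.
#' @param n_per_stratum Women to sample per stratum (`>= 1`).
#' @param seed Integer seed; identical `(seed, parameters)` give identical
#'   cohorts.
#' @return A `synthetic_cohort` data.frame: `id`, `arm`, `parity`,
#'   `outcome` (`"vaginal"`/`"caesarean"`), `time_to_delivery_h`,
#'   `oxytocin`, `oxytocin_duration_h`; the seed is kept as an attribute.
#' @export
sample_cohort <- function(profiles, n_per_stratum, seed) {
  if (inherits(profiles, "stratum_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "stratum_profile")),
            n_per_stratum >= 1, is.numeric(seed))
  for (pf in profiles) {
    total_mass <- pf$vd_curve$mass +
      if (is.null(pf$cs_curve)) 0 else pf$cs_curve$mass
    if (abs(total_mass - 1) > 1e-6) {
      stop(errorCondition(
        paste0("profile ", pf$arm, "/", pf$parity, " is not fully calibrated: ",
               "delivery masses sum to ", signif(total_mass, 6)),
        class = c("inductmod_dependency_error", "inductmod_error", "error")))
    }
  }
  n <- as.integer(n_per_stratum)
  withr::with_seed(as.integer(seed), {
    parts <- lapply(profiles, function(pf) {
      u_out <- stats::runif(n)
      u_time <- stats::runif(n)
      u_oxy <- stats::runif(n)
      vaginal <- u_out < pf$vd_curve$mass
      time <- numeric(n)
      time[vaginal] <- conditional_quantile(pf$vd_curve, u_time[vaginal])
      if (any(!vaginal)) {
        time[!vaginal] <- conditional_quantile(pf$cs_curve, u_time[!vaginal])
      }
      oxy <- u_oxy < pf$oxytocin_prob
      data.frame(
        arm = pf$arm, parity = pf$parity,
        outcome = ifelse(vaginal, "vaginal", "caesarean"),
        time_to_delivery_h = time,
        oxytocin = oxy,
        oxytocin_duration_h = ifelse(oxy, pf$oxytocin_duration_h, 0),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, parts)
    out <- cbind(id = seq_len(nrow(out)), out)
    structure(out, class = c("synthetic_cohort", "data.frame"),
              seed = as.integer(seed), n_per_stratum = n)
  })
}

#' Nonparametric cumulative incidence of vaginal delivery
#'
#' Aalen-Johansen estimate (via [survival::survfit()]) of the cumulative
#' incidence of vaginal delivery over hours since induction, treating
#' caesarean section as a competing event — the estimator whose unpublished
#' output the deterministic model consumes.
#'
#' @param cohort A `synthetic_cohort`.
#' @param arm,parity Optional stratum filters.
#' @return A data.frame step table: `time`, `cif_vaginal` (and
#'   `cif_caesarean`), starting from `(0, 0)`.
#' @export
km_estimate <- function(cohort, arm = NULL, parity = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort") || is.data.frame(cohort))
  d <- as.data.frame(cohort)
  if (!is.null(arm)) d <- d[d$arm == arm, ]
  if (!is.null(parity)) d <- d[d$parity == parity, ]
  if (nrow(d) == 0) stop("no records in the requested stratum")
  ev <- factor(d$outcome, levels = c("censored", "vaginal", "caesarean"))
  fit <- survival::survfit(survival::Surv(d$time_to_delivery_h, ev) ~ 1)
  st <- fit$pstate
  colnames(st) <- fit$states
  data.frame(
    time = c(0, fit$time),
    cif_vaginal = c(0, st[, "vaginal"]),
    cif_caesarean = c(0, st[, "caesarean"])
  )
}

step_interp <- function(times, values, at) {
  idx <- findInterval(at, times)
  c(0, values)[idx + 1L]
}

#' Cross-validate a deterministic trace against a micro-simulation
#'
#' Compares empirical 12/24-h vaginal-delivery proportions, mean time to
#' vaginal delivery, labour-suite bed hours and midwife workload minutes
#' (per woman) from a synthetic cohort against the corresponding
#' deterministic trace values, and flags any metric further than
#' `3` Monte-Carlo standard errors from the trace. Event times are
#' discretised with the trace's conventions (delivery during cycle
#' `floor(t)` timed at `floor(t) + 0.5`; suite occupancy `floor(t) + 1`
#' hours; workload from the expected-rate pathway form), so deterministic
#' and empirical quantities estimate the same thing.
#'
#' Cohorts smaller than `min_n` per stratum are marked underpowered and not
#' flagged.
#'
#' @param cohort A `synthetic_cohort` containing the trace's stratum.
#' @param trace The `cohort_trace` generated from the same profile.
#' @param schedule [resource_schedule()] used for the workload comparison.
#' @param min_n Below this stratum size the report is marked underpowered.
#' @return A `microsim_report` data.frame (metric, trace value, empirical
#'   value, Monte-Carlo SE, flag) with attributes `agreement` and
#'   `underpowered`.
#' @export
microsim_vs_cohort <- function(cohort, trace,
                               schedule = resource_schedule(),
                               min_n = 100) {
  stopifnot(inherits(trace, "cohort_trace"))
  d <- as.data.frame(cohort)
  d <- d[d$arm == attr(trace, "arm") & d$parity == attr(trace, "parity"), ]
  if (nrow(d) == 0) {
    stop(errorCondition("cohort contains no records for the trace's stratum",
                        class = c("inductmod_config_error",
                                  "inductmod_error", "error")))
  }
  n <- nrow(d)
  n_trace <- attr(trace, "n_women")
  active_h <- attr(trace, "active_labour_h")
  vag <- d$outcome == "vaginal"

  # empirical metrics under the trace's discretisation conventions
  cyc <- floor(d$time_to_delivery_h)
  p12_emp <- mean(vag & d$time_to_delivery_h <= 12)
  p24_emp <- mean(vag & d$time_to_delivery_h <= 24)
  t_disc <- cyc + 0.5
  mean_emp <- if (any(vag)) mean(t_disc[vag]) else NA_real_
  bed_emp <- cyc + 1
  stage1 <- pmin(cyc, active_h - 1)
  pre <- cyc - stage1
  wl <- mapply(function(p, a1, oxy) {
    sum(midwife_minutes_for_pathway(p, a1, 1, oxy, schedule,
                                    convention = "expected_rate"))
  }, pre, stage1, d$oxytocin)

  summ <- effectiveness_summary(trace)
  wl_trace <- aggregate_workload(list(trace), schedule, staffing_model())

  se_prop <- function(p) sqrt(pmax(p * (1 - p), 1e-12) / n)
  se_mean <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_

  metrics <- data.frame(
    metric = c("p_vd_within_12", "p_vd_within_24", "mean_time_to_vd_h",
               "bed_hours_per_woman", "workload_min_per_woman"),
    trace = c(summ$p_vd_within_12, summ$p_vd_within_24,
              summ$mean_time_to_vd_h,
              suite_occupancy_hours(trace) / n_trace,
              wl_trace$minutes_total / n_trace),
    empirical = c(p12_emp, p24_emp, mean_emp, mean(bed_emp), mean(wl)),
    mc_se = c(se_prop(p12_emp), se_prop(p24_emp),
              se_mean(t_disc[vag]), se_mean(bed_emp), se_mean(wl)),
    stringsAsFactors = FALSE
  )
  underpowered <- n < min_n
  metrics$flagged <- if (underpowered) NA else {
    abs(metrics$empirical - metrics$trace) > 3 * metrics$mc_se
  }
  structure(metrics, class = c("microsim_report", "data.frame"),
            n = n, underpowered = underpowered,
            agreement = !underpowered && isTRUE(!any(metrics$flagged)))
}

#' @export
print.microsim_report <- function(x, ...) {
  cat(sprintf("<microsim_report> n = %d%s\n", attr(x, "n"),
              if (attr(x, "underpowered")) " (underpowered)" else ""))
  print(as.data.frame(x), row.names = FALSE)
  if (!attr(x, "underpowered")) {
    cat(if (attr(x, "agreement")) "all metrics within 3 Monte-Carlo SEs\n"
        else "WARNING: at least one metric outside 3 Monte-Carlo SEs\n")
  }
  invisible(x)
}
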