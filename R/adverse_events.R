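ae_event_names <- c("total_ae", "tachysystole_no_fhr", "tachysystole_fhr",
                    "pph", "meconium", "nicu_admission", "low_apgar",
                    "uterine_rupture", "neonatal_acidosis")

#' Treatment-related adverse-event rate profile
#'
#' Per-arm rates of treatment-related intrapartum and neonatal adverse
#' events, applied to the whole modelled cohort. The categories follow the
#' trial's safety listing: uterine tachysystole without and with
#' fetal-heart-rate involvement, postpartum haemorrhage, meconium-stained
#' liquor, NICU admission, low Apgar score, uterine rupture and neonatal
#' acidosis, plus the overall treatment-related AE rate. Because several
#' events can occur during one labour, `total_ae` is the overall event
#' rate as reported, not the sum of the categories.
#'
#' @param dvi,mvi Named numeric vectors of rates in `[0, 1]`; names must be
#'   a subset of the fixed category list and include `total_ae`.
#' @return An object of class `ae_profile`.
#' @export
ae_profile <- function(dvi, mvi) {
  check_rates <- function(r, arm) {
    if (is.list(r)) r <- unlist(r)
    if (is.null(names(r)) || !all(names(r) %in% ae_event_names)) {
      stop("unknown AE categories for ", arm, "; allowed: ",
           paste(ae_event_names, collapse = ", "))
    }
    if (!("total_ae" %in% names(r))) stop("missing total_ae rate for ", arm)
    if (any(r < 0 | r > 1)) {
      stop(errorCondition(paste0("AE rates for ", arm, " must lie in [0, 1]"),
                          class = c("inductmod_validation_error",
                                    "inductmod_error", "error")))
    }
    r
  }
  dvi <- check_rates(dvi, "DVI")
  mvi <- check_rates(mvi, "MVI")
  if (!identical(sort(names(dvi)), sort(names(mvi)))) {
    stop("DVI and MVI must report the same AE categories")
  }
  events <- intersect(ae_event_names, names(dvi))
  structure(list(events = events, dvi = dvi[events], mvi = mvi[events]),
            class = "ae_profile")
}

round_half_up <- function(x) floor(x + 0.5)

#' Expected adverse-event counts per arm
#'
#' Applies each per-arm rate to the full cohort and rounds half-up to whole
#' events. Arm totals come from the reported overall AE rate (`total_ae`),
#' not from summing categories (the printed categories do not sum to the
#' printed totals). Fold ratios divide the MVI rate by the DVI rate and are
#' `NA` where the DVI rate is zero; the headline total fold is computed
#' from the rounded counts, with the rate-based fold reported alongside.
#'
#' @param profile An [ae_profile()].
#' @param n_cohort Number of women modelled per arm (`> 0`).
#' @return An object of class `ae_result`: a `table` data.frame (event,
#'   rates, counts, fold), `total_counts`, `total_difference`,
#'   `per_woman_excess` (2 dp), `fold_total_counts` (1 dp) and
#'   `fold_total_rates` (1 dp).
#' @export
expected_ae_counts <- function(profile, n_cohort) {
  stopifnot(inherits(profile, "ae_profile"))
  if (!isTRUE(n_cohort > 0)) {
    stop(errorCondition("n_cohort must be positive",
                        class = c("inductmod_validation_error",
                                  "inductmod_error", "error")))
  }
  counts_dvi <- round_half_up(profile$dvi * n_cohort)
  counts_mvi <- round_half_up(profile$mvi * n_cohort)
  fold <- ifelse(profile$dvi > 0, round(profile$mvi / profile$dvi, 1), NA_real_)
  tab <- data.frame(
    event = profile$events,
    rate_dvi = unname(profile$dvi),
    rate_mvi = unname(profile$mvi),
    count_dvi = unname(counts_dvi),
    count_mvi = unname(counts_mvi),
    fold_mvi_vs_dvi = unname(fold),
    stringsAsFactors = FALSE
  )
  tot_dvi <- counts_dvi[["total_ae"]]
  tot_mvi <- counts_mvi[["total_ae"]]
  structure(
    list(table = tab,
         total_counts = c(DVI = tot_dvi, MVI = tot_mvi),
         total_difference = tot_mvi - tot_dvi,
         per_woman_excess = round((tot_mvi - tot_dvi) / n_cohort, 2),
         fold_total_counts = if (tot_dvi > 0) round(tot_mvi / tot_dvi, 1)
                             else NA_real_,
         fold_total_rates = if (profile$dvi[["total_ae"]] > 0) {
           round(profile$mvi[["total_ae"]] / profile$dvi[["total_ae"]], 1)
         } else NA_real_,
         n_cohort = n_cohort),
    class = "ae_result"
  )
}

#' @export
print.ae_result <- function(x, ...) {
  cat(sprintf("<ae_result> cohort of %g women per arm\n", x$n_cohort))
  cat(sprintf("  total treatment-related AEs: %d (DVI) vs %d (MVI); +%.2f per woman; %.1f-fold\n",
              x$total_counts["DVI"], x$total_counts["MVI"],
              x$per_woman_excess, x$fold_total_counts))
  print(x$table, row.names = FALSE)
  invisible(x)
}
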