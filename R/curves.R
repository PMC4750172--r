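#' Summary anchors for one arm-by-parity stratum
#'
#' Bundles the printed summary statistics that identify a stratum's
#' time-to-vaginal-delivery curve: the proportions of women achieving
#' vaginal delivery within 12 and 24 hours of induction, and the arm's
#' overall caesarean-section probability. The 12/24-hour proportions are
#' interpreted as cumulative incidence of vaginal delivery in the presence
#' of caesarean section as a competing outcome, so the curve's terminal
#' mass is `1 - cs_total`.
#'
#' @param arm `"DVI"` (dinoprostone vaginal insert) or `"MVI"` (misoprostol
#'   vaginal insert).
#' @param parity `"parous"` or `"nulliparous"`.
#' @param p_vd_12h,p_vd_24h Proportion of the stratum delivering vaginally
#'   within 12 / 24 hours of insert placement; `0 <= p_vd_12h < p_vd_24h`.
#' @param cs_total Overall caesarean-section probability for the arm, in
#'   `[0, 1)`. The vaginal-delivery curve plateaus at `1 - cs_total`.
#' @param anchor_times_h Times (hours) at which the two anchor proportions
#'   are measured. Default `c(12, 24)`.
#' @param median_vd_h,mean_vd_h Optional reference median/mean time to
#'   vaginal delivery (hours); carried for reporting, never enforced.
#'
#' @return An object of class `summary_anchors`.
#' @seealso [fit_curve_to_anchors()]
#' @export
summary_anchors <- function(arm, parity, p_vd_12h, p_vd_24h, cs_total,
                            anchor_times_h = c(12, 24),
                            median_vd_h = NA_real_, mean_vd_h = NA_real_) {
  arm <- match.arg(arm, c("DVI", "MVI"))
  parity <- match.arg(parity, c("parous", "nulliparous"))
  stopifnot(is.numeric(p_vd_12h), is.numeric(p_vd_24h), is.numeric(cs_total),
            length(anchor_times_h) == 2L, all(anchor_times_h > 0),
            anchor_times_h[1] < anchor_times_h[2])
  if (cs_total < 0 || cs_total >= 1) {
    stop_calibration("cs_total must lie in [0, 1), got ", cs_total)
  }
  mass <- 1 - cs_total
  if (!(0 <= p_vd_12h && p_vd_12h < p_vd_24h)) {
    stop_calibration(
      "infeasible anchors for ", arm, "/", parity,
      ": need 0 <= p_vd_12h < p_vd_24h, got ", p_vd_12h, " and ", p_vd_24h
    )
  }
  if (p_vd_24h > mass) {
    stop_calibration(
      "infeasible anchors for ", arm, "/", parity, ": 24-h proportion ",
      p_vd_24h, " exceeds terminal vaginal-delivery mass ", mass
    )
  }
  structure(
    list(arm = arm, parity = parity,
         p_vd_12h = p_vd_12h, p_vd_24h = p_vd_24h,
         cs_total = cs_total, mass = mass,
         anchor_times_h = as.numeric(anchor_times_h),
         median_vd_h = median_vd_h, mean_vd_h = mean_vd_h),
    class = "summary_anchors"
  )
}

#' @export
print.summary_anchors <- function(x, ...) {
  cat(sprintf(
    "<summary_anchors> %s/%s: F(%g h) = %.3f, F(%g h) = %.3f, caesarean %.3f\n",
    x$arm, x$parity, x$anchor_times_h[1], x$p_vd_12h,
    x$anchor_times_h[2], x$p_vd_24h, x$cs_total
  ))
  invisible(x)
}

stop_calibration <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("inductmod_calibration_infeasible",
                                "inductmod_error", "error")))
}

stop_numerical <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("inductmod_numerical_error",
                                "inductmod_error", "error")))
}

curve_families <- c("weibull", "log_logistic", "piecewise_exponential")

#' Parametric cumulative-incidence curve
#'
#' A (possibly mass-deficient) cumulative-incidence function over hours
#' since induction: `F(t) = mass * G(t)` where `G` is a proper CDF on
#' `(0, Inf)` from the chosen family. `mass` is the terminal cumulative
#' incidence (sub-distribution total), e.g. the probability of ever
#' delivering vaginally when caesarean section competes.
#'
#' @param family `"weibull"`, `"log_logistic"` or `"piecewise_exponential"`.
#' @param params Named numeric vector. Weibull and log-logistic take
#'   `shape` and `scale` (hours); the piecewise exponential takes one
#'   `break1`, ..., `breakK` (hours, increasing) and `rate1`, ...,
#'   `rateK+1` (per hour, the last rate extending beyond the final break).
#' @param mass Terminal cumulative incidence in `(0, 1]`.
#'
#' @return An object of class `parametric_curve`.
#' @export
parametric_curve <- function(family, params, mass = 1) {
  family <- match.arg(family, curve_families)
  params <- unlist(params)
  if (!is.numeric(params) || is.null(names(params)) || any(names(params) == "")) {
    stop("`params` must be a named numeric vector")
  }
  if (any(!is.finite(params)) || any(params <= 0)) {
    stop("all curve parameters must be finite and positive")
  }
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass > 1) {
    stop("`mass` must be a single number in (0, 1]")
  }
  if (family %in% c("weibull", "log_logistic")) {
    stopifnot(all(c("shape", "scale") %in% names(params)))
  } else {
    nb <- sum(grepl("^break", names(params)))
    nr <- sum(grepl("^rate", names(params)))
    if (nr != nb + 1L) stop("piecewise exponential needs one more rate than breaks")
    brk <- params[grepl("^break", names(params))]
    if (is.unsorted(brk, strictly = TRUE)) stop("breaks must be strictly increasing")
  }
  structure(list(family = family, params = params, mass = mass),
            class = "parametric_curve")
}

#' @export
print.parametric_curve <- function(x, ...) {
  cat(sprintf("<parametric_curve> %s, mass %.4f\n  %s\n", x$family, x$mass,
              paste(names(x$params), signif(x$params, 6),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Evaluate a cumulative-incidence curve
#'
#' @param curve A [parametric_curve()].
#' @param t Times in hours (vectorised, `t >= 0`).
#' @return `F(t)`, the cumulative incidence at `t`; `F(0) = 0` and
#'   `F(t) -> mass` as `t -> Inf`.
#' @export
curve_cdf <- function(curve, t) {
  stopifnot(inherits(curve, "parametric_curve"), all(t >= 0))
  curve$mass * conditional_cdf(curve, t)
}

# proper CDF G(t) of the normalised sub-distribution
conditional_cdf <- function(curve, t) {
  p <- curve$params
  switch(curve$family,
    weibull = stats::pweibull(t, shape = p[["shape"]], scale = p[["scale"]]),
    log_logistic = {
      g <- 1 / (1 + (t / p[["scale"]])^(-p[["shape"]]))
      ifelse(t == 0, 0, g)
    },
    piecewise_exponential = 1 - exp(-piecewise_cumhaz(p, t))
  )
}

# inverse of G, for medians and inverse-CDF sampling
conditional_quantile <- function(curve, q) {
  stopifnot(all(q >= 0 & q < 1))
  p <- curve$params
  switch(curve$family,
    weibull = stats::qweibull(q, shape = p[["shape"]], scale = p[["scale"]]),
    log_logistic = p[["scale"]] * (q / (1 - q))^(1 / p[["shape"]]),
    piecewise_exponential = piecewise_cumhaz_inv(p, -log(1 - q))
  )
}

piecewise_pieces <- function(params) {
  brk <- unname(params[grepl("^break", names(params))])
  rate <- unname(params[grepl("^rate", names(params))])
  list(lower = c(0, brk), upper = c(brk, Inf), rate = rate)
}

piecewise_cumhaz <- function(params, t) {
  pc <- piecewise_pieces(params)
  vapply(t, function(ti) {
    sum(pc$rate * pmax(0, pmin(ti, pc$upper) - pc$lower))
  }, numeric(1))
}

piecewise_cumhaz_inv <- function(params, h) {
  pc <- piecewise_pieces(params)
  width <- pc$upper - pc$lower
  cum <- cumsum(c(0, (pc$rate * width)[-length(width)]))
  vapply(h, function(hi) {
    i <- max(which(cum <= hi))
    pc$lower[i] + (hi - cum[i]) / pc$rate[i]
  }, numeric(1))
}

#' Calibrate a parametric curve to two printed anchor proportions
#'
#' Solves for the curve whose cumulative incidence passes exactly through
#' the stratum's two printed vaginal-delivery proportions, with terminal
#' mass `1 - cs_total`. For the two-parameter families the shape is found
#' by bisection on `[0.05, 20]` with the scale solved in closed form from
#' the first anchor at every step (tolerance 1e-10, deterministic); the
#' piecewise exponential is exactly determined with a break at each anchor
#' time.
#'
#' @param anchors A [summary_anchors()] object.
#' @param family Curve family; default `"weibull"`.
#' @return A [parametric_curve()] with attributes `anchors` (the input) and
#'   `residuals` (fitted-minus-target at the anchor times).
#' @export
fit_curve_to_anchors <- function(anchors, family = "weibull") {
  stopifnot(inherits(anchors, "summary_anchors"))
  family <- match.arg(family, curve_families)
  t1 <- anchors$anchor_times_h[1]
  t2 <- anchors$anchor_times_h[2]
  mass <- anchors$mass
  g1 <- anchors$p_vd_12h / mass   # conditional CDF targets
  g2 <- anchors$p_vd_24h / mass
  if (g1 <= 0 || g2 >= 1) {
    # g1 = 0 leaves the first anchor uninformative; g2 = 1 needs infinite hazard
    stop_calibration("anchors for ", anchors$arm, "/", anchors$parity,
                     " are degenerate on the conditional scale (",
                     signif(g1, 4), ", ", signif(g2, 4), ")")
  }

  curve <- if (family == "piecewise_exponential") {
    r1 <- -log(1 - g1) / t1
    r2 <- -log((1 - g2) / (1 - g1)) / (t2 - t1)
    parametric_curve(family,
                     c(break1 = t1, break2 = t2, rate1 = r1, rate2 = r2, rate3 = r2),
                     mass = mass)
  } else {
    scale_for <- function(shape) {
      # closed-form scale pinning the first anchor, given the shape
      if (family == "weibull") t1 / (-log(1 - g1))^(1 / shape)
      else t1 / (g1 / (1 - g1))^(1 / shape)  # log-logistic via anchor odds
    }
    resid2 <- function(shape) {
      cv <- parametric_curve(family, c(shape = shape, scale = scale_for(shape)),
                             mass = mass)
      conditional_cdf(cv, t2) - g2
    }
    lo <- 0.05; hi <- 20
    flo <- resid2(lo); fhi <- resid2(hi)
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
      stop_numerical("shape bracket [0.05, 20] does not contain a root for ",
                     anchors$arm, "/", anchors$parity, " (", family, ")")
    }
    it <- 0L
    while (hi - lo > 1e-10 && it < 200L) {
      mid <- (lo + hi) / 2
      fm <- resid2(mid)
      if (fm == 0) { lo <- hi <- mid } else if (flo * fm < 0) hi <- mid else { lo <- mid; flo <- fm }
      it <- it + 1L
    }
    if (it >= 200L) {
      stop_numerical("bisection failed to converge for ",
                     anchors$arm, "/", anchors$parity, " (", family, ")")
    }
    shape <- (lo + hi) / 2
    parametric_curve(family, c(shape = shape, scale = scale_for(shape)), mass = mass)
  }

  fitted <- curve_cdf(curve, c(t1, t2))
  attr(curve, "anchors") <- anchors
  attr(curve, "residuals") <- fitted - c(anchors$p_vd_12h, anchors$p_vd_24h)
  curve
}

#' Hourly conditional transition probabilities from a curve
#'
#' Converts a cumulative-incidence curve into the per-cycle probability of
#' the event among those still at risk:
#' `p(t) = (F(t+1) - F(t)) / (1 - F(t))` for `t = 0, ..., horizon - 1`.
#' For a mass-deficient curve the probabilities decay to zero as the
#' sub-distribution plateaus.
#'
#' @param curve A [parametric_curve()].
#' @param horizon Number of hourly cycles (`>= 1`).
#' @return Numeric vector of length `horizon`, each element in `[0, 1)`.
#' @export
hourly_transition_probabilities <- function(curve, horizon) {
  stopifnot(inherits(curve, "parametric_curve"),
            length(horizon) == 1, horizon >= 1)
  horizon <- as.integer(horizon)
  Ft <- curve_cdf(curve, 0:horizon)
  surv <- 1 - Ft[seq_len(horizon)]
  if (any(surv <= 0)) {
    stop_numerical("absorbed state: F(t) reached 1 before the horizon, ",
                   "cannot condition on an empty risk set")
  }
  p <- diff(Ft) / surv
  pmin(pmax(p, 0), 1 - 1e-15)
}

#' Median and mean of the normalised sub-distribution
#'
#' Summaries of the event-time distribution among those who experience the
#' event (e.g. time to vaginal delivery among women delivering vaginally):
#' the median is `G^{-1}(1/2)` (equivalently `F^{-1}(mass/2)`) and the mean
#' is the expectation of the normalised sub-distribution, computed from the
#' closed form where available (Weibull, log-logistic with shape > 1) and
#' by integrating the conditional survival otherwise.
#'
#' @param curve A [parametric_curve()] with `mass > 0`.
#' @return A list with `median_h` and `mean_h` (hours among-delivered).
#' @export
curve_summary <- function(curve) {
  stopifnot(inherits(curve, "parametric_curve"))
  if (curve$mass <= 0) stop("curve has no event mass; summaries undefined")
  p <- curve$params
  median_h <- conditional_quantile(curve, 0.5)
  mean_h <- switch(curve$family,
    weibull = p[["scale"]] * gamma(1 + 1 / p[["shape"]]),
    log_logistic = {
      k <- p[["shape"]]
      if (k <= 1) Inf else p[["scale"]] * (pi / k) / sin(pi / k)
    },
    piecewise_exponential =
      stats::integrate(function(t) 1 - conditional_cdf(curve, t),
                       0, Inf, rel.tol = 1e-10)$value
  )
  list(median_h = unname(median_h), mean_h = unname(mean_h))
}

#' Export calibrated curves as a parameter table
#'
#' @param curves Named list of calibrated [parametric_curve()] objects (as
#'   returned by [fit_curve_to_anchors()], i.e. carrying their anchors).
#' @param file Optional CSV path; when given the table is also written out.
#' @return A data.frame with one row per stratum: arm, parity, family,
#'   parameters, mass and fitted-anchor residuals.
#' @export
calibration_table <- function(curves, file = NULL) {
  rows <- lapply(curves, function(cv) {
    an <- attr(cv, "anchors")
    res <- attr(cv, "residuals")
    pm <- as.list(cv$params)
    base <- data.frame(
      arm = if (is.null(an)) NA_character_ else an$arm,
      parity = if (is.null(an)) NA_character_ else an$parity,
      family = cv$family, mass = cv$mass,
      resid_anchor1 = if (is.null(res)) NA_real_ else res[1],
      resid_anchor2 = if (is.null(res)) NA_real_ else res[2],
      stringsAsFactors = FALSE
    )
    cbind(base, as.data.frame(pm))
  })
  out <- do.call(rbind_fill, rows)
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

# rbind data.frames with possibly different columns (filled with NA)
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[cols]
  }))
}
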