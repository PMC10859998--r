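## Weibull partitioned-survival machinery.
##
## Published survival inputs are (log-scale, shape) pairs from parametric fits.
## Two parameterizations are supported, with lambda = exp(log_scale) and
## k = exp(shape), t in years:
##   "rate-power" (default): S(t) = exp(-(lambda * t)^k)
##   "ph":                   S(t) = exp(-lambda * t^k)
## The default is the reading under which the published parameters imply
## clinically plausible survival (e.g. a ~27-month median OS on first-line
## EGFR-targeted therapy); the alternative is kept behind a switch.
## Hazard-ratio multipliers act proportionally on the hazard: S(t)^hr.

#' Construct a Weibull survival curve
#'
#' @param log_scale Log of the rate-like scale parameter.
#' @param shape Shape estimate; the shape used is `exp(shape)`.
#' @param hr Positive hazard multiplier (proportional hazards), default 1.
#' @param form `"rate-power"` for S(t) = exp(-(e^log_scale t)^(e^shape)), or
#'   `"ph"` for S(t) = exp(-e^log_scale t^(e^shape)).
#' @return An object of class `weibull_curve`.
#' @export
weibull_curve <- function(log_scale, shape, hr = 1, form = c("rate-power", "ph")) {
  form <- match.arg(form)
  if (!is.finite(log_scale) || !is.finite(shape))
    stop_config("weibull_curve: non-finite parameters")
  if (hr <= 0) stop_config("weibull_curve: hr must be positive")
  structure(list(log_scale = log_scale, shape = shape, hr = hr, form = form),
            class = "weibull_curve")
}

#' Evaluate a Weibull survival curve
#'
#' @param curve A [weibull_curve()].
#' @param t Non-negative times in years (vectorised).
#' @return Survival probabilities S(t).
#' @export
#' @examples
#' survival_at(weibull_curve(log(0.5), 0), 1)  # exponential, rate 0.5: e^{-0.5}
survival_at <- function(curve, t) {
  if (any(t < 0)) stop_config("survival_at: t must be non-negative")
  weibull_survival(t, curve$log_scale, curve$shape, curve$hr, curve$form)
}

weibull_survival <- function(t, log_scale, shape, hr = 1, form = "rate-power") {
  lambda <- exp(log_scale)
  k <- exp(shape)
  if (form == "rate-power") exp(-hr * (lambda * t)^k) else exp(-hr * lambda * t^k)
}

#' Apply a bundle of hazard-ratio adjustments to a curve
#'
#' Multiplies the curve's hazard by the product of the named adjustments:
#' `"calibration"` (subgroup survival-disparity calibration), `"egfr"`
#' (EGFR-targeted therapy adjustment, subgroup specific), `"tat"` (the
#' turnaround-time benefit of liquid-biopsy-triggered therapy, per scenario),
#' and any mismatched-therapy HR label (e.g. `"FP ALK"`,
#' `"TP PD-L1 + FN mut."`). Applied identically to PFS and OS curves.
#'
#' @param curve A [weibull_curve()].
#' @param bundle Character vector of adjustment labels (possibly empty).
#' @param draw A `dcea_draw` providing the hazard-ratio values.
#' @param subgroup Subgroup id, needed for `"calibration"` and `"egfr"`.
#' @param tat_scenario `"3-week"` or `"1-week"`, needed for `"tat"`.
#' @return The curve with its hazard multiplier updated.
#' @export
#' @examples
#' d <- point_estimate_draw(dcea_parameters())
#' crv <- weibull_curve(-1.1604, 0.1046)
#' apply_hazard_bundle(crv, c("calibration", "egfr", "tat"), d, "NH-White")$hr
apply_hazard_bundle <- function(curve, bundle, draw, subgroup,
                                tat_scenario = "3-week") {
  hr <- curve$hr
  for (label in bundle) {
    hr <- hr * switch(label,
      calibration = draw$calibration_hr[[subgroup]],
      egfr = draw$egfr_adjustment_hr[[subgroup]],
      tat = draw$tat_hr[[tat_scenario]],
      {
        if (!label %in% names(draw$mismatch_hr))
          stop_config("unknown hazard adjustment label: %s", label)
        draw$mismatch_hr[[label]]
      })
  }
  curve$hr <- hr
  curve
}

## Integration grid with composite-trapezoid weights and continuous-time
## discount factors; precomputed once per analysis.
psm_grid <- function(discount_rate, horizon, step) {
  t <- seq(0, horizon, by = step)
  if (t[length(t)] < horizon) t <- c(t, horizon)
  n <- length(t)
  dt <- diff(t)
  w <- numeric(n)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-1] + dt[-(n - 1)]) / 2
  list(t = t, w = w, disc = exp(-discount_rate * t),
       year = pmin(floor(t + 1e-12), ceiling(horizon) - 1) + 1)
}

## Vectorised partitioned-survival outcomes for a set of branches described by
## therapy contexts and hazard multipliers. Effective progression-free
## occupancy is min(PFS, OS) pointwise, so post-progression occupancy is never
## negative. Returns per-branch discounted and undiscounted occupancies and,
## optionally, discounted pre-progression occupancy sliced by model year (for
## duration-indexed drug-cost accrual).
psm_outcomes <- function(contexts, hrs, draw, grid, form = "rate-power",
                         yearly = FALSE, hr_application = "ph") {
  ## deduplicate (context, hr) pairs: branches sharing a therapy context and
  ## hazard multiplier share their survival curves
  key <- paste0(contexts, "|", hrs)
  ukey <- !duplicated(key)
  idx <- match(key, key[ukey])
  ucx <- contexts[ukey]
  uhr <- hrs[ukey]

  wb <- draw$weibull
  t <- grid$t
  nt <- length(t)
  cx_lev <- unique(ucx)
  ## cumulative-hazard bases per unique context, one column each
  base <- function(log_scale, shape) {
    lam <- exp(log_scale[cx_lev])
    k <- exp(shape[cx_lev])
    if (form == "rate-power")
      outer(t, lam, `*`)^rep(k, each = nt)
    else
      outer(t, rep(1, length(cx_lev)))^rep(k, each = nt) * rep(lam, each = nt)
  }
  hp <- base(wb$pfs_log_scale, wb$pfs_shape)
  ho <- base(wb$os_log_scale, wb$os_shape)
  ci <- match(ucx, cx_lev)
  if (hr_application == "rate") {
    ## hr multiplies the rate parameter (acceleration-factor style):
    ## S = exp(-(hr * lambda * t)^k), i.e. the cumulative hazard scales by hr^k
    hr_p <- uhr^exp(wb$pfs_shape[ucx])
    hr_o <- uhr^exp(wb$os_shape[ucx])
  } else {
    hr_p <- hr_o <- uhr
  }
  spfs <- exp(-hp[, ci, drop = FALSE] * rep(hr_p, each = nt))
  sos <- exp(-ho[, ci, drop = FALSE] * rep(hr_o, each = nt))
  spre <- pmin(spfs, sos)
  wd <- grid$w * grid$disc
  out <- list(
    t_pre_disc = as.numeric(crossprod(spre, wd))[idx],
    t_post_disc = as.numeric(crossprod(sos - spre, wd))[idx],
    t_pre_undisc = as.numeric(crossprod(spre, grid$w))[idx],
    t_post_undisc = as.numeric(crossprod(sos - spre, grid$w))[idx],
    mean_os_undisc = as.numeric(crossprod(sos, grid$w))[idx]
  )
  if (yearly) {
    out$t_pre_disc_year <- rowsum(spre * wd, grid$year)[, idx, drop = FALSE]
  }
  out
}

#' Discounted health outcome of one decision-tree branch
#'
#' Integrates state occupancy under the partitioned-survival model: the
#' pre-progression state occupies min(PFS, OS) at every time (curve crossings
#' are clamped), the post-progression state occupies OS - min(PFS, OS), and
#' quality-adjusted survival applies the pre-/post-progression utilities with
#' continuous discounting exp(-rt) inside the composite-trapezoid integral.
#'
#' @param pfs_curve,os_curve [weibull_curve()] objects.
#' @param utilities Numeric `c(pre, post)` utilities.
#' @param discount_rate Annual discount rate (default 0.03).
#' @param horizon Time horizon in years.
#' @param step Integration step in years (default one week).
#' @return A list of class `health_outcome`: `qalys`, `t_pre_disc`,
#'   `t_post_disc`, `t_pre_undisc`, `t_post_undisc`, `mean_os_undisc`.
#' @export
#' @examples
#' crv <- weibull_curve(log(0.5), 0)  # exponential PFS = OS
#' branch_health_outcome(crv, crv, c(0.7, 0.7), 0.03, 20, 1 / 52)$qalys
branch_health_outcome <- function(pfs_curve, os_curve, utilities,
                                  discount_rate = 0.03, horizon = 20,
                                  step = 1 / 52) {
  if (horizon <= 0 || step <= 0)
    stop_config("branch_health_outcome: horizon and step must be positive")
  grid <- psm_grid(discount_rate, horizon, step)
  spfs <- survival_at(pfs_curve, grid$t)
  sos <- survival_at(os_curve, grid$t)
  if (any(!is.finite(spfs)) || any(!is.finite(sos)))
    stop_config("branch_health_outcome: non-finite survival values")
  spre <- pmin(spfs, sos)
  wd <- grid$w * grid$disc
  t_pre_disc <- sum(spre * wd)
  t_post_disc <- sum((sos - spre) * wd)
  structure(list(
    qalys = utilities[1] * t_pre_disc + utilities[2] * t_post_disc,
    t_pre_disc = t_pre_disc,
    t_post_disc = t_post_disc,
    t_pre_undisc = sum(spre * grid$w),
    t_post_undisc = sum((sos - spre) * grid$w),
    mean_os_undisc = sum(sos * grid$w)
  ), class = "health_outcome")
}

#' Expected health outcome of a strategy
#'
#' Folds back the decision tree: the probability-weighted sum of per-branch
#' partitioned-survival outcomes over all terminal branches.
#'
#' @param branches Branch data frame from [enumerate_branches()].
#' @param draw The `dcea_draw` the branches were enumerated under.
#' @param settings Analysis settings list (see [dcea_parameters()]`$settings`);
#'   uses `discount_rate`, `horizon_years`, `time_step_years`, `weibull_form`.
#' @return A `health_outcome` list as in [branch_health_outcome()], aggregated
#'   over branches.
#' @export
expected_strategy_outcome <- function(branches, draw, settings) {
  grid <- psm_grid(settings$discount_rate, settings$horizon_years,
                   settings$time_step_years)
  po <- psm_outcomes(branches$context, branches$hr_multiplier, draw, grid,
                     form = settings$weibull_form,
                     hr_application = if (is.null(settings$hr_application)) "ph"
                                      else settings$hr_application)
  p <- branches$prob
  agg <- function(x) sum(p * x)
  t_pre <- agg(po$t_pre_disc)
  t_post <- agg(po$t_post_disc)
  structure(list(
    qalys = draw$u_pre * t_pre + draw$u_post * t_post,
    t_pre_disc = t_pre,
    t_post_disc = t_post,
    t_pre_undisc = agg(po$t_pre_undisc),
    t_post_undisc = agg(po$t_post_undisc),
    mean_os_undisc = agg(po$mean_os_undisc)
  ), class = "health_outcome")
}
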