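## Synthetic inputs for the reconstruction utilities and for pipeline
## robustness tests: simulated digitized Kaplan-Meier curves with risk tables,
## and multiplicatively perturbed full parameter sets. Every synthetic
## artifact passes the same validators as real inputs.

#' Specification for a synthetic digitized KM curve
#'
#' @param log_scale,shape Generating Weibull parameters (model convention:
#'   rate `exp(log_scale)`, shape `exp(shape)`).
#' @param n_subjects Number of subjects (>= 2).
#' @param censoring_rate Rate of independent exponential censoring per year
#'   (0 for none).
#' @param grid Ascending digitization times in years.
#' @param seed Integer seed making the curve reproducible.
#' @return A list of class `km_spec`.
#' @export
synthetic_km_spec <- function(log_scale, shape, n_subjects,
                              censoring_rate = 0,
                              grid = seq(0, 5, by = 0.1), seed = 1) {
  if (n_subjects < 2) stop_config("synthetic_km_spec: n_subjects must be >= 2")
  if (is.unsorted(grid)) stop_config("synthetic_km_spec: grid must be ascending")
  structure(list(log_scale = log_scale, shape = shape, n_subjects = n_subjects,
                 censoring_rate = censoring_rate, grid = grid, seed = seed),
            class = "km_spec")
}

#' Simulate a digitized Kaplan-Meier curve with a numbers-at-risk table
#'
#' Draws Weibull event times and independent exponential censoring times,
#' computes the Kaplan-Meier estimator, samples it on the digitization grid,
#' and records the number of subjects still at risk at each grid time. The
#' result emulates the published-figure inputs that pseudo-IPD reconstruction
#' consumes.
#'
#' @param spec A [synthetic_km_spec()].
#' @return A [digitized_km()] curve, with the generating spec attached as
#'   attribute `"spec"`. Warns if the grid extends beyond the maximum
#'   follow-up (the curve is truncated there).
#' @export
simulate_km <- function(spec) {
  stopifnot(inherits(spec, "km_spec"))
  lambda <- exp(spec$log_scale)
  k <- exp(spec$shape)
  sim <- function() {
    ev <- stats::rweibull(spec$n_subjects, shape = k, scale = 1 / lambda)
    cn <- if (spec$censoring_rate > 0)
      stats::rexp(spec$n_subjects, rate = spec$censoring_rate) else Inf
    data.frame(time = pmin(ev, cn), event = as.integer(ev <= cn))
  }
  d <- if (is.null(spec$seed)) {
    sim()
  } else {
    old <- save_rng_state()
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(spec$seed, kind = "Mersenne-Twister")
    sim()
  }

  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  grid <- spec$grid
  max_fu <- max(d$time)
  if (max(grid) > max_fu) {
    warning(sprintf("digitization grid truncated at maximum follow-up %.3f", max_fu))
    grid <- grid[grid <= max_fu]
    if (length(grid) == 0 || grid[1] > 0) grid <- c(0, grid)
  }
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  surv <- cummin(pmin(sf(grid), 1))
  risk_n <- vapply(grid, function(g) sum(d$time >= g - 1e-12), integer(1))
  keep <- risk_n > 0
  curve <- digitized_km(grid[keep], surv[keep], grid[keep], risk_n[keep])
  attr(curve, "spec") <- spec
  curve
}

#' Perturb a full parameter set
#'
#' Multiplies positive inputs by lognormal noise (sd `relative_scale` on the
#' log scale) and renormalises probability vectors, for robustness / fuzz
#' testing of the whole pipeline. Hazard-ratio confidence bounds are scaled by
#' the same factor as their point estimate so interval invariants survive.
#' The perturbed set passes [validate_parameters()]; `relative_scale = 0`
#' returns the input unchanged.
#'
#' @param params A `dcea_params` object.
#' @param relative_scale Non-negative noise scale.
#' @param seed Integer seed.
#' @return A validated, perturbed `dcea_params` object.
#' @export
jitter_parameters <- function(params, relative_scale, seed = 1) {
  if (relative_scale < 0) stop_config("jitter_parameters: relative_scale must be >= 0")
  if (relative_scale == 0) return(params)
  old <- save_rng_state()
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  noise <- function(n = 1) stats::rlnorm(n, 0, relative_scale)
  renorm_rows <- function(m) m / rowSums(m)

  p <- params
  p$subgroups$baseline_qale <- p$subgroups$baseline_qale * noise(4)
  p$subgroups$incidence_rate <- p$subgroups$incidence_rate * noise(4)
  p$subgroups$life_expectancy <- p$subgroups$life_expectancy * noise(4)
  sh <- p$subgroups$general_share * noise(4)
  p$subgroups$general_share <- sh / sum(sh)

  p$mutations$prevalence <- renorm_rows(p$mutations$prevalence *
                                          matrix(noise(length(p$mutations$prevalence)), 4))
  p$pdl1$distribution <- renorm_rows(p$pdl1$distribution *
                                       matrix(noise(length(p$pdl1$distribution)), 4))
  conf <- as.matrix(p$lb_test[, c("tp", "fp", "tn", "fn")])
  conf <- renorm_rows(conf * matrix(noise(length(conf)), nrow(conf)))
  p$lb_test[, c("tp", "fp", "tn", "fn")] <- conf

  p$survival$log_scale_se <- p$survival$log_scale_se * noise(nrow(p$survival))
  p$survival$shape_se <- p$survival$shape_se * noise(nrow(p$survival))

  for (nm in c("mismatch_hr", "tat_hr")) {
    f <- noise(nrow(p[[nm]]))
    p[[nm]]$hr <- p[[nm]]$hr * f
    p[[nm]]$ci_low <- p[[nm]]$ci_low * f
    p[[nm]]$ci_high <- p[[nm]]$ci_high * f
  }

  for (nm in c("lb_ngs", "rebiopsy", "rebiopsy_complication", "tb_ngs",
               "mgmt_pre", "mgmt_post"))
    p$costs[[nm]] <- p$costs[[nm]] * noise(length(p$costs[[nm]]))
  dcols <- c("year1", "year2", "year2plus", "second_line")
  p$costs$drug[dcols] <- p$costs$drug[dcols] *
    matrix(noise(nrow(p$costs$drug) * 4), ncol = 4)

  validate_parameters(p)
  p
}
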