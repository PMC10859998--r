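## Second-order Monte Carlo machinery: one complete parameter set is drawn per
## simulation from the distributions declared for each input (Dirichlet for
## prevalence and test-confusion vectors, bivariate normal for Weibull
## log-scale/shape pairs, lognormal for hazard ratios, beta for utilities and
## the rebiopsy complication probability, gamma for management costs; fixed
## inputs pass through unchanged).

## Independent per-draw RNG substreams from one master seed (L'Ecuyer-CMRG),
## so draws are order-independent and any draw is reproducible in isolation.
## Save the full RNG state (forcing initialisation so the generator kind is
## captured too) and restore it on exit; assigning .Random.seed restores the
## kind along with the state.
save_rng_state <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  get(".Random.seed", envir = globalenv())
}

psa_stream_states <- function(master_seed, n_draws) {
  old <- save_rng_state()
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master_seed), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  out <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    s <- parallel::nextRNGStream(s)
    out[[i]] <- s
  }
  out
}

with_rng_state <- function(state, expr) {
  old <- save_rng_state()
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  assign(".Random.seed", state, envir = globalenv())
  expr
}

## One Dirichlet draw with concentration `conc`; infinite or zero-variance
## concentrations degenerate to the normalized proportions.
rdirichlet1 <- function(conc) {
  if (any(!is.finite(conc))) return(conc_norm(conc))
  g <- stats::rgamma(length(conc), shape = conc, rate = 1)
  if (sum(g) <= 0) return(conc_norm(conc))
  g / sum(g)
}
conc_norm <- function(conc) {
  p <- ifelse(is.finite(conc), conc, 1)
  w <- if (any(!is.finite(conc))) as.numeric(!is.finite(conc)) else p
  w / sum(w)
}

## Lognormal HR matched to a printed point estimate (median convention) and
## 95% CI: sigma = (log hi - log lo) / (2 * 1.96).
rlnorm_ci <- function(hr, lo, hi) {
  if (hi <= lo) stop_config("distribution-fit error: CI high (%g) <= CI low (%g)", hi, lo)
  sigma <- (log(hi) - log(lo)) / (2 * stats::qnorm(0.975))
  if (sigma == 0) return(hr)
  stats::rlnorm(1, meanlog = log(hr), sdlog = sigma)
}

## Beta matched to mean and SE by moments.
rbeta_moments <- function(mean, se) {
  if (se == 0) return(mean)
  k <- mean * (1 - mean) / se^2 - 1
  if (k <= 0) stop_config("distribution-fit error: beta variance too large for mean %g", mean)
  stats::rbeta(1, shape1 = mean * k, shape2 = (1 - mean) * k)
}

## Gamma matched to mean and SE by moments.
rgamma_moments <- function(mean, se) {
  if (se == 0 || mean == 0) return(mean)
  stats::rgamma(1, shape = (mean / se)^2, rate = mean / se^2)
}

## Correlated bivariate normal draw.
rbvnorm <- function(m1, s1, m2, s2, rho) {
  z1 <- stats::rnorm(1)
  z2 <- stats::rnorm(1)
  c(m1 + s1 * z1, m2 + s2 * (rho * z1 + sqrt(1 - rho^2) * z2))
}

#' Point-estimate parameter draw
#'
#' Builds the degenerate parameter draw in which every stochastic quantity is
#' fixed at its point estimate (equivalently, all standard errors zero and all
#' Dirichlet counts infinite). Probability vectors are renormalised to sum to
#' one exactly. This is the deterministic skeleton the probabilistic draws
#' share.
#'
#' @param params A `dcea_params` object.
#' @return A `dcea_draw` object (see [draw_parameter_set()]).
#' @export
point_estimate_draw <- function(params) {
  build_draw(params, stochastic = FALSE, draw_index = 0L)
}

#' Draw one parameter set for probabilistic sensitivity analysis
#'
#' Samples every uncertain input from its declared distribution: mutation
#' prevalences, PD-L1 distributions and test confusion vectors from Dirichlet
#' distributions with concentration equal to backing sample size times
#' proportion; Weibull (log-scale, shape) pairs from bivariate normal
#' distributions with the published standard errors and correlation; hazard
#' ratios from lognormal distributions matched to the published 95% CIs;
#' utilities and the rebiopsy complication probability from beta distributions;
#' management costs from gamma distributions; fixed inputs pass through.
#' Identical `(master_seed, draw_index)` always yields the identical draw.
#'
#' @param params A `dcea_params` object.
#' @param draw_index Positive integer identifying the draw.
#' @param master_seed Integer master seed for the whole PSA.
#' @return A `dcea_draw` object: renormalised probability matrices, per-marker
#'   liquid-biopsy sensitivity/specificity, tissue-biopsy sensitivity/
#'   specificity, per-context Weibull parameters, hazard ratios, utilities and
#'   drawn cost inputs.
#' @export
draw_parameter_set <- function(params, draw_index, master_seed) {
  stopifnot(draw_index >= 1)
  state <- psa_stream_states(master_seed, draw_index)[[draw_index]]
  with_rng_state(state, build_draw(params, stochastic = TRUE, draw_index = draw_index))
}

## Shared constructor. Sampling order is fixed; do not reorder.
build_draw <- function(params, stochastic, draw_index) {
  sg_ids <- params$subgroups$id
  muts <- params$mutations$names

  norm1 <- function(p) p / sum(p)

  prevalence <- params$mutations$prevalence
  pdl1 <- params$pdl1$distribution
  for (i in seq_along(sg_ids)) {
    prevalence[i, ] <- if (stochastic)
      rdirichlet1(params$mutations$n[i] * prevalence[i, ]) else norm1(prevalence[i, ])
    pdl1[i, ] <- if (stochastic)
      rdirichlet1(params$pdl1$n[i] * pdl1[i, ]) else norm1(pdl1[i, ])
  }

  lb <- params$lb_test
  lb_se <- lb_sp <- numeric(length(muts))
  names(lb_se) <- names(lb_sp) <- muts
  for (i in seq_along(muts)) {
    v <- c(lb$tp[i], lb$fp[i], lb$tn[i], lb$fn[i])
    v <- if (stochastic) rdirichlet1(lb$n[i] * v) else norm1(v)
    lb_se[i] <- v[1] / (v[1] + v[4])
    lb_sp[i] <- v[3] / (v[3] + v[2])
  }
  tbv <- with(params$tb_test, c(tp, fp, tn, fn))
  tbv <- if (stochastic) rdirichlet1(params$tb_test$n * tbv) else norm1(tbv)
  tb_se <- tbv[1] / (tbv[1] + tbv[4])
  tb_sp <- tbv[3] / (tbv[3] + tbv[2])

  sv <- params$survival
  ls <- sv$log_scale
  sh <- sv$shape
  if (stochastic) {
    for (i in seq_len(nrow(sv))) {
      xy <- rbvnorm(sv$log_scale[i], sv$log_scale_se[i],
                    sv$shape[i], sv$shape_se[i], sv$correlation[i])
      ls[i] <- xy[1]
      sh[i] <- xy[2]
    }
  }
  ctx <- unique(sv$context)
  pick <- function(vec, outcome) {
    v <- vec[sv$outcome == outcome]
    names(v) <- sv$context[sv$outcome == outcome]
    v[ctx]
  }
  weibull <- list(
    pfs_log_scale = pick(ls, "PFS"), pfs_shape = pick(sh, "PFS"),
    os_log_scale = pick(ls, "OS"), os_shape = pick(sh, "OS")
  )

  mm <- params$mismatch_hr
  mismatch <- if (stochastic)
    vapply(seq_len(nrow(mm)), function(i) rlnorm_ci(mm$hr[i], mm$ci_low[i], mm$ci_high[i]),
           numeric(1))
  else mm$hr
  names(mismatch) <- mm$label

  tt <- params$tat_hr
  tat <- if (stochastic)
    vapply(seq_len(nrow(tt)), function(i) rlnorm_ci(tt$hr[i], tt$ci_low[i], tt$ci_high[i]),
           numeric(1))
  else tt$hr
  names(tat) <- tt$scenario

  ut <- params$utilities
  u_se <- (ut$ci_high - ut$ci_low) / (2 * stats::qnorm(0.975))
  if (stochastic) {
    u_pre <- rbeta_moments(ut$mean[1], u_se[1])
    u_post <- rbeta_moments(ut$mean[2], u_se[2])
    if (u_pre < u_post) {  # re-order rather than reject, to preserve draw count
      tmp <- u_pre; u_pre <- u_post; u_post <- tmp
    }
  } else {
    u_pre <- ut$mean[1]
    u_post <- ut$mean[2]
  }

  co <- params$costs
  complication <- if (stochastic)
    rbeta_moments(co$complication_prob, co$complication_se) else co$complication_prob
  draw_payer <- function(mean, se) {
    if (!stochastic) return(mean)
    out <- mean
    for (i in seq_along(mean)) out[i] <- rgamma_moments(mean[i], se[i])
    out
  }
  mgmt_pre <- draw_payer(co$mgmt_pre, co$mgmt_pre_se)
  mgmt_post <- draw_payer(co$mgmt_post, co$mgmt_post_se)

  cal <- params$subgroups$calibration_hr
  egfr <- params$subgroups$egfr_adjustment_hr
  names(cal) <- names(egfr) <- sg_ids

  structure(list(
    draw_index = as.integer(draw_index),
    subgroups = sg_ids,
    mutation_names = muts,
    prevalence = prevalence,
    pdl1 = pdl1,
    lb_se = lb_se, lb_sp = lb_sp,
    tb_se = tb_se, tb_sp = tb_sp,
    weibull = weibull,
    mismatch_hr = mismatch,
    tat_hr = tat,
    u_pre = u_pre, u_post = u_post,
    complication_prob = complication,
    mgmt_pre = mgmt_pre, mgmt_post = mgmt_post,
    calibration_hr = cal,
    egfr_adjustment_hr = egfr
  ), class = "dcea_draw")
}

#' Summarize a vector of simulation draws
#'
#' Mean and empirical 2.5th/97.5th percentiles (linear interpolation), the
#' convention used to report a 95% uncertainty interval around every
#' simulation outcome.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(mean, p2_5, p97_5)`.
#' @export
#' @examples
#' summarize_draws(1:1000)  # mean 500.5, percentiles 25.975 and 975.025
summarize_draws <- function(values) {
  if (length(values) == 0) stop_config("summarize_draws: empty vector")
  if (anyNA(values)) stop_config("summarize_draws: missing values")
  q <- stats::quantile(values, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(values), p2_5 = q[1], p97_5 = q[2])
}
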