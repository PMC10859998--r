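## The full distributional cost-effectiveness analysis: second-order Monte
## Carlo over the decision tree + partitioned-survival model, per-capita net
## health benefit with equally distributed opportunity costs, QALE shifting,
## and inequality indices - packaged behind one fitting-style entry point,
## dcea(), returning a classed result with print / summary / plot methods.

STRATEGIES <- c("TB-only", "LB-first")

## Core evaluation of one parameter draw: expected QALYs and costs per
## subgroup and strategy.
evaluate_draw <- function(draw, params, settings, grid, treatment_costs = FALSE) {
  sgs <- params$subgroups$id
  qaly <- diag_cost <- total_cost <- matrix(
    NA_real_, length(sgs), 2, dimnames = list(sgs, STRATEGIES))
  drug <- params$costs$drug
  ny <- max(grid$year)
  if (treatment_costs) {
    rate_mat <- vapply(drug$context, function(cx) {
      r <- drug[drug$context == cx, ]
      c(r$year1, r$year2, rep(r$year2plus, ny - 2))[seq_len(ny)]
    }, numeric(ny))
    if (is.finite(settings$io_cap_years))
      rate_mat[seq_len(ny) > settings$io_cap_years, ] <- 0
    sl_amt <- (1 - params$costs$bsc_fraction) * drug$second_line * drug$sl_duration_ratio
    names(sl_amt) <- drug$context
    mix <- params$costs$payer_mix
    mgmt_pre_rate <- sum(mix * draw$mgmt_pre)
    mgmt_post_rate <- sum(mix * draw$mgmt_post)
  }
  unit <- vapply(c("LB", "TB", "LB+TB"), diagnostic_unit_cost, numeric(1),
                 cost_params = params$costs,
                 complication_prob = draw$complication_prob)

  for (g in sgs) {
    for (s in STRATEGIES) {
      bt <- branch_table(s, draw, g, settings$tat_scenario,
                         settings$calibration_scope)
      po <- psm_outcomes(bt$context, bt$hr_multiplier, draw, grid,
                         form = settings$weibull_form, yearly = treatment_costs,
                         hr_application = settings$hr_application)
      p <- bt$prob
      qaly[g, s] <- sum(p * (draw$u_pre * po$t_pre_disc +
                               draw$u_post * po$t_post_disc))
      dg <- sum(p * unit[bt$tests])
      diag_cost[g, s] <- dg
      if (treatment_costs) {
        fl <- colSums(rate_mat[, bt$context, drop = FALSE] * po$t_pre_disc_year)
        sl <- sl_amt[bt$context] * po$t_post_disc
        mg <- mgmt_pre_rate * po$t_pre_disc + mgmt_post_rate * po$t_post_disc
        total_cost[g, s] <- dg + sum(p * (fl + sl + mg))
      }
    }
  }
  list(qaly = qaly, diag_cost = diag_cost,
       total_cost = if (treatment_costs) total_cost else NULL)
}

#' Run the distributional cost-effectiveness analysis
#'
#' Propagates parameter uncertainty through the diagnostic decision tree and
#' the Weibull partitioned-survival model with second-order Monte Carlo
#' simulation: for every draw, a complete parameter set is sampled
#' ([draw_parameter_set()]), both strategies' trees are folded back per
#' subgroup into expected discounted QALYs and diagnostic-workup (and,
#' optionally, treatment and disease-management) costs. Distributional
#' metrics - per-capita incremental net health benefit, QALE shifts, Atkinson
#' and Kolm indices, equally distributed equivalent health - are computed per
#' draw by [dcea_metrics()] and summarised by [summary.dcea()].
#'
#' @param params A `dcea_params` object; defaults to the packaged inputs.
#' @param n_draws Number of Monte Carlo draws (0 gives a point-estimate-only
#'   run).
#' @param seed Master seed; every source of randomness derives from it and
#'   identical seeds give identical results.
#' @param tat_scenario `"3-week"` (base case) or `"1-week"` turnaround-time
#'   benefit.
#' @param treatment_costs Also accumulate treatment and disease-management
#'   costs (needed for scenarios that include them).
#' @param ... Overrides for entries of `params$settings` (e.g. `threshold`,
#'   `atkinson_aversion`, `horizon_years`).
#' @return An object of class `dcea`: per-draw arrays `qaly`, `diag_cost`
#'   (draws x subgroup x strategy), optionally `total_cost`, the
#'   point-estimate evaluation `point`, shares, parameters and settings.
#' @export
#' @examples
#' \donttest{
#' fit <- dcea(n_draws = 200, seed = 1)
#' summary(fit)
#' }
dcea <- function(params = dcea_parameters(), n_draws = params$settings$n_draws,
                 seed = 1, tat_scenario = params$settings$tat_scenario,
                 treatment_costs = params$settings$include_treatment_costs, ...) {
  validate_parameters(params)
  settings <- utils::modifyList(params$settings, list(...))
  settings$tat_scenario <- tat_scenario
  grid <- psm_grid(settings$discount_rate, settings$horizon_years,
                   settings$time_step_years)
  sgs <- params$subgroups$id

  point <- evaluate_draw(point_estimate_draw(params), params, settings, grid,
                         treatment_costs)

  qaly <- diag_cost <- array(
    NA_real_, c(n_draws, length(sgs), 2),
    dimnames = list(NULL, sgs, STRATEGIES))
  total_cost <- if (treatment_costs) qaly else NULL
  if (n_draws > 0) {
    states <- psa_stream_states(seed, n_draws)
    failed <- 0L
    for (i in seq_len(n_draws)) {
      res <- tryCatch({
        draw <- with_rng_state(states[[i]],
                               build_draw(params, stochastic = TRUE, draw_index = i))
        evaluate_draw(draw, params, settings, grid, treatment_costs)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- failed + 1L
        warning(sprintf("draw %d failed: %s", i, conditionMessage(res)))
        if (failed > max(1, 0.01 * n_draws))
          stop_config("more than 1%% of draws failed; aborting")
        next
      }
      qaly[i, , ] <- res$qaly
      diag_cost[i, , ] <- res$diag_cost
      if (treatment_costs) total_cost[i, , ] <- res$total_cost
    }
    ok <- !is.na(qaly[, 1, 1])
    qaly <- qaly[ok, , , drop = FALSE]
    diag_cost <- diag_cost[ok, , , drop = FALSE]
    if (treatment_costs) total_cost <- total_cost[ok, , , drop = FALSE]
  }

  structure(list(
    qaly = qaly, diag_cost = diag_cost, total_cost = total_cost,
    point = point,
    patient_shares = patient_shares(params),
    general_shares = stats::setNames(params$subgroups$general_share, sgs),
    params = params, settings = settings,
    n_draws = dim(qaly)[1], seed = seed,
    call = match.call()
  ), class = "dcea")
}

## Row-wise weighted Atkinson / Kolm over a draws x subgroup matrix.
atkinson_rows <- function(Y, w, eps) {
  if (eps == 0) return(rep(0, nrow(Y)))
  mu <- as.numeric(Y %*% w)
  1 - (sweep(Y, 1, mu, "/")^(1 - eps) %*% w)^(1 / (1 - eps))
}
kolm_rows <- function(Y, w, alpha) {
  if (alpha == 0) return(rep(0, nrow(Y)))
  mu <- as.numeric(Y %*% w)
  log(exp(alpha * sweep(-Y, 1, mu, "+")) %*% w) / alpha
}

#' Per-draw distributional metrics of a fitted analysis
#'
#' Computes, for every Monte Carlo draw of a [dcea()] run: incremental QALYs
#' and costs per subgroup and pooled over the patient population; per-capita
#' incremental net health benefit (equally distributed opportunity costs) by
#' subgroup and overall; the shifted QALE distribution; Atkinson and Kolm
#' inequality indices of patient QALYs under both strategies and of the
#' pre/post QALE distributions; and the corresponding equally distributed
#' equivalent (EDE) health values.
#'
#' @param object A `dcea` object.
#' @param threshold Opportunity-cost threshold (USD/QALY).
#' @param atkinson_aversion,kolm_aversion Inequality-aversion parameters.
#' @param include_treatment_costs Use total costs rather than diagnostic
#'   workup costs in the net-health-benefit calculation (requires the run to
#'   have been made with `treatment_costs = TRUE`).
#' @return A list of class `dcea_metrics` with element `per_draw` (a data
#'   frame, one row per draw) and the scalar baseline QALE indices.
#' @export
dcea_metrics <- function(object,
                         threshold = object$settings$threshold,
                         atkinson_aversion = object$settings$atkinson_aversion,
                         kolm_aversion = object$settings$kolm_aversion,
                         include_treatment_costs = FALSE) {
  params <- object$params
  sg <- params$subgroups
  cost_arr <- if (include_treatment_costs) {
    if (is.null(object$total_cost))
      stop_config("run dcea() with treatment_costs = TRUE for this scenario")
    object$total_cost
  } else object$diag_cost

  dq <- object$qaly[, , "LB-first", drop = FALSE][, , 1] -
    object$qaly[, , "TB-only", drop = FALSE][, , 1]
  dc <- cost_arr[, , "LB-first", drop = FALSE][, , 1] -
    cost_arr[, , "TB-only", drop = FALSE][, , 1]
  if (object$n_draws == 1) {
    dq <- matrix(dq, 1, dimnames = list(NULL, sg$id))
    dc <- matrix(dc, 1, dimnames = list(NULL, sg$id))
  }
  ps <- object$patient_shares
  gs <- object$general_shares
  risk <- lifetime_risk(params) * sg$insufficient_tissue

  dq_all <- as.numeric(dq %*% ps)
  dc_all <- as.numeric(dc %*% ps)
  opp <- as.numeric(dc %*% (gs * risk)) / threshold
  inhb <- sweep(sweep(dq, 2, risk, "*"), 1, opp, "-")
  inhb_all <- as.numeric(inhb %*% gs)

  a_pat <- lapply(STRATEGIES, function(s)
    as.numeric(atkinson_rows(object$qaly[, , s], ps, atkinson_aversion)))
  k_pat <- lapply(STRATEGIES, function(s)
    as.numeric(kolm_rows(object$qaly[, , s], ps, kolm_aversion)))
  names(a_pat) <- names(k_pat) <- STRATEGIES

  qale_pre <- sg$baseline_qale
  qale_post <- sweep(inhb, 2, qale_pre, "+")
  a_qale_pre <- if (atkinson_aversion == 0) 0 else
    atkinson_index(qale_pre, atkinson_aversion, weights = gs)
  k_qale_pre <- if (kolm_aversion == 0) 0 else
    kolm_index(qale_pre, kolm_aversion, weights = gs)
  a_qale_post <- as.numeric(atkinson_rows(qale_post, gs, atkinson_aversion))
  k_qale_post <- as.numeric(kolm_rows(qale_post, gs, kolm_aversion))

  mu_pat <- list("TB-only" = as.numeric(object$qaly[, , "TB-only"] %*% ps),
                 "LB-first" = as.numeric(object$qaly[, , "LB-first"] %*% ps))
  mu_qale_pre <- sum(gs * qale_pre)
  mu_qale_post <- as.numeric(qale_post %*% gs)

  per_draw <- data.frame(
    draw = seq_len(object$n_draws),
    dq, dq_all = dq_all, dc_all = dc_all,
    inhb_per_100k = inhb * 1e5, inhb_all_per_100k = inhb_all * 1e5,
    atkinson_tb = a_pat[["TB-only"]], atkinson_lb = a_pat[["LB-first"]],
    kolm_tb = k_pat[["TB-only"]], kolm_lb = k_pat[["LB-first"]],
    atkinson_qale_post = a_qale_post, kolm_qale_post = k_qale_post,
    ede_qaly_tb = mu_pat[["TB-only"]] * (1 - a_pat[["TB-only"]]),
    ede_qaly_lb = mu_pat[["LB-first"]] * (1 - a_pat[["LB-first"]]),
    ede_qale_pre = mu_qale_pre * (1 - a_qale_pre),
    ede_qale_post = mu_qale_post * (1 - a_qale_post),
    check.names = FALSE
  )
  names(per_draw)[2:(1 + ncol(dq))] <- paste0("dq_", sg$id)

  structure(list(
    per_draw = per_draw,
    atkinson_qale_pre = a_qale_pre,
    kolm_qale_pre = k_qale_pre,
    threshold = threshold,
    atkinson_aversion = atkinson_aversion,
    kolm_aversion = kolm_aversion,
    include_treatment_costs = include_treatment_costs,
    subgroups = sg$id
  ), class = "dcea_metrics")
}

#' Summarise a fitted distributional cost-effectiveness analysis
#'
#' Means and 95% uncertainty intervals (2.5th/97.5th percentiles across
#' draws) of per-patient QALYs and diagnostic costs by strategy and subgroup,
#' incremental outcomes, per-capita incremental net health benefit, the
#' inequality indices under both strategies with their difference and
#' relative change, and the probabilities of the equity-impact-plane
#' quadrants.
#'
#' @param object A `dcea` object.
#' @param ... Passed to [dcea_metrics()] (e.g. `threshold`,
#'   `atkinson_aversion`).
#' @return An object of class `summary.dcea`.
#' @export
summary.dcea <- function(object, ...) {
  m <- dcea_metrics(object, ...)
  pd <- m$per_draw
  sgs <- object$params$subgroups$id
  summ3 <- function(v) summarize_draws(v)

  qaly_tab <- do.call(rbind, lapply(c(sgs, "All"), function(g) {
    pick <- function(s) if (g == "All") object$qaly[, , s] %*% object$patient_shares
    else object$qaly[, g, s]
    data.frame(group = g,
               t(c(tb = summ3(as.numeric(pick("TB-only"))),
                   lb = summ3(as.numeric(pick("LB-first"))),
                   d = summ3(as.numeric(pick("LB-first")) - as.numeric(pick("TB-only"))))))
  }))
  cost_tab <- do.call(rbind, lapply(c(sgs, "All"), function(g) {
    pick <- function(s) if (g == "All") object$diag_cost[, , s] %*% object$patient_shares
    else object$diag_cost[, g, s]
    data.frame(group = g,
               t(c(tb = summ3(as.numeric(pick("TB-only"))),
                   lb = summ3(as.numeric(pick("LB-first"))),
                   d = summ3(as.numeric(pick("LB-first")) - as.numeric(pick("TB-only"))))))
  }))
  inhb_cols <- c(paste0("inhb_per_100k.", sgs), "inhb_all_per_100k")
  colnames(pd) <- sub("^inhb_per_100k\\.", "inhb_per_100k.", colnames(pd))
  inhb_tab <- do.call(rbind, lapply(seq_along(c(sgs, "All")), function(i) {
    g <- c(sgs, "All")[i]
    v <- if (g == "All") pd$inhb_all_per_100k else pd[[paste0("inhb_per_100k.", g)]]
    data.frame(group = g, t(summ3(v)))
  }))

  rel_atk <- 100 * (pd$atkinson_lb - pd$atkinson_tb) / pd$atkinson_tb
  rel_kolm <- 100 * (pd$kolm_lb - pd$kolm_tb) / pd$kolm_tb
  rel_qale_atk <- if (m$atkinson_qale_pre > 0)
    100 * (pd$atkinson_qale_post - m$atkinson_qale_pre) / m$atkinson_qale_pre
  else rep(NA_real_, nrow(pd))

  ineq_tab <- rbind(
    data.frame(outcome = "QALY (patient)", family = "Atkinson",
               aversion = m$atkinson_aversion,
               t(c(tb = summ3(pd$atkinson_tb), lb = summ3(pd$atkinson_lb),
                   d = summ3(pd$atkinson_lb - pd$atkinson_tb),
                   rel = summ3(rel_atk)))),
    data.frame(outcome = "QALY (patient)", family = "Kolm",
               aversion = m$kolm_aversion,
               t(c(tb = summ3(pd$kolm_tb), lb = summ3(pd$kolm_lb),
                   d = summ3(pd$kolm_lb - pd$kolm_tb),
                   rel = summ3(rel_kolm)))),
    data.frame(outcome = "QALE (general)", family = "Atkinson",
               aversion = m$atkinson_aversion,
               t(c(tb = c(mean = m$atkinson_qale_pre, p2_5 = m$atkinson_qale_pre,
                          p97_5 = m$atkinson_qale_pre),
                   lb = summ3(pd$atkinson_qale_post),
                   d = summ3(pd$atkinson_qale_post - m$atkinson_qale_pre),
                   rel = summ3(rel_qale_atk)))),
    data.frame(outcome = "QALE (general)", family = "Kolm",
               aversion = m$kolm_aversion,
               t(c(tb = c(mean = m$kolm_qale_pre, p2_5 = m$kolm_qale_pre,
                          p97_5 = m$kolm_qale_pre),
                   lb = summ3(pd$kolm_qale_post),
                   d = summ3(pd$kolm_qale_post - m$kolm_qale_pre),
                   rel = summ3(100 * (pd$kolm_qale_post - m$kolm_qale_pre) /
                                 m$kolm_qale_pre))))
  )

  quadrants <- c(
    qaly_gain_ineq_increase = mean(pd$dq_all > 0 &
                                     pd$atkinson_lb > pd$atkinson_tb),
    general_gain_no_ineq_increase = mean(pd$inhb_all_per_100k > 0 &
                                           pd$atkinson_qale_post <= m$atkinson_qale_pre)
  )

  structure(list(qaly = qaly_tab, diag_cost = cost_tab, inhb = inhb_tab,
                 inequality = ineq_tab, quadrants = quadrants,
                 metrics = m, n_draws = object$n_draws,
                 settings = object$settings, seed = object$seed),
            class = "summary.dcea")
}

#' @export
print.summary.dcea <- function(x, digits = 3, ...) {
  fmt <- function(m, lo, hi, d = digits)
    sprintf("%.*f (%.*f to %.*f)", d, m, d, lo, d, hi)
  cat(sprintf("Distributional cost-effectiveness analysis: LB-first vs TB-only (%d draws)\n\n",
              x$n_draws))
  cat("Discounted QALYs per patient:\n")
  q <- x$qaly
  for (i in seq_len(nrow(q)))
    cat(sprintf("  %-9s TB-only %s | LB-first %s | diff %s\n", q$group[i],
                fmt(q$tb.mean[i], q$tb.p2_5[i], q$tb.p97_5[i], 2),
                fmt(q$lb.mean[i], q$lb.p2_5[i], q$lb.p97_5[i], 2),
                fmt(q$d.mean[i], q$d.p2_5[i], q$d.p97_5[i], 2)))
  cat("\nDiagnostic workup costs per patient (USD):\n")
  co <- x$diag_cost
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %-9s TB-only %s | LB-first %s | diff %s\n", co$group[i],
                fmt(co$tb.mean[i], co$tb.p2_5[i], co$tb.p97_5[i], 0),
                fmt(co$lb.mean[i], co$lb.p2_5[i], co$lb.p97_5[i], 0),
                fmt(co$d.mean[i], co$d.p2_5[i], co$d.p97_5[i], 0)))
  cat(sprintf("\nIncremental NHB per 100,000 general population (threshold $%s/QALY):\n",
              format(x$metrics$threshold, big.mark = ",")))
  nh <- x$inhb
  for (i in seq_len(nrow(nh)))
    cat(sprintf("  %-9s %s\n", nh$group[i], fmt(nh$mean[i], nh$p2_5[i], nh$p97_5[i], 0)))
  cat("\nInequality indices:\n")
  iq <- x$inequality
  for (i in seq_len(nrow(iq)))
    cat(sprintf("  %-15s %-8s (aversion %g): TB %s | LB %s | rel. change %s%%\n",
                iq$outcome[i], iq$family[i], iq$aversion[i],
                fmt(iq$tb.mean[i], iq$tb.p2_5[i], iq$tb.p97_5[i], 5),
                fmt(iq$lb.mean[i], iq$lb.p2_5[i], iq$lb.p97_5[i], 5),
                fmt(iq$rel.mean[i], iq$rel.p2_5[i], iq$rel.p97_5[i], 2)))
  cat(sprintf("\nP(QALY gain & patient-inequality increase): %.3f\n",
              x$quadrants["qaly_gain_ineq_increase"]))
  cat(sprintf("P(general-population gain without inequality increase): %.3f\n",
              x$quadrants["general_gain_no_ineq_increase"]))
  invisible(x)
}

#' @export
print.dcea <- function(x, ...) {
  cat(sprintf("dcea: %d PSA draws, seed %s, TAT scenario %s, %s costs\n",
              x$n_draws, format(x$seed), x$settings$tat_scenario,
              if (is.null(x$total_cost)) "diagnostic" else "diagnostic + treatment"))
  dq <- x$qaly[, , "LB-first"] %*% x$patient_shares -
    x$qaly[, , "TB-only"] %*% x$patient_shares
  if (length(dq))
    cat(sprintf("  mean incremental QALYs per patient: %.3f\n", mean(dq)))
  cat("  use summary() for the full distributional results\n")
  invisible(x)
}

#' Equity-impact plane of a fitted analysis
#'
#' Scatter of per-draw average health gain against the change in inequality:
#' incremental QALYs per patient versus the change in the patient-population
#' Atkinson index (`population = "patient"`), or incremental QALE per 100,000
#' members of the general population versus the change in the QALE Atkinson
#' index (`population = "general"`). Inequality reduction is plotted to the
#' right, as on an equity-impact plane.
#'
#' @param x A `dcea` object.
#' @param population `"patient"` or `"general"`.
#' @param ... Passed to [dcea_metrics()].
#' @return The per-draw coordinates, invisibly.
#' @export
plot.dcea <- function(x, population = c("patient", "general"), ...) {
  population <- match.arg(population)
  m <- dcea_metrics(x, ...)
  pd <- m$per_draw
  if (population == "patient") {
    xv <- -(pd$atkinson_lb - pd$atkinson_tb)
    yv <- pd$dq_all
    xlab <- "Reduction in Atkinson index of patient QALYs"
    ylab <- "Incremental QALYs per patient"
  } else {
    xv <- -(pd$atkinson_qale_post - m$atkinson_qale_pre)
    yv <- pd$inhb_all_per_100k
    xlab <- "Reduction in Atkinson index of general-population QALE"
    ylab <- "Incremental QALE per 100,000 general population"
  }
  graphics::plot(xv, yv, pch = 16, cex = 0.4, col = "#00000080",
                 xlab = xlab, ylab = ylab)
  graphics::abline(h = 0, v = 0, lty = 2)
  invisible(data.frame(inequality_reduction = xv, health_gain = yv))
}

#' Run scenario analyses over thresholds, aversions and turnaround times
#'
#' Re-evaluates the model under a grid of analysis settings with shared random
#' numbers: the survival/cost core is run once per turnaround-time scenario
#' with the same master seed (identical per-draw parameter sets), and
#' thresholds and aversion parameters are applied as post-processing, so
#' scenario contrasts are low-variance.
#'
#' @param params A `dcea_params` object.
#' @param n_draws,seed As in [dcea()].
#' @param tat_scenarios Character vector of turnaround-time scenarios.
#' @param thresholds Opportunity-cost thresholds (USD/QALY).
#' @param atkinson_grid,kolm_grid Aversion grids.
#' @param include_treatment_costs Logical vector of cost perspectives to run.
#' @return A list of class `dcea_scenarios`: `fits` (one `dcea` per TAT
#'   scenario) and `grid` (a data frame with one row per scenario and the
#'   summary statistics of incremental NHB and inequality change, plus EDE
#'   values per aversion).
#' @export
dcea_scenarios <- function(params = dcea_parameters(), n_draws = 1000, seed = 1,
                           tat_scenarios = c("3-week", "1-week"),
                           thresholds = c(50000, 100000, 150000, 200000),
                           atkinson_grid = c(0, 0.9, 5, 11, 15),
                           kolm_grid = c(0, 0.025, 0.1, 0.15, 0.3),
                           include_treatment_costs = c(FALSE, TRUE)) {
  fits <- lapply(tat_scenarios, function(ts)
    dcea(params, n_draws = n_draws, seed = seed, tat_scenario = ts,
         treatment_costs = any(include_treatment_costs)))
  names(fits) <- tat_scenarios

  rows <- list()
  for (ts in tat_scenarios) for (tc in include_treatment_costs)
    for (th in thresholds) for (eps in atkinson_grid) {
      m <- dcea_metrics(fits[[ts]], threshold = th, atkinson_aversion = eps,
                        include_treatment_costs = tc)
      pd <- m$per_draw
      d_ede <- pd$ede_qaly_lb - pd$ede_qaly_tb
      d_ede_qale <- pd$ede_qale_post - pd$ede_qale_pre
      rows[[length(rows) + 1]] <- data.frame(
        tat = ts, treatment_costs = tc, threshold = th, atkinson_aversion = eps,
        dq_all = mean(pd$dq_all),
        inhb_all_per_100k = mean(pd$inhb_all_per_100k),
        atkinson_tb = mean(pd$atkinson_tb), atkinson_lb = mean(pd$atkinson_lb),
        d_ede_qaly = mean(d_ede),
        d_ede_qaly_lo = unname(summarize_draws(d_ede)["p2_5"]),
        d_ede_qaly_hi = unname(summarize_draws(d_ede)["p97_5"]),
        d_ede_qale_per_100k = mean(d_ede_qale) * 1e5
      )
    }
  structure(list(fits = fits, grid = do.call(rbind, rows),
                 kolm_grid = kolm_grid, seed = seed),
            class = "dcea_scenarios")
}

#' Write analysis outputs as delimited text files
#'
#' Emits the result tables of a fitted analysis into a directory:
#' strategy-by-subgroup outcome summaries (`outcomes_by_subgroup.tsv`),
#' inequality indices (`inequality_indices.tsv`), per-draw equity-plane
#' coordinates (`equity_plane.tsv`), EDE-versus-aversion curves
#' (`ede_curves.tsv`) and a run-metadata document (`run_metadata.yaml`).
#'
#' @param object A `dcea` object.
#' @param out_dir Output directory (created if needed).
#' @param atkinson_grid Aversion grid for the EDE curves.
#' @return Data frame manifest (file, rows), invisibly.
#' @export
write_outputs <- function(object, out_dir,
                          atkinson_grid = c(0, 0.9, 5, 11, 15)) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop_config("cannot create output directory: %s", out_dir)
  }
  s <- summary(object)
  m <- s$metrics
  pd <- m$per_draw

  files <- list()
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    files[[length(files) + 1]] <<- data.frame(file = name, rows = nrow(df))
  }

  put(cbind(outcome = "QALYs per patient", s$qaly), "outcomes_by_subgroup.tsv")
  put(s$inequality, "inequality_indices.tsv")
  plane <- data.frame(
    draw = pd$draw,
    dq_all = pd$dq_all,
    d_atkinson_patient = pd$atkinson_lb - pd$atkinson_tb,
    inhb_all_per_100k = pd$inhb_all_per_100k,
    d_atkinson_qale = pd$atkinson_qale_post - m$atkinson_qale_pre
  )
  put(plane, "equity_plane.tsv")
  ede <- do.call(rbind, lapply(atkinson_grid, function(eps) {
    mm <- dcea_metrics(object, atkinson_aversion = eps)
    p <- mm$per_draw
    data.frame(atkinson_aversion = eps,
               d_ede_qaly = mean(p$ede_qaly_lb - p$ede_qaly_tb),
               d_ede_qale_per_100k = mean(p$ede_qale_post - p$ede_qale_pre) * 1e5)
  }))
  put(ede, "ede_curves.tsv")
  meta <- list(n_draws = object$n_draws, seed = object$seed,
               settings = object$settings,
               package_version = as.character(utils::packageVersion("lbdcea")),
               r_version = R.version.string)
  yaml::write_yaml(meta, file.path(out_dir, "run_metadata.yaml"))
  files[[length(files) + 1]] <- data.frame(file = "run_metadata.yaml", rows = NA)

  invisible(do.call(rbind, files))
}
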