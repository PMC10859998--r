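## Costs are computed under a blended payer perspective: a fixed Medicare /
## commercial mix applied to payer-specific unit costs. Diagnostic workup
## costs accrue at time zero (no discounting); treatment and disease-
## management costs (scenario analyses only) accrue over discounted state
## occupancy from the partitioned-survival model.

payer_blend <- function(unit_costs, payer_mix) sum(payer_mix * unit_costs)

## Expected blended cost of the tests performed on one branch type.
## Rebiopsy cost pools the complication outcome:
## (1 - p) * rebiopsy + p * rebiopsy-with-complication, per payer.
diagnostic_unit_cost <- function(tests, cost_params, complication_prob) {
  mix <- cost_params$payer_mix
  rebiopsy_eff <- (1 - complication_prob) * cost_params$rebiopsy +
    complication_prob * cost_params$rebiopsy_complication
  lb <- payer_blend(cost_params$lb_ngs, mix)
  tb <- payer_blend(rebiopsy_eff + cost_params$tb_ngs, mix)
  switch(tests, "LB" = lb, "TB" = tb, "LB+TB" = lb + tb,
         stop_config("unknown test combination: %s", tests))
}

#' Expected diagnostic-workup cost of a branch set
#'
#' Probability-weighted blended-payer cost of the tests performed across all
#' terminal branches: liquid-biopsy NGS, tissue rebiopsy (pooling the
#' complication probability) and tissue NGS. Diagnostic costs accrue at the
#' time of diagnosis and are not discounted.
#'
#' @param branches Branch data frame from [enumerate_branches()] (or any data
#'   frame with `prob` and `tests` columns).
#' @param cost_params The `costs` element of a `dcea_params` object.
#' @param complication_prob Probability of a rebiopsy complication; defaults
#'   to the point estimate in `cost_params`.
#' @return Expected cost in USD.
#' @export
#' @examples
#' p <- dcea_parameters()
#' d <- point_estimate_draw(p)
#' br <- enumerate_branches("TB-only", d, "NH-White")
#' diagnostic_workup_cost(br, p$costs)  # ~4072
diagnostic_workup_cost <- function(branches, cost_params,
                                   complication_prob = cost_params$complication_prob) {
  unit <- vapply(unique(branches$tests), diagnostic_unit_cost, numeric(1),
                 cost_params = cost_params, complication_prob = complication_prob)
  sum(branches$prob * unit[branches$tests])
}

## Discounted first-line drug cost for one branch: annualized year-indexed
## rates (year 1 / year 2 / year 2+) accrued over discounted pre-progression
## occupancy, using pre-progression time as the proxy for time on first-line
## treatment. `t_pre_disc_year` is the discounted occupancy within each model
## year. An optional cap (years of drug cost) truncates accrual.
drug_cost_first_line <- function(context, t_pre_disc_year, drug, cap_years = Inf) {
  row <- drug[drug$context == context, ]
  if (nrow(row) != 1) stop_config("no drug-cost row for therapy context: %s", context)
  ny <- length(t_pre_disc_year)
  rates <- c(row$year1, row$year2, rep(row$year2plus, max(0, ny - 2)))[seq_len(ny)]
  if (is.finite(cap_years)) rates[seq_len(ny) > cap_years] <- 0
  sum(rates * t_pre_disc_year)
}

#' Treatment and disease-management cost of a branch
#'
#' First-line drug cost accrues the year-indexed annualized rate of the
#' branch's therapy context over discounted pre-progression time; second-line
#' drug cost accrues the second-line annualized rate over a fraction of
#' discounted post-progression time (the published second-line-duration
#' ratio), among the share of patients not opting for best supportive care;
#' disease-management costs accrue blended annualized pre-/post-progression
#' rates over the respective discounted occupancies.
#'
#' @param context Therapy context of the branch (e.g. `"EGFR"`, `"PD-L1>=50"`,
#'   `"wild type"`).
#' @param health_outcome A `health_outcome` from [branch_health_outcome()] for
#'   the same branch, or a list with `t_pre_disc`, `t_post_disc` and (for
#'   year-indexed accrual) `t_pre_disc_year`.
#' @param cost_params The `costs` element of a `dcea_params` object.
#' @param mgmt_pre,mgmt_post Per-payer annualized management costs; default to
#'   the point estimates (a PSA draw supplies its own).
#' @param io_cap_years Optional cap on years of first-line drug-cost accrual.
#' @return A list: `drug_first_line`, `drug_second_line`, `management`,
#'   `total`, all discounted USD.
#' @export
treatment_management_cost <- function(context, health_outcome, cost_params,
                                      mgmt_pre = cost_params$mgmt_pre,
                                      mgmt_post = cost_params$mgmt_post,
                                      io_cap_years = Inf) {
  tpre_y <- health_outcome$t_pre_disc_year
  if (is.null(tpre_y)) tpre_y <- health_outcome$t_pre_disc  # single bucket, year-1 rate
  fl <- drug_cost_first_line(context, tpre_y, cost_params$drug, io_cap_years)
  row <- cost_params$drug[cost_params$drug$context == context, ]
  sl <- (1 - cost_params$bsc_fraction) * row$second_line *
    row$sl_duration_ratio * health_outcome$t_post_disc
  mix <- cost_params$payer_mix
  mgmt <- payer_blend(mgmt_pre, mix) * health_outcome$t_pre_disc +
    payer_blend(mgmt_post, mix) * health_outcome$t_post_disc
  list(drug_first_line = fl, drug_second_line = sl, management = mgmt,
       total = fl + sl + mgmt)
}
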