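## Distributional metrics: Atkinson (relative) and Kolm (absolute) inequality
## indices over a weighted subgroup health distribution, the corresponding
## equally distributed equivalent (EDE) health, per-capita net health benefit
## with equally distributed opportunity costs, and the QALE shift that turns
## per-patient incremental outcomes into a general-population health
## distribution.

#' Construct a weighted health distribution
#'
#' @param values Per-subgroup health (QALYs per patient or QALE per member of
#'   the general population).
#' @param weights Population shares; normalised to sum to 1.
#' @param level `"patient"` or `"general"`, a bookkeeping tag.
#' @return An object of class `health_distribution`.
#' @export
health_distribution <- function(values, weights, level = c("patient", "general")) {
  level <- match.arg(level)
  if (length(values) != length(weights))
    stop_config("health_distribution: values and weights differ in length")
  if (any(weights < 0) || sum(weights) <= 0)
    stop_config("health_distribution: weights must be non-negative and not all zero")
  structure(list(values = as.numeric(values), weights = weights / sum(weights),
                 level = level, subgroups = names(values)),
            class = "health_distribution")
}

as_dist <- function(dist, weights = NULL) {
  if (inherits(dist, "health_distribution")) return(dist)
  if (is.null(weights)) stop_config("weights required when not passing a health_distribution")
  health_distribution(dist, weights)
}

#' Atkinson inequality index
#'
#' Relative (scale-invariant) inequality of a weighted health distribution:
#' \deqn{A_\epsilon = 1 - \left[\sum_i w_i (y_i/\mu)^{1-\epsilon}\right]^{1/(1-\epsilon)}}
#' with weighted mean \eqn{\mu}. Zero iff all values are equal; increases with
#' the inequality-aversion parameter on any unequal distribution.
#'
#' @param dist A [health_distribution()], or a numeric vector with `weights`.
#' @param eps Inequality aversion, `eps >= 0`, `eps != 1`.
#' @param weights Optional weights when `dist` is a plain vector.
#' @return The index, in `[0, 1)`.
#' @export
#' @examples
#' atkinson_index(c(68.798, 65.446, 74.878, 71.762),
#'                eps = 11, weights = c(0.6057, 0.1389, 0.0623, 0.1931))
atkinson_index <- function(dist, eps, weights = NULL) {
  d <- as_dist(dist, weights)
  if (eps < 0) stop_config("atkinson_index: eps must be >= 0")
  if (eps == 1) stop_config("atkinson_index: eps = 1 is not supported")
  if (any(d$values <= 0))
    stop_config("atkinson_index: values must be positive for a relative index")
  mu <- sum(d$weights * d$values)
  1 - sum(d$weights * (d$values / mu)^(1 - eps))^(1 / (1 - eps))
}

#' Kolm inequality index
#'
#' Absolute (translation-invariant) inequality of a weighted health
#' distribution:
#' \deqn{K_\alpha = \frac{1}{\alpha}\log \sum_i w_i e^{\alpha(\mu - y_i)}}
#'
#' @inheritParams atkinson_index
#' @param alpha Inequality aversion, `alpha > 0`.
#' @return The index, `>= 0`.
#' @export
kolm_index <- function(dist, alpha, weights = NULL) {
  d <- as_dist(dist, weights)
  if (alpha <= 0) stop_config("kolm_index: alpha must be positive")
  mu <- sum(d$weights * d$values)
  log(sum(d$weights * exp(alpha * (mu - d$values)))) / alpha
}

#' Equally distributed equivalent health
#'
#' The uniform level of health that would yield the same social welfare as the
#' actual distribution: `mu * (1 - A)` for the Atkinson family, `mu - K` for
#' the Kolm family. Always at most the weighted mean, with equality iff the
#' distribution is degenerate or aversion is zero.
#'
#' @inheritParams atkinson_index
#' @param aversion Aversion parameter of the chosen family.
#' @param family `"atkinson"` or `"kolm"`.
#' @return EDE health value.
#' @export
ede <- function(dist, aversion, family = c("atkinson", "kolm"), weights = NULL) {
  family <- match.arg(family)
  d <- as_dist(dist, weights)
  mu <- sum(d$weights * d$values)
  if (family == "atkinson") mu * (1 - atkinson_index(d, aversion))
  else mu - kolm_index(d, aversion)
}

#' Per-capita incremental net health benefit with equally distributed
#' opportunity costs
#'
#' Converts per-patient incremental QALYs and costs into net health benefit
#' per member of the general population by subgroup:
#' \deqn{iNHB_g = r_g \Delta QALY_g - \frac{\sum_h w_h r_h \Delta Cost_h}{\tau}}
#' where `r_g` is the risk of belonging to the target patient population
#' (lifetime risk of advanced NSCLC times the insufficient-tissue fraction),
#' `w_h` the general-population shares, and `tau` the opportunity-cost
#' threshold. The bracketed opportunity-cost term is identical for every
#' subgroup: health forgone elsewhere is assumed equally distributed. The
#' overall iNHB is the share-weighted sum and equals the iNHB computed from
#' pooled increments.
#'
#' @param delta_qalys,delta_costs Named per-subgroup incremental QALYs and
#'   costs per patient.
#' @param params A `dcea_params` object (for shares and lifetime risks).
#' @param threshold Opportunity-cost threshold in USD per QALY.
#' @return List with `by_subgroup` (per general-population member), `overall`,
#'   and `per_100k` scaled versions.
#' @export
per_capita_inhb <- function(delta_qalys, delta_costs, params,
                            threshold = params$settings$threshold) {
  if (threshold <= 0) stop_config("per_capita_inhb: threshold must be positive")
  sg <- params$subgroups
  risk <- lifetime_risk(params) * sg$insufficient_tissue
  w <- sg$general_share
  opp <- sum(w * risk * delta_costs) / threshold
  inhb <- risk * delta_qalys - opp
  names(inhb) <- sg$id
  list(by_subgroup = inhb,
       overall = sum(w * inhb),
       per_100k = inhb * 1e5,
       overall_per_100k = sum(w * inhb) * 1e5,
       opportunity_cost_per_capita = opp)
}

#' Shift a baseline QALE distribution by per-capita net health benefit
#'
#' @param baseline_dist A general-population [health_distribution()] of QALE.
#' @param inhb_per_person Per-subgroup iNHB per general-population member, in
#'   the same subgroup order.
#' @return The shifted `health_distribution`.
#' @export
qale_shift <- function(baseline_dist, inhb_per_person) {
  d <- as_dist(baseline_dist)
  if (length(inhb_per_person) != length(d$values))
    stop_config("qale_shift: misaligned subgroups")
  if (!is.null(names(inhb_per_person)) && !is.null(d$subgroups) &&
      !identical(names(inhb_per_person), d$subgroups))
    stop_config("qale_shift: subgroup names do not match")
  d$values <- d$values + as.numeric(inhb_per_person)
  d
}

#' Health inequality impact
#'
#' Difference between the inequality index after and before the intervention
#' (or between intervention and comparator). A positive difference is an
#' increase in inequality. The relative change is reported in percent of the
#' pre-intervention index.
#'
#' @param pre_index,post_index Indices of the same family and aversion.
#' @return List with `absolute` (post - pre) and `relative_pct`
#'   (100 (post - pre) / pre; `NA` with a warning flag when `pre` is 0).
#' @export
inequality_impact <- function(pre_index, post_index) {
  delta <- post_index - pre_index
  rel <- if (pre_index == 0) NA_real_ else 100 * delta / pre_index
  list(absolute = delta, relative_pct = rel, undefined_relative = pre_index == 0)
}
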