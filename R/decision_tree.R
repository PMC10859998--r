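## Diagnostic decision tree for the two testing strategies.
##
## LB-first: every patient receives liquid-biopsy NGS. A positive LB result
## (true positive for the patient's driver mutation, or false positive for
## some mutation in a no-driver patient) triggers targeted therapy with the
## turnaround-time (TAT) benefit. A negative LB result triggers a tissue
## rebiopsy with TB NGS; its result (and, when mutation-negative, the PD-L1
## tumor proportion score measured on the tissue specimen) determines therapy
## without the TAT benefit.
##
## TB-only: every patient receives the rebiopsy + TB NGS pathway directly.
##
## Positive-call allocation among the mutually exclusive markers is
## sequential in the published marker order (EGFR first): each marker's call
## is conditional on all previous markers testing negative, preserving mutual
## exclusivity of the assigned therapy. A patient whose true mutation is m
## tests positive on marker m with the sensitivity and false-positive on any
## other marker with one minus its specificity; a no-driver patient can only
## test false-positive. The overall probability of a negative panel for a
## true-m patient is therefore (1 - Se_m) * prod(Sp_m'), which reproduces the
## published expected diagnostic costs of the LB-first strategy per subgroup.
## PD-L1 is tissue-only and dichotomised as TPS>=50 versus not for
## misclassification: a false-negative TPS>=50 patient is treated in the
## TPS 1-49 (chemo-immunotherapy) context, a false-positive patient in the
## TPS>=50 (immunotherapy monotherapy) context.

PDL1_SUBTREE <- data.frame(
  stratum = c("TPS>=50", "TPS>=50", "TPS1-49", "TPS1-49", "TPS<1", "TPS<1"),
  result  = c("TP", "FN", "TN", "FP", "TN", "FP"),
  context = c("PD-L1>=50", "PD-L1 1-49", "PD-L1 1-49", "PD-L1>=50",
              "wild type", "PD-L1>=50"),
  label_fn_mut = c("TP PD-L1 + FN mut.", "FN PD-L1 + FN mut.",
                   "TN PD-L1 + FN mut.", "FP PD-L1 + FN mut.",
                   "TN PD-L1 + FN mut.", "FP PD-L1 + FN mut."),
  label_tn_mut = c(NA, "FN PD-L1 + TN mut.", NA, "FP PD-L1 + TN mut.",
                   NA, "FP PD-L1 + TN mut."),
  stringsAsFactors = FALSE
)

## Fast internal builder: returns a list of parallel vectors.
branch_table <- function(strategy, draw, subgroup,
                         tat_scenario = "3-week",
                         calibration_scope = "both") {
  if (!subgroup %in% draw$subgroups)
    stop_config("unknown subgroup: %s", subgroup)
  strategy <- match.arg(strategy, c("LB-first", "TB-only"))
  muts <- draw$mutation_names
  prev <- draw$prevalence[subgroup, ]
  pdl1 <- draw$pdl1[subgroup, ]
  nmut <- length(muts)

  acc <- new.env(parent = emptyenv())
  acc$true_state <- acc$outcome <- acc$context <- acc$mismatch <- acc$tests <- list()
  acc$prob <- acc$lb_triggered <- list()
  n_add <- 0L
  add <- function(true_state, outcome, context, prob, mismatch, lb_triggered, tests) {
    k <- length(prob)
    n_add <<- n_add + 1L
    acc$true_state[[n_add]] <- rep_len(true_state, k)
    acc$outcome[[n_add]] <- outcome
    acc$context[[n_add]] <- rep_len(context, k)
    acc$prob[[n_add]] <- prob
    acc$mismatch[[n_add]] <- rep_len(mismatch, k)
    acc$lb_triggered[[n_add]] <- rep_len(lb_triggered, k)
    acc$tests[[n_add]] <- rep_len(tests, k)
  }

  ## Sequential panel over the eight markers: positive-call probabilities and
  ## the probability of a fully negative panel, for a given true state.
  panel <- function(true_state, se, sp) {
    p_pos <- 1 - sp
    if (true_state != "none") p_pos[true_state] <- se[true_state]
    cneg <- cumprod(1 - p_pos)
    list(p_call = c(1, cneg[-nmut]) * p_pos, p_neg = cneg[nmut])
  }

  pdl1_se <- draw$tb_se  # PD-L1 assessed on tissue with TB performance
  pdl1_sp <- draw$tb_sp
  add_pdl1 <- function(weight, mut_status, true_state, prefix, tests) {
    if (weight <= 0) return(invisible())
    p_strat <- pdl1[c(1, 1, 2, 2, 3, 3)]
    p_res <- c(pdl1_se, 1 - pdl1_se, pdl1_sp, 1 - pdl1_sp, pdl1_sp, 1 - pdl1_sp)
    lab <- if (mut_status == "fn") PDL1_SUBTREE$label_fn_mut else PDL1_SUBTREE$label_tn_mut
    ts <- if (true_state == "none")
      paste0("none:", PDL1_SUBTREE$stratum) else rep(true_state, 6)
    add(ts,
        paste0(prefix, "+PD-L1-", PDL1_SUBTREE$result, ":", PDL1_SUBTREE$stratum),
        PDL1_SUBTREE$context,
        weight * p_strat * p_res,
        lab, FALSE, tests)
  }

  se_tb <- rep(draw$tb_se, nmut)
  sp_tb <- rep(draw$tb_sp, nmut)
  names(se_tb) <- names(sp_tb) <- muts

  ## Tissue NGS sub-tree entered with the given per-true-state weights.
  add_tb_subtree <- function(weight_by_state, via, tests) {
    for (s in c(muts, "none")) {
      w <- weight_by_state[[s]]
      if (w <= 0) next
      pn <- panel(s, se_tb, sp_tb)
      tp <- muts == s
      add(s,
          paste0(via, "TB-", ifelse(tp, "TP", "FP"), ":", muts),
          muts, w * pn$p_call,
          ifelse(tp, NA_character_, paste("FP", muts)), FALSE, tests)
      add_pdl1(w * pn$p_neg, if (s == "none") "tn" else "fn", s,
               paste0(via, "TB-", if (s == "none") "TN" else "FN"), tests)
    }
  }

  if (strategy == "TB-only") {
    add_tb_subtree(as.list(prev), "", "TB")
  } else {
    tb_weights <- list()
    for (s in c(muts, "none")) {
      ps <- prev[[s]]
      pn <- panel(s, draw$lb_se, draw$lb_sp)
      tp <- muts == s
      add(s,
          paste0("LB-", ifelse(tp, "TP", "FP"), ":", muts),
          muts, ps * pn$p_call,
          ifelse(tp, NA_character_, paste("FP", muts)), TRUE, "LB")
      tb_weights[[s]] <- ps * pn$p_neg
    }
    add_tb_subtree(tb_weights, "LB-neg->", "LB+TB")
  }
  for (nm in ls(acc)) acc[[nm]] <- unlist(acc[[nm]], use.names = FALSE)

  total <- sum(acc$prob)
  if (abs(total - 1) > 1e-9)
    stop_config("internal consistency error: branch probabilities sum to %.12f", total)

  hr <- rep(1, length(acc$prob))
  cal <- draw$calibration_hr[[subgroup]]
  if (calibration_scope == "both") {
    hr <- hr * cal
  } else {
    hr <- hr * ifelse(acc$lb_triggered, 1, cal)
  }
  hr <- hr * ifelse(acc$context == "EGFR", draw$egfr_adjustment_hr[[subgroup]], 1)
  hr <- hr * ifelse(acc$lb_triggered, draw$tat_hr[[tat_scenario]], 1)
  mi <- !is.na(acc$mismatch)
  hr[mi] <- hr[mi] * draw$mismatch_hr[acc$mismatch[mi]]

  list(strategy = strategy, subgroup = subgroup,
       true_state = acc$true_state, outcome = acc$outcome,
       context = acc$context, prob = acc$prob,
       mismatch_label = acc$mismatch, lb_triggered = acc$lb_triggered,
       tests = acc$tests, hr_multiplier = unname(hr))
}

#' Enumerate the terminal branches of the diagnostic decision tree
#'
#' For a given strategy, parameter draw and subgroup, returns every terminal
#' path of the test-outcome tree with its probability, the therapy context
#' whose survival curves apply, the hazard-ratio multiplier bundled from the
#' subgroup calibration HR, the EGFR-therapy adjustment, the turnaround-time
#' benefit (liquid-biopsy-triggered therapy only) and any mismatched-therapy
#' HR, and the diagnostic tests performed on the path.
#'
#' @param strategy `"LB-first"` or `"TB-only"`.
#' @param draw A `dcea_draw` (see [point_estimate_draw()], [draw_parameter_set()]).
#' @param subgroup Subgroup id.
#' @param tat_scenario `"3-week"` (base case) or `"1-week"`.
#' @param calibration_scope `"both"` (subgroup calibration HR on every branch,
#'   the default) or `"tb-informed"` (only on branches whose therapy was not
#'   triggered by a positive liquid-biopsy result).
#' @return A data frame with one row per terminal branch: `strategy`,
#'   `subgroup`, `true_state`, `outcome`, `context`, `prob`, `mismatch_label`,
#'   `lb_triggered`, `tests`, `hr_multiplier`. Probabilities sum to 1.
#' @export
#' @examples
#' d <- point_estimate_draw(dcea_parameters())
#' br <- enumerate_branches("LB-first", d, "NH-White")
#' sum(br$prob)
#' br[br$outcome == "LB-TP:EGFR", c("prob", "context", "hr_multiplier")]
enumerate_branches <- function(strategy, draw, subgroup,
                               tat_scenario = "3-week",
                               calibration_scope = "both") {
  bt <- branch_table(strategy, draw, subgroup, tat_scenario, calibration_scope)
  data.frame(strategy = bt$strategy, subgroup = bt$subgroup,
             true_state = bt$true_state, outcome = bt$outcome,
             context = bt$context, prob = bt$prob,
             mismatch_label = bt$mismatch_label, lb_triggered = bt$lb_triggered,
             tests = bt$tests, hr_multiplier = bt$hr_multiplier,
             stringsAsFactors = FALSE)
}

#' Total probability of branches matching a predicate
#'
#' @param branches A branch data frame from [enumerate_branches()].
#' @param predicate A function taking the branch data frame and returning a
#'   logical vector selecting rows.
#' @return Sum of probabilities of the selected branches.
#' @export
#' @examples
#' d <- point_estimate_draw(dcea_parameters())
#' br <- enumerate_branches("LB-first", d, "NH-White")
#' outcome_probability(br, function(b) grepl("TB", b$tests))  # rebiopsy performed
outcome_probability <- function(branches, predicate) {
  sel <- predicate(branches)
  if (!is.logical(sel) || length(sel) != nrow(branches))
    stop_config("predicate must return one logical per branch")
  sum(branches$prob[sel])
}
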