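test_that("branch probabilities conserve mass for every strategy, subgroup and draw", {
  for (g in PARAMS$subgroups$id) {
    for (s in c("LB-first", "TB-only")) {
      br <- enumerate_branches(s, POINT, g)
      expect_prob_vector(br$prob)
    }
  }
  for (i in 1:10) {
    d <- draw_parameter_set(PARAMS, i, master_seed = 7)
    br <- enumerate_branches("LB-first", d, "NH-Black")
    expect_prob_vector(br$prob)
  }
})

test_that("perfect tests collapse the tree to one matched branch per true state", {
  d <- perfect_test_draw()
  for (s in c("LB-first", "TB-only")) {
    br <- enumerate_branches(s, d, "NH-White")
    br <- br[br$prob > 0, ]
    expect_true(all(is.na(br$mismatch_label)))
    # mutation patients end on their own targeted therapy
    mut <- br[br$true_state %in% PARAMS$mutations$names, ]
    expect_equal(mut$context, mut$true_state)
    agg <- tapply(br$prob, br$true_state, sum)
    prev <- POINT$prevalence["NH-White", ]
    for (m in PARAMS$mutations$names)
      expect_equal(unname(agg[m]), unname(prev[m]), tolerance = 1e-12)
  }
})

test_that("the liquid-biopsy true-positive probability is prevalence times sensitivity", {
  br <- enumerate_branches("LB-first", POINT, "NH-White")
  # EGFR is first in the sequential panel, so no preceding-marker conditioning
  expect_lt(abs(br$prob[br$outcome == "LB-TP:EGFR"] - 0.129 * 0.700), 5e-4)
  expect_true(br$lb_triggered[br$outcome == "LB-TP:EGFR"])
})

test_that("with zero LB sensitivity and perfect LB specificity the downstream tree equals TB-only", {
  d <- POINT
  d$lb_se[] <- 0
  d$lb_sp[] <- 1
  lb <- enumerate_branches("LB-first", d, "Asian")
  tb <- enumerate_branches("TB-only", d, "Asian")
  expect_false(any(lb$lb_triggered[lb$prob > 0]))
  key <- function(b) { b <- b[b$prob > 0, ]
    tapply(b$prob, paste(b$context, b$mismatch_label), sum) }
  expect_equal(key(lb), key(tb), tolerance = 1e-12)
  # only cost events differ: every LB-first patient still had an LB
  expect_true(all(grepl("LB", lb$tests)))
})

test_that("raising a sensitivity moves mass onto matched therapy with the TAT benefit", {
  matched_tat <- function(se) {
    d <- POINT
    d$lb_se["EGFR"] <- se
    br <- enumerate_branches("LB-first", d, "NH-White")
    outcome_probability(br, function(b)
      b$lb_triggered & is.na(b$mismatch_label))
  }
  vals <- vapply(c(0.2, 0.5, 0.7, 0.9), matched_tat, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("outcome_probability sums matching branches", {
  br <- enumerate_branches("LB-first", POINT, "NH-White")
  expect_equal(outcome_probability(br, function(b) rep(TRUE, nrow(b))), 1)
  # rebiopsy performed iff the LB panel was negative
  p_reb <- outcome_probability(br, function(b) b$tests == "LB+TB")
  prev <- POINT$prevalence["NH-White", ]
  p_neg_m <- vapply(PARAMS$mutations$names, function(m)
    (1 - POINT$lb_se[[m]]) * prod(POINT$lb_sp[names(POINT$lb_sp) != m]),
    numeric(1))
  expected <- sum(prev[PARAMS$mutations$names] * p_neg_m) +
    prev[["none"]] * prod(POINT$lb_sp)
  expect_equal(p_reb, expected, tolerance = 1e-12)
  expect_error(outcome_probability(br, function(b) TRUE), "logical per branch")
})

test_that("hazard bundles compose calibration, EGFR adjustment, TAT and mismatch HRs", {
  br <- enumerate_branches("LB-first", POINT, "NH-White")
  # matched EGFR via LB, 3-week scenario: 1.345 * 0.675 * 0.72
  expect_equal(br$hr_multiplier[br$outcome == "LB-TP:EGFR"],
               1.345 * 0.675 * 0.72)
  # false-positive ALK via LB additionally carries the FP ALK HR 3.45
  expect_equal(br$hr_multiplier[br$outcome == "LB-FP:ALK" &
                                  br$true_state == "none"],
               1.345 * 0.72 * 3.45)
  # follow-up TB branches get no TAT benefit
  expect_equal(br$hr_multiplier[br$outcome == "LB-neg->TB-TP:EGFR"],
               1.345 * 0.675)
  crv <- weibull_curve(-1.1604, 0.1046)
  crv2 <- apply_hazard_bundle(crv, c("calibration", "egfr", "tat"), POINT, "NH-White")
  expect_equal(crv2$hr, 1.345 * 0.675 * 0.72)
  expect_equal(apply_hazard_bundle(crv, character(0), POINT, "NH-White")$hr, 1)
  expect_error(apply_hazard_bundle(crv, "no-such-label", POINT, "NH-White"),
               "unknown hazard")
})
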