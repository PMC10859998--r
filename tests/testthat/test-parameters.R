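test_that("packaged defaults reproduce the published inputs", {
  p <- PARAMS
  expect_equal(p$subgroups$general_share[1], 0.6057)
  expect_equal(p$subgroups$baseline_qale, c(68.798, 65.446, 74.878, 71.762))
  expect_equal(p$costs$complication_prob, 0.073)
  expect_equal(p$mutations$prevalence["Asian", "EGFR"], 0.524)
  # published LB EGFR sensitivity 0.700 is tp/(tp+fn) of the confusion vector
  expect_equal(POINT$lb_se[["EGFR"]], 0.700, tolerance = 0.005)
  expect_equal(POINT$lb_sp[["EGFR"]], 0.993, tolerance = 0.005)
  expect_equal(POINT$tb_se, 0.99)
  expect_equal(p$tat_hr$hr, c(0.72, 0.90))
})

test_that("every probability vector of a parameter draw sums to one", {
  expect_prob_vector(as.numeric(POINT$prevalence["NH-White", ]))
  for (g in PARAMS$subgroups$id) {
    expect_prob_vector(as.numeric(POINT$prevalence[g, ]))
    expect_prob_vector(as.numeric(POINT$pdl1[g, ]))
  }
})

test_that("lifetime risk is incidence times life expectancy, with override", {
  risk <- lifetime_risk(PARAMS)
  expect_equal(unname(risk["NH-White"]), 23.0e-5 * 78.8)
  expect_equal(round(100 * unname(risk["Asian"]), 2), 1.54)
  expect_equal(unname(risk["Hispanic"]), 11.6e-5 * 80.2)

  p0 <- PARAMS
  p0$subgroups$incidence_rate[1] <- 0
  expect_equal(unname(lifetime_risk(p0, "NH-White")), 0)

  po <- PARAMS
  po$subgroups$lifetime_risk_override[4] <- 0.0095
  expect_equal(unname(lifetime_risk(po, "Hispanic")), 0.0095)

  expect_error(lifetime_risk(PARAMS, "Martian"), "unknown subgroup")
})

test_that("patient shares are share-times-risk weights and reproduce the published proportions", {
  w <- patient_shares(PARAMS)
  expect_equal(sum(w), 1)
  # invariance to a common rescaling of lifetime risks
  p2 <- PARAMS
  p2$subgroups$incidence_rate <- p2$subgroups$incidence_rate * 7
  expect_equal(patient_shares(p2), w)
  # equal risks: weights collapse to the general shares
  p3 <- PARAMS
  p3$subgroups$incidence_rate <- rep(20, 4)
  p3$subgroups$life_expectancy <- rep(80, 4)
  expect_equal(unname(patient_shares(p3)), p3$subgroups$general_share)
  # one subgroup only
  p4 <- p3
  p4$subgroups$general_share <- c(1, 0, 0, 0)
  expect_equal(unname(patient_shares(p4)), c(1, 0, 0, 0))
  # with the published rounded Hispanic lifetime risk (0.95%), the weights
  # match the published patient-population proportions
  p5 <- PARAMS
  p5$subgroups$lifetime_risk_override[4] <- 0.0095
  expect_equal(unname(patient_shares(p5)), c(0.6677, 0.1624, 0.0583, 0.1115),
               tolerance = 0.001)
})

test_that("validation rejects broken inputs, naming the rule", {
  bad <- PARAMS
  bad$pdl1$distribution["NH-White", ] <- c(0.5, 0.3, 0.1)  # sums to 0.9
  expect_error(validate_parameters(bad), "pdl1")

  bad2 <- PARAMS
  bad2$subgroups$general_share[1] <- 0.7
  expect_error(validate_parameters(bad2), "general_share")

  bad3 <- PARAMS
  bad3$mismatch_hr$ci_low[1] <- 99
  expect_error(validate_parameters(bad3), "bracket")

  bad4 <- PARAMS
  bad4$utilities$mean <- c(0.5, 0.6)  # post above pre
  expect_error(validate_parameters(bad4), "utility")

  bad5 <- PARAMS
  bad5$settings$atkinson_aversion <- 1
  expect_error(validate_parameters(bad5), "atkinson_aversion")

  expect_error(read_dcea_config("/nonexistent/config.yaml"), "not found")
})

test_that("configuration round-trips identically through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_dcea_config(PARAMS, path)
  expect_equal(read_dcea_config(path), PARAMS, tolerance = 1e-12)
  # packaged fixture matches the in-code defaults
  pkg <- system.file("extdata", "model_parameters.yaml", package = "lbdcea")
  expect_equal(read_dcea_config(pkg), PARAMS, tolerance = 1e-12)
  # missing section is a configuration error naming the key
  raw <- yaml::read_yaml(path)
  raw$utilities <- NULL
  path2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path2)
  expect_error(read_dcea_config(path2), "utilities")
})
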