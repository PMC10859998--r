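test_that("Weibull curves start at one and match the exponential closed form", {
  crv <- weibull_curve(-1.1604, 0.1046)
  expect_equal(survival_at(crv, 0), 1)
  # shape 0 means exponential with rate exp(log_scale)
  expo <- weibull_curve(log(0.5), 0)
  tt <- c(0.3, 1, 2.7)
  expect_equal(survival_at(expo, tt), exp(-0.5 * tt))
  # a hazard ratio of 2 halves the exponential median
  expo2 <- weibull_curve(log(0.5), 0, hr = 2)
  med <- function(crv) uniroot(function(t) survival_at(crv, t) - 0.5, c(0.01, 50),
                               tol = 1e-10)$root
  expect_equal(med(expo2), med(expo) / 2, tolerance = 1e-6)
  expect_error(survival_at(expo, -1), "non-negative")
})

test_that("discounted QALYs match the closed form for exponential curves", {
  lam <- 0.5; r <- 0.03; H <- 20; u <- 0.7
  crv <- weibull_curve(log(lam), 0)
  ho <- branch_health_outcome(crv, crv, c(u, u), r, H, 1 / 52)
  closed <- u / (lam + r) * (1 - exp(-(lam + r) * H))
  expect_equal(ho$qalys, closed, tolerance = 1e-4)
  # zero utilities give zero QALYs
  ho0 <- branch_health_outcome(crv, crv, c(0, 0), r, H, 1 / 52)
  expect_equal(ho0$qalys, 0)
  # identical PFS and OS leave no post-progression time
  expect_equal(ho$t_post_disc, 0)
})

test_that("halving the integration step changes QALYs negligibly for every published curve", {
  ctxs <- unique(PARAMS$survival$context)
  for (cx in ctxs) {
    pfs <- weibull_curve(POINT$weibull$pfs_log_scale[[cx]], POINT$weibull$pfs_shape[[cx]])
    os <- weibull_curve(POINT$weibull$os_log_scale[[cx]], POINT$weibull$os_shape[[cx]])
    q1 <- branch_health_outcome(pfs, os, c(0.71, 0.67), 0.03, 20, 1 / 52)$qalys
    q2 <- branch_health_outcome(pfs, os, c(0.71, 0.67), 0.03, 20, 1 / 104)$qalys
    expect_lt(abs(q1 - q2), 1e-4)
  }
})

test_that("state occupancy is clamped so post-progression time is never negative", {
  # an OS curve dropping faster than PFS forces a crossing
  pfs <- weibull_curve(log(0.2), 0)
  os <- weibull_curve(log(1.5), 0)
  ho <- branch_health_outcome(pfs, os, c(0.71, 0.67), 0.03, 20, 1 / 52)
  expect_gte(ho$t_post_disc, 0)
  expect_lte(ho$t_pre_disc, ho$t_pre_undisc)
  expect_lte(ho$t_pre_undisc + ho$t_post_undisc, ho$mean_os_undisc + 1e-9)
})

test_that("QALYs fall with every hazard multiplier and rise as the TAT HR falls", {
  base <- expected_strategy_outcome(
    enumerate_branches("LB-first", POINT, "NH-White"), POINT, PARAMS$settings)
  worse <- POINT
  worse$mismatch_hr[] <- worse$mismatch_hr * 1.5
  worse$calibration_hr[] <- worse$calibration_hr * 1.2
  q_worse <- expected_strategy_outcome(
    enumerate_branches("LB-first", worse, "NH-White"), worse, PARAMS$settings)
  expect_lt(q_worse$qalys, base$qalys)
  faster <- POINT
  faster$tat_hr["3-week"] <- 0.6
  q_fast <- expected_strategy_outcome(
    enumerate_branches("LB-first", faster, "NH-White"), faster, PARAMS$settings)
  expect_gt(q_fast$qalys, base$qalys)
  # bounds: discounted <= undiscounted <= u_pre * horizon
  expect_lte(base$qalys,
             POINT$u_pre * base$t_pre_undisc + POINT$u_post * base$t_post_undisc)
  expect_lte(base$t_pre_undisc + base$t_post_undisc, PARAMS$settings$horizon_years)
})

test_that("expected strategy outcome is the probability-weighted branch sum", {
  br <- enumerate_branches("TB-only", POINT, "Asian")
  one <- br[5, , drop = FALSE]
  one$prob <- 1
  o1 <- expected_strategy_outcome(one, POINT, PARAMS$settings)
  pfs <- weibull_curve(POINT$weibull$pfs_log_scale[[one$context]],
                       POINT$weibull$pfs_shape[[one$context]], hr = one$hr_multiplier)
  os <- weibull_curve(POINT$weibull$os_log_scale[[one$context]],
                      POINT$weibull$os_shape[[one$context]], hr = one$hr_multiplier)
  o2 <- branch_health_outcome(pfs, os, c(POINT$u_pre, POINT$u_post),
                              PARAMS$settings$discount_rate,
                              PARAMS$settings$horizon_years,
                              PARAMS$settings$time_step_years)
  expect_equal(o1$qalys, o2$qalys, tolerance = 1e-10)
  # folding back the full tree equals the sum over branch outcomes
  full <- expected_strategy_outcome(br, POINT, PARAMS$settings)
  parts <- vapply(seq_len(nrow(br)), function(i) {
    b <- br[i, , drop = FALSE]; b$prob <- 1
    expected_strategy_outcome(b, POINT, PARAMS$settings)$qalys
  }, numeric(1))
  expect_equal(full$qalys, sum(br$prob * parts), tolerance = 1e-9)
})

test_that("LB-first weakly dominates TB-only in QALYs at point estimates", {
  for (g in PARAMS$subgroups$id) {
    q_lb <- expected_strategy_outcome(
      enumerate_branches("LB-first", POINT, g), POINT, PARAMS$settings)$qalys
    q_tb <- expected_strategy_outcome(
      enumerate_branches("TB-only", POINT, g), POINT, PARAMS$settings)$qalys
    expect_gte(q_lb, q_tb)
  }
})
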