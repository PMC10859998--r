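# The baseline general-population QALE distribution across race/ethnicity
QALE <- c(68.798, 65.446, 74.878, 71.762)
W <- c(0.6057, 0.1389, 0.0623, 0.1931)

test_that("Atkinson index reproduces the published baseline QALE values", {
  expect_lt(abs(atkinson_index(QALE, 11, weights = W) - 0.0058032), 1e-5)
  expect_lt(abs(atkinson_index(QALE, 5, weights = W) - 0.0027011), 1e-5)
  expect_lt(abs(atkinson_index(QALE, 0.9, weights = W) - 0.0004948), 1e-5)
  expect_lt(abs(atkinson_index(QALE, 15, weights = W) - 0.0077995), 1e-5)
  expect_equal(atkinson_index(rep(4, 4), 11, weights = W), 0)
  expect_error(atkinson_index(QALE, 1, weights = W), "eps = 1")
  expect_error(atkinson_index(c(-1, 2), 5, weights = c(0.5, 0.5)), "positive")
})

test_that("Kolm index reproduces the published baseline QALE values", {
  expect_lt(abs(kolm_index(QALE, 0.15, weights = W) - 0.3791431), 1e-3)
  expect_lt(abs(kolm_index(QALE, 0.025, weights = W) - 0.065946), 1e-4)
  expect_lt(abs(kolm_index(QALE, 0.3, weights = W) - 0.7259447), 1e-3)
  expect_equal(kolm_index(rep(7, 4), 0.15, weights = W), 0)
  expect_error(kolm_index(QALE, 0, weights = W), "positive")
})

test_that("Atkinson is scale-invariant and Kolm translation-invariant", {
  set.seed(17)
  for (i in 1:25) {
    y <- runif(4, 1, 100)
    w <- lbdcea:::rdirichlet1(rep(2, 4))
    eps <- runif(1, 0.1, 14); eps <- if (abs(eps - 1) < 0.05) 2 else eps
    alpha <- runif(1, 0.01, 0.3)
    expect_equal(atkinson_index(3.7 * y, eps, weights = w),
                 atkinson_index(y, eps, weights = w), tolerance = 1e-10)
    expect_equal(kolm_index(y + 13.1, alpha, weights = w),
                 kolm_index(y, alpha, weights = w), tolerance = 1e-9)
    # indices are non-negative and vanish only for degenerate distributions
    expect_gte(atkinson_index(y, eps, weights = w), 0)
    expect_gte(kolm_index(y, alpha, weights = w), 0)
    if (diff(range(y)) > 1e-6 && all(w > 0)) {
      expect_gt(atkinson_index(y, eps, weights = w), 0)
      expect_gt(kolm_index(y, alpha, weights = w), 0)
    }
  }
})

test_that("both indices are non-decreasing in aversion on the baseline QALE grids", {
  atk <- vapply(c(0, 0.9, 5, 11, 15), function(e) atkinson_index(QALE, e, weights = W),
                numeric(1))
  expect_true(all(diff(atk) > 0))
  kol <- vapply(c(0.025, 0.1, 0.15, 0.3), function(a) kolm_index(QALE, a, weights = W),
                numeric(1))
  expect_true(all(diff(kol) > 0))
})

test_that("EDE is mean times (1 - A) or mean minus K, and never exceeds the mean", {
  mu <- sum(W * QALE)
  expect_equal(ede(QALE, 11, "atkinson", weights = W),
               mu * (1 - atkinson_index(QALE, 11, weights = W)))
  expect_equal(ede(QALE, 0.15, "kolm", weights = W),
               mu - kolm_index(QALE, 0.15, weights = W))
  expect_lt(abs(ede(QALE, 11, "atkinson", weights = W) - 68.8814), 1e-3)
  expect_equal(ede(rep(5, 4), 11, "atkinson", weights = W), 5)
  set.seed(3)
  for (i in 1:10) {
    y <- runif(4, 10, 90)
    expect_lte(ede(y, 7, "atkinson", weights = W), sum(W * y) + 1e-12)
    expect_lte(ede(y, 0.2, "kolm", weights = W), sum(W * y) + 1e-12)
  }
})

test_that("per-capita iNHB distributes opportunity costs equally and aggregates consistently", {
  dq <- c(0.20, 0.21, 0.31, 0.17)
  dc <- c(3326, 3195, 2536, 3431)
  r <- per_capita_inhb(dq, dc, PARAMS, threshold = 150000)
  # the opportunity-cost term is common to all subgroups
  risk <- lifetime_risk(PARAMS) * 0.30
  expect_equal(unname(r$by_subgroup + r$opportunity_cost_per_capita),
               unname(risk * dq))
  # published per-subgroup magnitudes
  expect_equal(unname(r$per_100k), c(99, 112, 131, 37), tolerance = 3)
  expect_equal(r$overall_per_100k, 91, tolerance = 3)
  # aggregation consistency: weighted subgroup iNHB equals pooled iNHB
  gs <- PARAMS$subgroups$general_share
  pooled <- sum(gs * risk * dq) - sum(gs * risk * dc) / 150000
  expect_equal(r$overall, pooled)
  # zero increments give zero everywhere
  z <- per_capita_inhb(rep(0, 4), rep(0, 4), PARAMS)
  expect_equal(unname(z$per_100k), rep(0, 4))
  # a higher threshold strictly increases every subgroup iNHB when costs > 0
  r2 <- per_capita_inhb(dq, dc, PARAMS, threshold = 300000)
  expect_true(all(r2$by_subgroup > r$by_subgroup))
  expect_error(per_capita_inhb(dq, dc, PARAMS, threshold = -1), "positive")
})

test_that("QALE shifting adds per-person benefit and preserves the weighted mean shift", {
  base <- health_distribution(setNames(QALE, PARAMS$subgroups$id), W, "general")
  inhb <- setNames(c(99, 112, 131, 37) / 1e5, PARAMS$subgroups$id)
  post <- qale_shift(base, inhb)
  expect_equal(post$values[1], 68.798 + 99e-5)
  expect_equal(sum(post$weights * post$values) - sum(base$weights * base$values),
               sum(W * inhb))
  expect_equal(qale_shift(base, rep(0, 4))$values, base$values)
  expect_error(qale_shift(base, inhb[1:3]), "misaligned")
})

test_that("inequality impact reports the signed difference and relative change", {
  ii <- inequality_impact(0.01109, 0.01291)
  expect_equal(ii$absolute, 0.00182)
  expect_equal(ii$relative_pct, 100 * 0.00182 / 0.01109)
  expect_equal(inequality_impact(0.5, 0.5)$absolute, 0)
  zz <- inequality_impact(0, 0.1)
  expect_true(zz$undefined_relative)
  expect_true(is.na(zz$relative_pct))
})
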