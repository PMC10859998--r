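# Shared fixtures: the packaged parameter set and its point-estimate draw are
# built once per test run.
PARAMS <- dcea_parameters()
POINT <- point_estimate_draw(PARAMS)

# A draw with perfect tests (every marker and PD-L1 classified correctly).
perfect_test_draw <- function(draw = POINT) {
  draw$lb_se[] <- 1
  draw$lb_sp[] <- 1
  draw$tb_se <- 1
  draw$tb_sp <- 1
  draw
}

expect_prob_vector <- function(p, tol = 1e-9) {
  expect_true(all(p >= -tol & p <= 1 + tol))
  expect_equal(sum(p), 1, tolerance = tol)
}
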