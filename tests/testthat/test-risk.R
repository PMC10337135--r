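rr <- default_rr_spec()
grid <- bmi_grid()

test_that("log-linear curves evaluate the printed bands around the TMREL", {
  # RR(TMREL) = 1 for every log-linear disease
  for (d in c("chd", "stroke", "colorectal_cancer", "pancreatic_cancer")) {
    expect_equal(rr_at_bmi(rr, d, "male", 45, 22), 1, label = d)
  }
  # one 5-unit step above TMREL returns the band value itself
  expect_equal(rr_at_bmi(rr, "chd", "male", 45, 27), 1.50)
  expect_equal(rr_at_bmi(rr, "stroke", "female", 65, 27), 1.49)
  # below TMREL the curve is floored at 1
  expect_equal(rr_at_bmi(rr, "chd", "male", 45, 18), 1)
  # ages below the youngest printed band reuse it; above the oldest likewise
  expect_equal(
    rr_at_bmi(rr, "chd", "male", 25, 30),
    rr_at_bmi(rr, "chd", "male", 45, 30)
  )
  expect_equal(rr_at_bmi(rr, "stroke", "male", 95, 27), 1.10)
})

test_that("categorical and restricted curves follow the printed bands", {
  expect_equal(rr_at_bmi(rr, "hhd", "female", 50, 30), 2.03)
  expect_equal(rr_at_bmi(rr, "hhd", "female", 50, 20), 1.17)
  expect_equal(rr_at_bmi(rr, "t2dm", "male", 40, 27), 2.16)
  expect_equal(rr_at_bmi(rr, "cirrhosis", "male", 40, 22), 0.73)
  # applicability windows: RR = 1 outside
  expect_equal(rr_at_bmi(rr, "liver_cancer", "male", 30, 32), 1)
  expect_gt(rr_at_bmi(rr, "liver_cancer", "male", 50, 32), 1)
  expect_equal(rr_at_bmi(rr, "breast_cancer", "male", 70, 32), 1)
  expect_equal(rr_at_bmi(rr, "breast_cancer", "female", 50, 32), 1)
  expect_equal(rr_at_bmi(rr, "breast_cancer", "female", 65, 27), 1.12)
  # sex-specific cancers
  expect_equal(rr_at_bmi(rr, "colorectal_cancer", "male", 50, 27), 1.24)
  expect_equal(rr_at_bmi(rr, "colorectal_cancer", "female", 50, 27), 1.09)
  expect_error(rr_at_bmi(rr[0, ], "chd", "male", 45, 27), "no bands")
})

test_that("potential impact fractions match hand-computed cases", {
  curve <- rr_curve(rr, "chd", "male", 45)
  # identical distributions: PIF exactly zero
  d <- list(mean = 28, sd = 4)
  expect_identical(pif(d, d, curve, grid), 0)
  expect_identical(incidence_multiplier(d, d, curve, grid), 1)

  # two-point reference: 25% at RR 1, 75% at RR 2; counterfactual all at RR 1
  rr_step <- ifelse(grid >= 25, 2, 1)
  w_ref <- ifelse(grid >= 25, 0.75 / sum(grid >= 25), 0.25 / sum(grid < 25))
  w_cf <- ifelse(grid < 25, 1 / sum(grid < 25), 0)
  expect_equal(pif(w_ref, w_cf, rr_step, grid), 0.42857, tolerance = 1e-5)
  expect_equal(incidence_multiplier(w_ref, w_cf, rr_step, grid), 0.57143,
    tolerance = 1e-5
  )

  # point mass at 27 under a 1.5-per-5 curve vs TMREL: (1.5 - 1)/1.5
  expect_equal(
    pif(list(mean = 27, sd = 0), list(mean = 22, sd = 0), curve, grid),
    1 / 3,
    tolerance = 1e-6
  )

  # a counterfactual with strictly higher BMI raises incidence
  expect_gt(
    incidence_multiplier(list(mean = 27, sd = 3), list(mean = 29, sd = 3), curve, grid),
    1
  )
})

test_that("pif and incidence multiplier are exact complements", {
  curve <- rr_curve(rr, "t2dm", "female", 50)
  set.seed(42)
  for (rep in 1:20) {
    ref <- list(mean = runif(1, 24, 32), sd = runif(1, 2, 6))
    cf <- list(mean = runif(1, 22, 30), sd = runif(1, 2, 6))
    expect_equal(
      pif(ref, cf, curve, grid) + incidence_multiplier(ref, cf, curve, grid),
      1,
      tolerance = 1e-15
    )
  }
})

test_that("the PIF integral is grid-converged for realistic spreads", {
  curve <- rr_curve(rr, "chd", "male", 45)
  ref <- list(mean = 28, sd = 4)
  cf <- list(mean = 27.5, sd = 4)
  g1 <- bmi_grid(step = 0.1)
  g2 <- bmi_grid(step = 0.05)
  g10 <- bmi_grid(step = 0.01)
  p1 <- pif(ref, cf, curve, g1)
  p2 <- pif(ref, cf, curve, g2)
  p10 <- pif(ref, cf, curve, g10)
  expect_lt(abs(p1 - p2), 1e-4)
  expect_lt(abs(p1 - p10), 1e-4)

  # narrow spread still converges at the default step
  p1n <- pif(list(mean = 28, sd = 1), cf, curve, g1)
  p10n <- pif(list(mean = 28, sd = 1), cf, curve, g10)
  expect_lt(abs(p1n - p10n), 1e-4)
})

test_that("lower counterfactual means strictly increase the PIF", {
  curve <- rr_curve(rr, "stroke", "male", 50)
  ref <- list(mean = 29, sd = 4)
  pifs <- vapply(
    seq(28, 23, by = -1),
    function(mu) pif(ref, list(mean = mu, sd = 4), curve, grid),
    numeric(1)
  )
  expect_true(all(diff(pifs) > 0))
})

test_that("swapping reference and counterfactual obeys the PIF identity", {
  curve <- rr_curve(rr, "ckd", "female", 60)
  ref <- list(mean = 29, sd = 4)
  cf <- list(mean = 26, sd = 3.5)
  p <- pif(ref, cf, curve, grid)
  p_rev <- pif(cf, ref, curve, grid)
  expect_equal(p_rev, -p / (1 - p), tolerance = 1e-12)
})
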