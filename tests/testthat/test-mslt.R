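test_that("lag application shifts multiplier series and neutralizes the head", {
  m <- c(1.01, 1.02, 1.03, 1.04)
  expect_identical(apply_lag(m, 0), m)
  expect_equal(apply_lag(m, 2), c(1, 1, 1.01, 1.02))
  expect_equal(apply_lag(m, 12), rep(1, 4))
  mm <- rbind(m, m + 0.1)
  lagged <- apply_lag(mm, 1)
  expect_equal(lagged[, 1], c(1, 1), ignore_attr = TRUE)
  expect_equal(lagged[, 2:4], mm[, 1:3], ignore_attr = TRUE)
  expect_error(apply_lag(m, -1), "non-negative")
})

test_that("disease life table matches the independent bookkeeping oracle", {
  cases <- list(
    list(i = 0.01, r = 0, f = 0.02, m = 0.01, mult = 1, C0 = 0),
    list(i = 0.03, r = 0.1, f = 0.15, m = 0.005, mult = 1, C0 = 50),
    list(
      i = 0.02, r = 0, f = 0.05, m = 0.02,
      mult = c(1, 1, 1, 1, 1, 1.2, 1.25, 1.3, 1.3, 1.35, 1.4), C0 = 20
    )
  )
  for (cs in cases) {
    lt <- run_disease_lifetable(
      incidence = cs$i, remission = cs$r, case_fatality = cs$f,
      other_mortality = cs$m, multipliers = cs$mult,
      init_healthy = 1000 - cs$C0, init_diseased = cs$C0, n_cycles = 11
    )
    orc <- oracle_lifetable(cs$i, cs$r, cs$f, cs$m, cs$mult, 1000 - cs$C0, cs$C0, 11)
    expect_equal(as.vector(lt$new_cases), orc$cases, tolerance = 1e-9)
    expect_equal(as.vector(lt$disease_deaths), orc$deaths, tolerance = 1e-9)
    expect_equal(as.vector(lt$states[1, , "healthy"]), orc$S, tolerance = 1e-9)
    expect_equal(as.vector(lt$states[1, , "diseased"]), orc$C, tolerance = 1e-9)
    # conservation at every year boundary
    totals <- apply(lt$states[1, , ], 1, sum)
    expect_equal(totals, rep(1000, 12), tolerance = 1e-9)
  }
})

test_that("cumulative incidence matches the closed form when f = r = 0", {
  i <- 0.015
  lt <- run_disease_lifetable(
    incidence = i, remission = 0, case_fatality = 0, other_mortality = 0,
    multipliers = 1, init_healthy = 1000, init_diseased = 0, n_cycles = 11
  )
  expect_equal(
    sum(lt$new_cases), 1000 * (1 - exp(-i * 11)),
    tolerance = 1e-6
  )
})

test_that("zero incidence produces no cases, deaths, or prevalent pool", {
  lt <- run_disease_lifetable(
    incidence = 0, remission = 0, case_fatality = 0.1, other_mortality = 0.01,
    multipliers = 1, init_healthy = 500, init_diseased = 0, n_cycles = 11
  )
  expect_true(all(lt$new_cases == 0))
  expect_true(all(lt$disease_deaths == 0))
  expect_true(all(lt$states[, , "diseased"] == 0))
})

test_that("cohort mass is conserved in every stratum-year of a full run", {
  run <- bau_run()
  totals <- run$states$healthy + run$states$diseased +
    run$states$dead_disease + run$states$dead_other
  init <- dplyr::inner_join(
    run$states[, c("disease_id", "sex", "cohort_age")],
    dplyr::rename(default_inputs()$population,
      cohort_age = "age", init = "count"
    )[, c("sex", "cohort_age", "init")],
    by = c("sex", "cohort_age")
  )
  expect_equal(totals, init$init, tolerance = 1e-9)
})

test_that("a frozen-baseline trajectory is neutral", {
  inputs <- tiny_inputs()
  frozen <- mean_growth_trajectory(
    inputs$bmi_baseline, 0, seq(inputs$config$start_year, inputs$config$end_year),
    scenario_id = "S2"
  )
  lagged <- run_mslt(inputs, frozen, lag = TRUE)
  unlagged <- run_mslt(inputs, frozen, lag = FALSE)
  expect_equal(lagged$burden$value, unlagged$burden$value, tolerance = 1e-12)
  # and matches the prevalence-hold construction of Scenario 2
  held <- build_canonical_scenarios(inputs$config, inputs$bmi_baseline)$S2
  held_run <- run_mslt(inputs, held)
  expect_equal(held_run$burden$value, lagged$burden$value, tolerance = 1e-9)
})

test_that("scenario contrasts respect the five and ten year lags", {
  burden <- default_burden()
  wide <- tidyr::pivot_wider(
    burden[burden$outcome == "cases", ],
    names_from = "scenario_id", values_from = "value"
  )
  diff_bau <- wide$BAU - wide$S3
  # no disease diverges from BAU before the shortest lag completes
  expect_true(all(abs(diff_bau[wide$year <= 2024]) < 1e-9))
  # non-cancers first diverge in the 2024->2025 cycle
  t2dm25 <- wide[wide$disease_id == "t2dm" & wide$year == 2025, ]
  expect_gt(t2dm25$BAU - t2dm25$S3, 0)
  # cancers stay on BAU through 2029 and diverge only in the final cycle
  canc <- wide[wide$disease_id %in% cancer_ids(), ]
  expect_true(all(abs(canc$BAU[canc$year <= 2029] - canc$S3[canc$year <= 2029]) < 1e-9))
  canc30 <- canc[canc$year == 2030, ]
  expect_true(all(canc30$BAU - canc30$S3 > 0))
})

test_that("attributable burden is non-negative and monotone in BMI dominance", {
  burden <- default_burden()
  expect_true(all(burden$value >= -1e-9))
  wide <- tidyr::pivot_wider(
    burden,
    names_from = "scenario_id", values_from = "value"
  )
  expect_true(all(wide$BAU - wide$S1 >= -1e-9))
  expect_true(all(wide$S1 - wide$S2 >= -1e-9))
  expect_true(all(wide$S2 - wide$S3 >= -1e-9))
})

test_that("averted burden is exactly zero when the scenario equals BAU", {
  inputs <- tiny_inputs()
  ctx_burden <- attributable_burden(inputs, build_canonical_scenarios(
    inputs$config, inputs$bmi_baseline
  )$BAU)
  twin <- attributable_burden(inputs, build_canonical_scenarios(
    inputs$config, inputs$bmi_baseline
  )$BAU)
  expect_identical(ctx_burden$value, twin$value)
  expect_true(all(ctx_burden$value - twin$value == 0))
})

test_that("a population already at the TMREL carries no attributable burden", {
  inputs <- tiny_inputs()
  at_tmrel <- mslt_inputs(
    population = inputs$population,
    bmi_baseline = dplyr::mutate(inputs$bmi_baseline, mean_bmi = 22, sd_bmi = 0),
    disease_epi = inputs$disease_epi,
    rr_spec = inputs$rr_spec,
    config = inputs$config
  )
  burden <- attributable_burden(
    at_tmrel, tmrel_trajectory(at_tmrel$config, at_tmrel$bmi_baseline)
  )
  expect_true(all(abs(burden$value) < 1e-9))
})

test_that("the central life table shrinks monotonically and tracks mortality", {
  run <- bau_run()
  lt <- run$life_table
  for (s in c("male", "female")) {
    alive <- tidyr::pivot_wider(
      lt[lt$sex == s, c("cohort_age", "year", "alive")],
      names_from = "year", values_from = "alive"
    )
    mat <- as.matrix(alive[, -1])
    expect_true(all(diff(t(mat)) <= 0)) # no resurrection
    expect_true(all(mat >= 0))
  }
})
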