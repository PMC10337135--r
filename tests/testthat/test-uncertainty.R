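test_that("lognormal RR draws recover the printed CI scale", {
  rr <- default_rr_spec()
  chd <- rr[rr$disease_id == "chd" & rr$age_lo == 35, ]
  log_sd <- (log(chd$rr_high) - log(chd$rr_low)) / (2 * 1.96)
  expect_equal(log_sd, 0.0391, tolerance = 0.0001 / 0.0391)

  # degenerate CI: the draw is always the point estimate
  degen <- chd
  degen$rr_low <- degen$rr_high <- degen$rr
  drawn <- sample_rr(degen, z = c(chd = 3))
  expect_equal(drawn$rr, degen$rr)

  # the draw median sits at the point estimate
  set.seed(99)
  draws <- replicate(10000, sample_rr(chd)$rr)
  expect_gt(median(draws), 1.48)
  expect_lt(median(draws), 1.52)

  # bands of one disease share a draw: ratios to the point are log-proportional
  chd_all <- rr[rr$disease_id == "chd", ]
  one <- sample_rr(chd_all, z = c(chd = 1.3))
  expect_equal(
    log(one$rr / chd_all$rr),
    1.3 * (log(chd_all$rr_high) - log(chd_all$rr_low)) / (2 * 1.96),
    tolerance = 1e-12
  )
  bad <- chd
  bad$rr_low <- 0
  expect_error(sample_rr(bad), "positive")
})

test_that("Monte Carlo runs are reproducible and degenerate cases collapse", {
  inputs <- tiny_inputs()
  spec <- draw_spec(n_draws = 4, seed = 11)
  a <- run_monte_carlo(inputs, spec)
  b <- run_monte_carlo(inputs, spec)
  expect_identical(a$burden, b$burden)
  expect_identical(a$averted, b$averted)

  # a single draw gives a zero-width interval at that draw's value
  one <- run_monte_carlo(inputs, draw_spec(n_draws = 1, seed = 5), keep_draws = TRUE)
  expect_equal(one$burden$ci_low, one$burden$ci_high)
  expect_equal(one$burden$ci_low, as.vector(one$draws[1, ]))

  # all parameter distributions degenerate: the interval collapses onto the
  # point run
  frozen <- run_monte_carlo(
    inputs,
    draw_spec(n_draws = 3, seed = 5, sample_rr = FALSE, sample_bmi = FALSE)
  )
  expect_equal(frozen$burden$ci_low, frozen$burden$value, tolerance = 1e-12)
  expect_equal(frozen$burden$ci_high, frozen$burden$value, tolerance = 1e-12)
})

test_that("halving the RR confidence intervals narrows the uncertainty", {
  inputs <- tiny_inputs()
  narrow_rr <- inputs$rr_spec
  narrow_rr$rr_low <- exp(log(narrow_rr$rr) + (log(narrow_rr$rr_low) - log(narrow_rr$rr)) / 2)
  narrow_rr$rr_high <- exp(log(narrow_rr$rr) + (log(narrow_rr$rr_high) - log(narrow_rr$rr)) / 2)
  narrow_inputs <- mslt_inputs(
    inputs$population, inputs$bmi_baseline, inputs$disease_epi, narrow_rr,
    inputs$config
  )
  spec <- draw_spec(n_draws = 30, seed = 7, sample_bmi = FALSE)
  wide <- run_monte_carlo(inputs, spec, keep_draws = TRUE)
  tight <- run_monte_carlo(narrow_inputs, spec, keep_draws = TRUE)

  total_width <- function(mc) {
    sel <- mc$burden$outcome == "cases" & mc$burden$scenario_id == "BAU"
    tot <- rowSums(mc$draws[, sel, drop = FALSE])
    diff(quantile(tot, c(0.025, 0.975)))
  }
  expect_lt(total_width(tight), total_width(wide))
})

test_that("intervals from a single sampled RR cover the point estimate", {
  rr <- default_rr_spec()
  chd <- rr[rr$disease_id == "chd" & rr$age_lo == 35, ]
  covered <- vapply(1:50, function(s) {
    set.seed(s)
    draws <- replicate(100, sample_rr(chd)$rr)
    ui <- quantile(draws, c(0.025, 0.975))
    ui[1] <= chd$rr && chd$rr <= ui[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("averted intervals come from paired per-draw differences", {
  inputs <- tiny_inputs()
  mc <- run_monte_carlo(inputs, draw_spec(n_draws = 8, seed = 3), keep_draws = TRUE)
  cell <- which(
    mc$burden$outcome == "cases" & mc$burden$disease_id == "t2dm" &
      mc$burden$scenario_id == "S3" & mc$burden$year == 2030
  )
  bau_cell <- which(
    mc$burden$outcome == "cases" & mc$burden$disease_id == "t2dm" &
      mc$burden$scenario_id == "BAU" & mc$burden$year == 2030
  )
  paired <- mc$draws[, bau_cell] - mc$draws[, cell]
  av_row <- mc$averted[
    mc$averted$outcome == "cases" & mc$averted$disease_id == "t2dm" &
      mc$averted$scenario_id == "S3" & mc$averted$year == 2030,
  ]
  expect_equal(av_row$ci_low, unname(quantile(paired, 0.025)))
  expect_equal(av_row$ci_high, unname(quantile(paired, 0.975)))
})
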