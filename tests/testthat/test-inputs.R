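test_that("disease registry encodes the lag and remission conventions", {
  reg <- disease_registry()
  expect_equal(nrow(reg), 11)
  expect_setequal(reg$lag_years[reg$is_cancer], 10L)
  expect_setequal(reg$lag_years[!reg$is_cancer], 5L)
  expect_length(cancer_ids(), 5)
  expect_setequal(unlist(default_grouping()), disease_ids())
})

test_that("shipped relative-risk table round-trips the printed bands", {
  rr <- default_rr_spec()
  chd <- rr[rr$disease_id == "chd" & rr$age_lo == 35, ]
  expect_equal(chd$rr, 1.50)
  expect_equal(chd$rr_low, 1.39)
  expect_equal(chd$rr_high, 1.62)
  expect_true(all(rr$rr_low <= rr$rr & rr$rr <= rr$rr_high))
  expect_setequal(unique(rr$disease_id), disease_ids())
})

test_that("input bundles round-trip through write_inputs/load_inputs", {
  inputs <- tiny_inputs()
  dir <- withr::local_tempdir()
  cfg_path <- write_inputs(inputs, dir)
  back <- load_inputs(cfg_path)
  for (tab in c("population", "bmi_baseline", "disease_epi", "rr_spec")) {
    expect_equal(
      as.data.frame(back[[tab]]), as.data.frame(inputs[[tab]]),
      tolerance = 1e-12, label = tab
    )
  }
  expect_equal(unclass(back$config), unclass(inputs$config))
})

test_that("schema violations raise errors naming the file and field", {
  inputs <- tiny_inputs()
  dir <- withr::local_tempdir()
  cfg_path <- write_inputs(inputs, dir)

  epi_path <- file.path(dir, "disease_epi.csv")
  epi <- readr::read_csv(epi_path, show_col_types = FALSE)
  readr::write_csv(epi[, setdiff(names(epi), "remission")], epi_path)
  expect_error(load_inputs(cfg_path), "disease_epi.*remission")

  renamed <- epi
  renamed$disease_id[1] <- "gout"
  readr::write_csv(renamed, epi_path)
  expect_error(load_inputs(cfg_path), "unknown disease_id gout")

  readr::write_csv(epi[-2, ], epi_path)
  expect_error(load_inputs(cfg_path), "stratum gap")

  expect_error(load_inputs(file.path(dir, "nope.yaml")), "not found")
})

test_that("results fixture satisfies the printed column-sum identities", {
  ref <- load_reference_burden()
  # the two typo cells repaired by the column-sum identities
  expect_equal(
    ref$value[ref$outcome == "cases" & ref$disease_id == "cirrhosis" &
      ref$scenario_id == "BAU"],
    14630
  )
  expect_equal(
    ref$value[ref$outcome == "cases" & ref$disease_id == "stroke" &
      ref$scenario_id == "S2"],
    78493
  )
  # cancer cells sum to the printed subtotal in every scenario column
  cancers <- ref[ref$disease_id %in% cancer_ids(), ]
  printed <- ref[ref$disease_id == "total_cancer", ]
  sums <- dplyr::summarise(
    cancers,
    value = sum(value), .by = c("outcome", "scenario_id")
  )
  joined <- dplyr::inner_join(
    sums, printed,
    by = c("outcome", "scenario_id"), suffix = c("_sum", "_printed")
  )
  expect_equal(nrow(joined), 8)
  expect_equal(joined$value_sum, joined$value_printed)
})

test_that("epi consistency checks flag rule violations and pass the generator", {
  inputs <- tiny_inputs()
  expect_equal(nrow(validate_epi_consistency(inputs$disease_epi, inputs$population)), 0)

  bad <- inputs$disease_epi
  bad$remission[bad$disease_id == "cirrhosis"] <- 0.1
  f <- validate_epi_consistency(bad, inputs$population)
  expect_true("remission_non_cancer" %in% f$rule)
  expect_true(all(f$disease_id[f$rule == "remission_non_cancer"] == "cirrhosis"))

  flat <- inputs$disease_epi
  sel <- flat$disease_id == "t2dm"
  flat$incidence[sel] <- 0
  flat$prevalence[sel] <- 0.2
  f2 <- validate_epi_consistency(flat, inputs$population)
  # steady-state prevalence with zero incidence is 0, so 0.2 must be flagged
  expect_true(any(f2$rule == "steady_state" & f2$disease_id == "t2dm"))
})
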