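#' Assemble and validate a model input bundle
#'
#' Bundles the five inputs of the projection model — population, baseline
#' BMI distributions, disease epidemiology, relative-risk specification and
#' configuration — and validates their joint consistency: complete strata
#' (both sexes, all ages 20-80), all 11 registry diseases present in both
#' the epidemiology and the relative-risk specification, and the lag/
#' remission conventions (remission only for cancers).
#'
#' @param population Tibble `sex, age, count, all_cause_mortality_rate`.
#' @param bmi_baseline Tibble `sex, age, mean_bmi, sd_bmi`.
#' @param disease_epi Tibble `disease_id, sex, age, incidence, remission,
#'   case_fatality, prevalence`.
#' @param rr_spec Tibble in the [default_rr_spec()] schema.
#' @param config An [model_config()] object.
#' @return An object of class `mslt_inputs`.
#' @export
mslt_inputs <- function(population, bmi_baseline, disease_epi, rr_spec,
                        config = model_config()) {
  validate_population(population)
  validate_bmi_baseline(bmi_baseline, population)
  validate_disease_epi(disease_epi, population)
  validate_rr_spec(rr_spec)
  missing_rr <- setdiff(unique(disease_epi$disease_id), unique(rr_spec$disease_id))
  if (length(missing_rr) > 0) {
    stop(
      "input bundle: no relative-risk specification for ",
      paste(missing_rr, collapse = ", "), call. = FALSE
    )
  }
  structure(
    list(
      population = population,
      bmi_baseline = bmi_baseline,
      disease_epi = disease_epi,
      rr_spec = rr_spec,
      config = config
    ),
    class = "mslt_inputs"
  )
}

#' @export
print.mslt_inputs <- function(x, ...) {
  cat("<mslt_inputs>\n")
  cat(
    "  population:", nrow(x$population), "strata,",
    format(sum(x$population$count), big.mark = ","), "persons\n"
  )
  cat(
    "  diseases:", length(unique(x$disease_epi$disease_id)),
    " | ages", min(x$population$age), "-", max(x$population$age), "\n"
  )
  print(x$config)
  invisible(x)
}

required_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(
      "schema error in ", file, ": missing column ",
      paste(missing, collapse = ", "), call. = FALSE
    )
  }
  invisible(TRUE)
}

validate_population <- function(pop, file = "population") {
  required_columns(pop, c("sex", "age", "count", "all_cause_mortality_rate"), file)
  if (!setequal(unique(pop$sex), c("male", "female"))) {
    stop("schema error in ", file, ": sex must cover male and female",
      call. = FALSE
    )
  }
  for (s in c("male", "female")) {
    ages <- sort(pop$age[pop$sex == s])
    gap <- setdiff(seq(min(ages), max(ages)), ages)
    if (length(gap) > 0 || anyDuplicated(ages) > 0) {
      stop(
        "schema error in ", file, ": stratum gap or duplicate for sex ", s,
        " at age ", paste(head(gap, 3), collapse = ", "), call. = FALSE
      )
    }
  }
  bad <- pop$count < 0 | pop$all_cause_mortality_rate < 0
  if (any(bad)) {
    stop(
      "schema error in ", file, ": negative count or mortality rate at row ",
      which(bad)[1], call. = FALSE
    )
  }
  invisible(TRUE)
}

validate_bmi_baseline <- function(bmi, pop, file = "bmi_baseline") {
  required_columns(bmi, c("sex", "age", "mean_bmi", "sd_bmi"), file)
  if (any(bmi$sd_bmi < 0)) {
    stop("schema error in ", file, ": sd_bmi must be non-negative, row ",
      which(bmi$sd_bmi < 0)[1],
      call. = FALSE
    )
  }
  key_pop <- paste(pop$sex, pop$age)
  key_bmi <- paste(bmi$sex, bmi$age)
  miss <- setdiff(key_pop, key_bmi)
  if (length(miss) > 0) {
    stop(
      "schema error in ", file, ": stratum gap (missing ",
      paste(head(miss, 3), collapse = "; "), ")", call. = FALSE
    )
  }
  invisible(TRUE)
}

validate_disease_epi <- function(epi, pop, file = "disease_epi") {
  required_columns(
    epi,
    c("disease_id", "sex", "age", "incidence", "remission", "case_fatality",
      "prevalence"),
    file
  )
  assert_known_diseases(epi$disease_id, file)
  reg <- disease_registry()
  for (rate in c("incidence", "remission", "case_fatality")) {
    if (any(epi[[rate]] < 0)) {
      stop("schema error in ", file, ": negative ", rate, " at row ",
        which(epi[[rate]] < 0)[1],
        call. = FALSE
      )
    }
  }
  if (any(epi$prevalence < 0 | epi$prevalence > 1)) {
    stop("schema error in ", file, ": prevalence outside [0, 1] at row ",
      which(epi$prevalence < 0 | epi$prevalence > 1)[1],
      call. = FALSE
    )
  }
  key_pop <- paste(pop$sex, pop$age)
  for (d in unique(epi$disease_id)) {
    key_d <- paste(epi$sex[epi$disease_id == d], epi$age[epi$disease_id == d])
    miss <- setdiff(key_pop, key_d)
    if (length(miss) > 0) {
      stop(
        "schema error in ", file, ": stratum gap for disease ", d,
        " (missing ", paste(head(miss, 3), collapse = "; "), ")",
        call. = FALSE
      )
    }
  }
  invisible(TRUE)
}

validate_rr_spec <- function(rr, file = "rr_spec") {
  required_columns(
    rr,
    c("disease_id", "form", "sex", "age_lo", "age_hi", "bmi_lo", "bmi_hi",
      "rr", "rr_low", "rr_high"),
    file
  )
  assert_known_diseases(rr$disease_id, file)
  if (!all(rr$form %in% c("per5_loglinear", "categorical"))) {
    stop("schema error in ", file, ": unknown functional form", call. = FALSE)
  }
  bad <- !(rr$rr_low <= rr$rr & rr$rr <= rr$rr_high)
  if (any(bad)) {
    stop(
      "schema error in ", file, ": rr_low <= rr <= rr_high violated at row ",
      which(bad)[1], call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Published relative-risk specification for the 11 diseases
#'
#' The relative risks per 5 kg/m^2 of BMI (with 95% CIs) by sex and age
#' group, and the categorical BMI-band risks, as published for the
#' meta-analysis underlying the model (coronary heart disease and stroke
#' by age band; hypertensive heart disease, type 2 diabetes, chronic
#' kidney disease and cirrhosis by BMI band; sex-specific colorectal and
#' kidney cancer; liver cancer restricted to ages 35-79; breast cancer to
#' women above 60). `extend_age` marks diseases whose age bands are
#' extended to cover the full 20-80 simulation range (youngest/oldest
#' printed band reused); restricted-applicability diseases return RR = 1
#' outside their window.
#'
#' @return A tibble in the `rr_spec` schema: `disease_id, form, sex,
#'   age_lo, age_hi, bmi_lo, bmi_hi, rr, rr_low, rr_high, extend_age`.
#' @export
default_rr_spec <- function() {
  path <- system.file("extdata", "rr_spec.csv", package = "pmslt")
  if (path == "") stop("rr_spec.csv fixture not found", call. = FALSE)
  read_rr_spec(path)
}

#' Read a relative-risk specification CSV
#' @param path CSV file in the `rr_spec` schema (see [default_rr_spec()]).
#' @return Validated rr_spec tibble.
#' @export
read_rr_spec <- function(path) {
  rr <- readr::read_csv(
    path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      disease_id = "c", form = "c", sex = "c",
      age_lo = "d", age_hi = "d", bmi_lo = "d", bmi_hi = "d",
      rr = "d", rr_low = "d", rr_high = "d", extend_age = "l"
    )
  )
  validate_rr_spec(rr, basename(path))
  rr
}

#' Read a population CSV
#' @param path CSV with columns `sex, age, count, all_cause_mortality_rate`.
#' @return Validated population tibble.
#' @export
read_population <- function(path) {
  pop <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  validate_population(pop, basename(path))
  pop
}

#' Read a disease epidemiology CSV
#' @param path CSV with columns `disease_id, sex, age, incidence, remission,
#'   case_fatality, prevalence`.
#' @param population Population tibble defining the expected strata.
#' @return Validated disease epidemiology tibble.
#' @export
read_disease_epi <- function(path, population) {
  epi <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  validate_disease_epi(epi, population, basename(path))
  epi
}

#' Read a baseline BMI CSV
#' @param path CSV with columns `sex, age, mean_bmi, sd_bmi`.
#' @param population Population tibble defining the expected strata.
#' @return Validated BMI baseline tibble.
#' @export
read_bmi_baseline <- function(path, population) {
  bmi <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  validate_bmi_baseline(bmi, population, basename(path))
  bmi
}

#' Write a model input bundle to a directory
#'
#' Writes the four CSV tables and a `config.yaml` mirroring the model
#' configuration; [load_inputs()] on the written config restores a bundle
#' equal field-by-field.
#'
#' @param inputs An [mslt_inputs()] bundle.
#' @param dir Output directory (created if needed).
#' @return The path to the written `config.yaml`, invisibly.
#' @export
write_inputs <- function(inputs, dir) {
  stopifnot(inherits(inputs, "mslt_inputs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(inputs$population, file.path(dir, "population.csv"))
  readr::write_csv(inputs$disease_epi, file.path(dir, "disease_epi.csv"))
  readr::write_csv(inputs$rr_spec, file.path(dir, "rr_spec.csv"))
  readr::write_csv(inputs$bmi_baseline, file.path(dir, "bmi_baseline.csv"))
  cfg <- unclass(inputs$config)
  cfg$files <- list(
    population = "population.csv",
    disease_epi = "disease_epi.csv",
    rr_spec = "rr_spec.csv",
    bmi_baseline = "bmi_baseline.csv"
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Load a model input bundle from a config file
#'
#' Reads a `config.yaml` (as written by [write_inputs()]) naming the four
#' CSV tables, reads and validates each, and returns the assembled
#' bundle. Paths in the config are resolved relative to its directory.
#'
#' @param config_path Path to the YAML configuration.
#' @return An [mslt_inputs()] bundle.
#' @export
load_inputs <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("config file not found: ", config_path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(config_path)
  files <- cfg$files
  for (f in c("population", "disease_epi", "rr_spec", "bmi_baseline")) {
    if (is.null(files[[f]])) {
      stop("schema error in ", basename(config_path), ": missing file entry ",
        f,
        call. = FALSE
      )
    }
  }
  dir <- dirname(config_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  pop <- read_population(resolve(files$population))
  config <- model_config(
    start_year = cfg$start_year, end_year = cfg$end_year,
    tmrel_bmi = cfg$tmrel_bmi,
    bau_annual_bmi_increase = cfg$bau_annual_bmi_increase,
    scenario1_annual_bmi_increase = cfg$scenario1_annual_bmi_increase,
    scenario2_prevalence_target = cfg$scenario2_prevalence_target,
    scenario3_total_reduction = cfg$scenario3_total_reduction,
    scenario3_annual_step = cfg$scenario3_annual_step,
    n_draws = cfg$n_draws, seed = cfg$seed,
    bmi_grid_lo = cfg$bmi_grid_lo, bmi_grid_hi = cfg$bmi_grid_hi,
    bmi_grid_step = cfg$bmi_grid_step
  )
  mslt_inputs(
    population = pop,
    bmi_baseline = read_bmi_baseline(resolve(files$bmi_baseline), pop),
    disease_epi = read_disease_epi(resolve(files$disease_epi), pop),
    rr_spec = read_rr_spec(resolve(files$rr_spec)),
    config = config
  )
}

#' Published projection results fixture
#'
#' The published per-scenario attributable cases and deaths for the 11
#' diseases (plus the printed cancer subtotals) over the 2019-2030
#' horizon, as shipped in `inst/extdata/reference_burden.csv`. Two cells
#' whose printed values are typographically corrupt are repaired as forced
#' by the column-sum identities (documented in the file header); two
#' unparseable confidence-bound cells are stored as `NA`.
#'
#' @param include_subtotals Keep the printed `total_cancer` rows (default
#'   `TRUE`); set `FALSE` to return only the 11 diseases.
#' @return Burden tibble: `outcome` (cases/deaths), `disease_id`,
#'   `scenario_id` (BAU/S1/S2/S3), `value`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' ref <- load_reference_burden()
#' subset(ref, outcome == "deaths" & disease_id == "chd")
load_reference_burden <- function(include_subtotals = TRUE) {
  path <- system.file("extdata", "reference_burden.csv", package = "pmslt")
  if (path == "") stop("reference_burden.csv fixture not found", call. = FALSE)
  ref <- readr::read_csv(
    path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      outcome = "c", disease_id = "c", scenario_id = "c",
      value = "d", ci_low = "d", ci_high = "d"
    )
  )
  if (!include_subtotals) {
    ref <- ref[ref$disease_id %in% disease_ids(), , drop = FALSE]
  }
  ref
}

#' Check internal consistency of disease epidemiology
#'
#' A simplified internal-consistency screen over an epidemiology table
#' (the full rate-balancing optimization performed by dedicated tools is
#' out of scope). Flags, as findings rather than errors:
#' * rates that convert to annual probabilities outside `[0, 1]`
#'   (negative rates);
#' * non-zero remission for non-cancer diseases;
#' * prevalence grossly inconsistent with the illness-death steady state
#'   implied by incidence, remission and case fatality (ratio outside the
#'   tolerance band, with absolute slack for near-zero prevalences).
#'
#' @param epi Disease epidemiology tibble.
#' @param population Population tibble sharing the strata.
#' @param ratio_tol Tolerance band for prevalence vs steady state; a
#'   finding is raised when prevalence falls outside
#'   `[steady / ratio_tol, steady * ratio_tol]`. Default 1.5.
#' @param abs_tol Absolute slack below which prevalence discrepancies are
#'   ignored. Default 1e-4.
#' @return Tibble of findings (`disease_id`, `sex`, `age`, `rule`,
#'   `message`); zero rows when consistent.
#' @export
validate_epi_consistency <- function(epi, population, ratio_tol = 1.5,
                                     abs_tol = 1e-4) {
  validate_disease_epi(epi, population)
  reg <- disease_registry()
  findings <- list()
  note <- function(d, s, a, rule, msg) {
    tibble::tibble(disease_id = d, sex = s, age = a, rule = rule, message = msg)
  }
  for (rate in c("incidence", "remission", "case_fatality")) {
    bad <- which(epi[[rate]] < 0)
    for (k in bad) {
      findings[[length(findings) + 1]] <- note(
        epi$disease_id[k], epi$sex[k], epi$age[k], "negative_rate",
        paste0("negative ", rate, " converts to probability outside [0, 1]")
      )
    }
  }
  noncancer <- reg$disease_id[!reg$is_cancer]
  bad <- which(epi$disease_id %in% noncancer & epi$remission > 0)
  for (k in bad) {
    findings[[length(findings) + 1]] <- note(
      epi$disease_id[k], epi$sex[k], epi$age[k], "remission_non_cancer",
      "non-zero remission for non-cancer disease"
    )
  }
  steady <- steady_state_prevalence(epi$incidence, epi$remission, epi$case_fatality)
  dev <- abs(epi$prevalence - steady) > abs_tol
  off <- dev & (epi$prevalence > steady * ratio_tol |
    epi$prevalence < steady / ratio_tol)
  for (k in which(off)) {
    findings[[length(findings) + 1]] <- note(
      epi$disease_id[k], epi$sex[k], epi$age[k], "steady_state",
      sprintf(
        "prevalence %.4g inconsistent with steady state %.4g implied by i, r, f",
        epi$prevalence[k], steady[k]
      )
    )
  }
  if (length(findings) == 0) {
    return(tibble::tibble(
      disease_id = character(), sex = character(), age = numeric(),
      rule = character(), message = character()
    ))
  }
  dplyr::bind_rows(findings)
}
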