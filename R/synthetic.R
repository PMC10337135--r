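#' Parameters for the synthetic Chilean input bundle
#'
#' Controls the synthetic generator that emulates the study population:
#' a closed cohort of Chilean adults aged 20-80 in 2019, with BMI
#' distributions anchored to the National-Health-Survey-style statistics
#' (male mean 28.1 kg/m^2, female mean 29.4 kg/m^2, overweight prevalence
#' 75.7%) and order-of-magnitude-plausible disease rates for the 11
#' modelled diseases. The per-stratum standard deviation is solved from
#' the overweight-prevalence anchor, so the two printed anchors identify
#' the two-parameter normal family.
#'
#' @param seed Integer seed (the generator is deterministic; the seed is
#'   recorded and reused by downstream Monte Carlo machinery).
#' @param scale Cohort size per sex. Default 1e5.
#' @param male_mean_bmi,female_mean_bmi Population mean BMI anchors,
#'   kg/m^2.
#' @param overweight_prev Overweight prevalence anchor, `P(BMI >= 25)`.
#' @param bmi_age_amplitude Linear age gradient amplitude of mean BMI
#'   (kg/m^2 spread across the age range); the population-weighted mean
#'   stays at the anchor.
#' @param gompertz_rate Exponential age slope of all-cause mortality.
#' @param male_mortality_20,female_mortality_20 All-cause mortality rate
#'   at age 20 per sex (person-year rates).
#' @param disease_params Optional tibble overriding the per-disease base
#'   incidence/case-fatality magnitudes (see
#'   [default_disease_params()]).
#' @return An object of class `synthetic_params` (a list).
#' @export
synthetic_params <- function(seed = 1234L,
                             scale = 1e5,
                             male_mean_bmi = 28.1,
                             female_mean_bmi = 29.4,
                             overweight_prev = 0.757,
                             bmi_age_amplitude = 0.5,
                             gompertz_rate = 0.082,
                             male_mortality_20 = 5e-4,
                             female_mortality_20 = 3.5e-4,
                             disease_params = default_disease_params()) {
  if (scale <= 0) stop("population scale must be positive", call. = FALSE)
  if (overweight_prev <= 0 || overweight_prev >= 1) {
    stop("overweight prevalence anchor must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed),
      scale = scale,
      male_mean_bmi = male_mean_bmi,
      female_mean_bmi = female_mean_bmi,
      overweight_prev = overweight_prev,
      bmi_age_amplitude = bmi_age_amplitude,
      gompertz_rate = gompertz_rate,
      male_mortality_20 = male_mortality_20,
      female_mortality_20 = female_mortality_20,
      disease_params = disease_params
    ),
    class = "synthetic_params"
  )
}

#' Default synthetic disease-rate magnitudes
#'
#' Per-disease base incidence and case fatality at age 20 (person-year
#' rates), exponential age slopes, the remission rate (cancers only) and
#' relative female incidence. Magnitudes are order-of-magnitude plausible
#' for an adult general population; they are deliberately not calibrated
#' to any published national rate set.
#'
#' @return A tibble, one row per disease.
#' @export
default_disease_params <- function() {
  tibble::tibble(
    disease_id = disease_ids(),
    base_incidence = c(
      5e-4, 4e-4, 1e-4, 2e-3, 1.5e-3, 1.5e-4,
      3e-5, 1e-5, 8e-6, 6e-5, 1e-5
    ),
    incidence_slope = c(
      0.055, 0.060, 0.060, 0.030, 0.035, 0.030,
      0.065, 0.060, 0.060, 0.045, 0.070
    ),
    base_case_fatality = c(
      0.030, 0.025, 0.020, 0.004, 0.010, 0.060,
      0.080, 0.090, 0.250, 0.040, 0.350
    ),
    case_fatality_slope = c(
      0.030, 0.030, 0.030, 0.020, 0.025, 0.010,
      0.010, 0.010, 0.005, 0.010, 0.003
    ),
    remission = ifelse(disease_id %in% cancer_ids(), 0.1, 0),
    female_multiplier = c(
      0.7, 0.9, 1.1, 1.0, 0.9, 0.6,
      0.8, 0.6, 0.5, 50, 0.9
    )
  )
}

#' Generate a synthetic closed-cohort population
#'
#' Both sexes, single-year ages 20-80, with a gently declining age
#' pyramid and Gompertz all-cause mortality (exponential increase with
#' age). Deterministic given the parameters.
#'
#' @param params A [synthetic_params()] object.
#' @return Population tibble: `sex`, `age`, `count`,
#'   `all_cause_mortality_rate`.
#' @export
generate_population <- function(params = synthetic_params()) {
  ages <- 20:80
  w <- exp(-0.015 * (ages - 20))
  purrr::map_dfr(c("male", "female"), function(s) {
    m20 <- if (s == "male") params$male_mortality_20 else params$female_mortality_20
    tibble::tibble(
      sex = s,
      age = ages,
      count = round(params$scale * w / sum(w)),
      all_cause_mortality_rate = m20 * exp(params$gompertz_rate * (ages - 20))
    )
  })
}

#' Generate the synthetic baseline BMI distributions
#'
#' Normal BMI distribution per sex/age stratum. Stratum means follow a
#' mild linear age gradient whose population-weighted average equals the
#' sex anchor; each stratum's standard deviation is solved so that
#' `P(BMI >= 25)` equals the overweight-prevalence anchor, hence the
#' pooled prevalence hits the anchor exactly.
#'
#' @param params A [synthetic_params()] object.
#' @param population Optional population tibble (defaults to
#'   [generate_population()] with the same params) used for the age
#'   weighting.
#' @return BMI baseline tibble: `sex`, `age`, `mean_bmi`, `sd_bmi`.
#' @export
generate_bmi_baseline <- function(params = synthetic_params(),
                                  population = NULL) {
  population <- population %||% generate_population(params)
  z <- qnorm(params$overweight_prev)
  purrr::map_dfr(c("male", "female"), function(s) {
    pop_s <- population[population$sex == s, ]
    anchor <- if (s == "male") params$male_mean_bmi else params$female_mean_bmi
    abar <- sum(pop_s$age * pop_s$count) / sum(pop_s$count)
    mean_bmi <- anchor + params$bmi_age_amplitude * (pop_s$age - abar) / 30
    sd_bmi <- (mean_bmi - 25) / z
    if (any(sd_bmi <= 0)) {
      stop(
        "infeasible BMI anchors for sex ", s, ": the mean/prevalence pair ",
        "requires a non-positive standard deviation", call. = FALSE
      )
    }
    tibble::tibble(sex = s, age = pop_s$age, mean_bmi = mean_bmi, sd_bmi = sd_bmi)
  })
}

steady_state_prevalence <- function(i, r, f) {
  # Equilibrium of dp/dt = i(1-p) - (r+f)p + f p^2 (all-cause mortality
  # cancels); smaller quadratic root, reducing to i/(i+r) when f = 0.
  p <- ifelse(
    f > 0,
    ((i + r + f) - sqrt((i + r + f)^2 - 4 * f * i)) / (2 * f),
    ifelse(i + r > 0, i / (i + r), 0)
  )
  pmin(pmax(p, 0), 1)
}

#' Generate synthetic disease epidemiology
#'
#' Eleven diseases with exponentially age-increasing incidence and case
#' fatality, remission for the five cancers only, and prevalence set to
#' the illness-death steady state implied by (incidence, remission, case
#' fatality), so [validate_epi_consistency()] returns no findings by
#' construction.
#'
#' @param params A [synthetic_params()] object.
#' @param population Population tibble defining the strata.
#' @return Disease epidemiology tibble: `disease_id`, `sex`, `age`,
#'   `incidence`, `remission`, `case_fatality`, `prevalence`.
#' @export
generate_disease_epi <- function(params = synthetic_params(),
                                 population = NULL) {
  population <- population %||% generate_population(params)
  dp <- params$disease_params
  assert_known_diseases(dp$disease_id, "disease_params")
  purrr::map_dfr(seq_len(nrow(dp)), function(k) {
    d <- dp[k, ]
    purrr::map_dfr(c("male", "female"), function(s) {
      ages <- sort(unique(population$age[population$sex == s]))
      sexmult <- if (s == "female") d$female_multiplier else 1
      i <- d$base_incidence * sexmult * exp(d$incidence_slope * (ages - 20))
      f <- d$base_case_fatality * exp(d$case_fatality_slope * (ages - 20))
      r <- rep(d$remission, length(ages))
      tibble::tibble(
        disease_id = d$disease_id,
        sex = s,
        age = ages,
        incidence = i,
        remission = r,
        case_fatality = f,
        prevalence = steady_state_prevalence(i, r, f)
      )
    })
  })
}

#' Generate the full synthetic input bundle
#'
#' Population, baseline BMI distributions, disease epidemiology, the
#' published relative-risk specification and a model configuration,
#' assembled into a validated [mslt_inputs()] bundle. Deterministic given
#' the parameters; every downstream stage of the package is testable on
#' this bundle without any external data.
#'
#' @param params A [synthetic_params()] object.
#' @param config An [model_config()] object; its seed defaults to the
#'   generator seed.
#' @return An `mslt_inputs` bundle.
#' @export
#' @examples
#' inputs <- generate_synthetic_inputs(synthetic_params(scale = 1e4))
#' inputs
generate_synthetic_inputs <- function(params = synthetic_params(),
                                      config = NULL) {
  config <- config %||% model_config(seed = params$seed)
  pop <- generate_population(params)
  mslt_inputs(
    population = pop,
    bmi_baseline = generate_bmi_baseline(params, pop),
    disease_epi = generate_disease_epi(params, pop),
    rr_spec = default_rr_spec(),
    config = config
  )
}
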