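#' Project mean-BMI growth over the horizon
#'
#' Builds a BMI trajectory in which each stratum's mean grows geometrically
#' at a fixed annual rate while its standard deviation stays fixed:
#' `mean(t) = mean(start_year) * (1 + rate)^(t - start_year)`. The
#' start-year distributions equal the baseline exactly.
#'
#' @param baseline BMI baseline tibble: `sex`, `age`, `mean_bmi`, `sd_bmi`.
#' @param annual_rate Annual relative increase of mean BMI (>= 0; use the
#'   prevalence mechanisms for reductions).
#' @param years Integer vector of years, first element the baseline year.
#' @param scenario_id Label stored in the trajectory.
#' @return A BMI trajectory tibble: `scenario_id`, `year`, `sex`, `age`,
#'   `mean_bmi`, `sd_bmi`.
#' @export
#' @examples
#' base <- tibble::tibble(
#'   sex = "male", age = 40, mean_bmi = 28, sd_bmi = 4
#' )
#' mean_growth_trajectory(base, 0.004, 2019:2030)
mean_growth_trajectory <- function(baseline, annual_rate, years,
                                   scenario_id = "BAU") {
  if (annual_rate < 0) {
    stop(
      "annual_rate must be non-negative; use a prevalence mechanism ",
      "for reductions", call. = FALSE
    )
  }
  y0 <- years[1]
  purrr::map_dfr(years, function(y) {
    dplyr::mutate(
      baseline,
      scenario_id = scenario_id,
      year = y,
      mean_bmi = .data$mean_bmi * (1 + annual_rate)^(y - y0),
      .before = 1
    )
  })
}

#' Shift a BMI distribution to hit a target overweight prevalence
#'
#' Moves the mean of a normal BMI distribution (standard deviation fixed)
#' so that `P(BMI >= 25)` equals the target prevalence. For a normal
#' distribution the shifted mean has the closed form
#' `25 + sd * qnorm(target)`.
#'
#' @param mean,sd Current mean and standard deviation, kg/m^2 (`sd > 0`).
#' @param target_prevalence Target overweight prevalence, strictly in
#'   (0, 1).
#' @param cutoff Overweight threshold, default 25 kg/m^2.
#' @return The shifted mean (vectorized over `mean`/`sd`/`target`).
#' @export
#' @examples
#' prevalence_to_mean_shift(27, 4, 0.75) # 27.698
prevalence_to_mean_shift <- function(mean, sd, target_prevalence,
                                     cutoff = 25) {
  if (any(target_prevalence <= 0) || any(target_prevalence >= 1)) {
    stop(
      "target overweight prevalence must be strictly between 0 and 1",
      call. = FALSE
    )
  }
  if (any(sd <= 0)) {
    stop("prevalence shifts require sd > 0", call. = FALSE)
  }
  cutoff + sd * qnorm(target_prevalence)
}

#' Trajectory holding or reducing overweight prevalence
#'
#' Builds a BMI trajectory in which each stratum's overweight prevalence
#' follows a prescribed relative path of its baseline value, implemented
#' as a mean shift with fixed standard deviation
#' ([prevalence_to_mean_shift()]). `relative_path = 1` for every year
#' reproduces the frozen baseline (the prevalence-hold mechanism).
#'
#' @param baseline BMI baseline tibble: `sex`, `age`, `mean_bmi`, `sd_bmi`.
#' @param relative_path Numeric vector, one value per year: the stratum
#'   prevalence in that year as a fraction of its baseline prevalence.
#' @param years Integer vector of years (same length as `relative_path`,
#'   first element the baseline year with `relative_path[1] == 1`).
#' @param scenario_id Label stored in the trajectory.
#' @return A BMI trajectory tibble (see [mean_growth_trajectory()]).
#' @export
prevalence_path_trajectory <- function(baseline, relative_path, years,
                                       scenario_id) {
  stopifnot(length(relative_path) == length(years))
  if (abs(relative_path[1] - 1) > 1e-12) {
    stop(
      "prevalence path must start at 1 so the trajectory coincides with ",
      "the baseline in the start year", call. = FALSE
    )
  }
  base_prev <- overweight_prevalence(baseline$mean_bmi, baseline$sd_bmi)
  purrr::map_dfr(seq_along(years), function(k) {
    target <- pmin(pmax(base_prev * relative_path[k], 1e-12), 1 - 1e-12)
    dplyr::mutate(
      baseline,
      scenario_id = scenario_id,
      year = years[k],
      mean_bmi = prevalence_to_mean_shift(
        baseline$mean_bmi, baseline$sd_bmi, target
      ),
      .before = 1
    )
  })
}

#' Build the four canonical BMI scenarios
#'
#' Constructs the business-as-usual and three counterfactual trajectories
#' from the baseline BMI distributions:
#' * `BAU`: mean BMI grows 0.4%/yr (the observed 2003-2017 trend).
#' * `S1`: growth halved, 0.2%/yr.
#' * `S2`: each stratum's overweight prevalence held at its baseline value
#'   (the frozen-baseline trajectory; the configured 76.9% anchor is the
#'   population average this hold represents).
#' * `S3`: overweight prevalence reduced linearly by 0.61%/yr, reaching a
#'   6.7% relative reduction by the end year.
#'
#' All four trajectories equal the baseline in `start_year`.
#'
#' @param config An [model_config()] object.
#' @param baseline BMI baseline tibble: `sex`, `age`, `mean_bmi`, `sd_bmi`.
#' @return Named list of four BMI trajectory tibbles: `BAU`, `S1`, `S2`,
#'   `S3`.
#' @export
build_canonical_scenarios <- function(config, baseline) {
  years <- seq(config$start_year, config$end_year)
  k <- seq_along(years) - 1
  s3_path <- 1 - config$scenario3_annual_step * k
  list(
    BAU = mean_growth_trajectory(
      baseline, config$bau_annual_bmi_increase, years, "BAU"
    ),
    S1 = mean_growth_trajectory(
      baseline, config$scenario1_annual_bmi_increase, years, "S1"
    ),
    S2 = prevalence_path_trajectory(baseline, rep(1, length(years)), years, "S2"),
    S3 = prevalence_path_trajectory(baseline, s3_path, years, "S3")
  )
}

#' TMREL reference trajectory
#'
#' A degenerate trajectory holding every stratum at the theoretical
#' minimum-risk BMI (point mass, `sd = 0`) in every year. Used as the
#' counterfactual reference when computing attributable burden.
#'
#' @inheritParams build_canonical_scenarios
#' @return A BMI trajectory tibble with `mean_bmi = tmrel`, `sd_bmi = 0`.
#' @export
tmrel_trajectory <- function(config, baseline) {
  years <- seq(config$start_year, config$end_year)
  purrr::map_dfr(years, function(y) {
    dplyr::mutate(
      baseline,
      scenario_id = "TMREL",
      year = y,
      mean_bmi = config$tmrel_bmi,
      sd_bmi = 0,
      .before = 1
    )
  })
}
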