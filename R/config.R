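#' Model configuration
#'
#' Bundles the projection horizon, the canonical scenario parameters, the
#' theoretical-minimum-risk exposure level (TMREL), the BMI discretization
#' grid and the Monte Carlo settings.
#'
#' Scenario parameters (annual fractions unless noted):
#' * `bau_annual_bmi_increase`: business-as-usual mean-BMI growth, 0.4%/yr
#'   (the 2003-2017 trend continued).
#' * `scenario1_annual_bmi_increase`: the BAU growth halved, 0.2%/yr.
#' * `scenario2_prevalence_target`: the overweight-prevalence anchor held by
#'   Scenario 2 (on average 76.9%); the hold mechanism freezes each
#'   stratum's baseline prevalence so all scenarios coincide in
#'   `start_year`.
#' * `scenario3_total_reduction` / `scenario3_annual_step`: Scenario 3
#'   reduces overweight prevalence by 6.7% (relative) over the horizon,
#'   0.61% per year, applied linearly on the prevalence scale.
#'
#' @param start_year First simulated year (baseline). Default 2019.
#' @param end_year Last simulated year. Default 2030.
#' @param tmrel_bmi Theoretical minimum-risk BMI, kg/m^2. Default 22.
#' @param bau_annual_bmi_increase Annual relative increase of mean BMI under
#'   business as usual. Default 0.004.
#' @param scenario1_annual_bmi_increase Annual relative increase under
#'   Scenario 1. Default 0.002.
#' @param scenario2_prevalence_target Overweight prevalence anchor for
#'   Scenario 2. Default 0.769.
#' @param scenario3_total_reduction Total relative reduction of overweight
#'   prevalence reached by `end_year` under Scenario 3. Default 0.067.
#' @param scenario3_annual_step Annual relative reduction step under
#'   Scenario 3. Default 0.0061.
#' @param n_draws Monte Carlo draws for uncertainty intervals. Default 1000.
#' @param seed Integer seed for the Monte Carlo sampler.
#' @param bmi_grid_lo,bmi_grid_hi,bmi_grid_step BMI discretization grid
#'   bounds and step (kg/m^2) for potential-impact-fraction integrals.
#'   Defaults 10, 60, 0.1.
#' @return An object of class `mslt_config` (a validated list).
#' @export
#' @examples
#' model_config()
model_config <- function(start_year = 2019L,
                         end_year = 2030L,
                         tmrel_bmi = 22,
                         bau_annual_bmi_increase = 0.004,
                         scenario1_annual_bmi_increase = 0.002,
                         scenario2_prevalence_target = 0.769,
                         scenario3_total_reduction = 0.067,
                         scenario3_annual_step = 0.0061,
                         n_draws = 1000L,
                         seed = 1L,
                         bmi_grid_lo = 10,
                         bmi_grid_hi = 60,
                         bmi_grid_step = 0.1) {
  cfg <- list(
    start_year = as.integer(start_year),
    end_year = as.integer(end_year),
    tmrel_bmi = tmrel_bmi,
    bau_annual_bmi_increase = bau_annual_bmi_increase,
    scenario1_annual_bmi_increase = scenario1_annual_bmi_increase,
    scenario2_prevalence_target = scenario2_prevalence_target,
    scenario3_total_reduction = scenario3_total_reduction,
    scenario3_annual_step = scenario3_annual_step,
    n_draws = as.integer(n_draws),
    seed = as.integer(seed),
    bmi_grid_lo = bmi_grid_lo,
    bmi_grid_hi = bmi_grid_hi,
    bmi_grid_step = bmi_grid_step
  )
  validate_config(cfg)
  structure(cfg, class = "mslt_config")
}

validate_config <- function(cfg) {
  if (cfg$start_year >= cfg$end_year) {
    stop("model config: start_year must precede end_year", call. = FALSE)
  }
  pos <- c(
    "bau_annual_bmi_increase", "scenario1_annual_bmi_increase",
    "scenario2_prevalence_target", "scenario3_total_reduction",
    "scenario3_annual_step"
  )
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0) {
      stop("model config: ", p, " must be positive", call. = FALSE)
    }
  }
  if (cfg$scenario2_prevalence_target >= 1) {
    stop("model config: scenario2_prevalence_target must be below 1",
      call. = FALSE
    )
  }
  if (cfg$n_draws < 1L) {
    stop("model config: n_draws must be at least 1", call. = FALSE)
  }
  if (cfg$bmi_grid_lo >= cfg$bmi_grid_hi || cfg$bmi_grid_step <= 0) {
    stop("model config: invalid BMI grid specification", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.mslt_config <- function(x, ...) {
  cat("<mslt_config>\n")
  cat("  horizon:", x$start_year, "-", x$end_year,
    " TMREL:", x$tmrel_bmi, "kg/m^2\n"
  )
  cat(
    "  scenarios: BAU +", 100 * x$bau_annual_bmi_increase,
    "%/yr | S1 +", 100 * x$scenario1_annual_bmi_increase,
    "%/yr | S2 hold | S3 -", 100 * x$scenario3_total_reduction,
    "% by", x$end_year, "\n"
  )
  cat("  Monte Carlo:", x$n_draws, "draws, seed", x$seed, "\n")
  invisible(x)
}

#' BMI discretization grid midpoints
#'
#' Midpoint grid over `[lo, hi]` used to integrate relative-risk curves
#' against BMI densities. Tail mass outside the grid is truncated and the
#' discretized distribution renormalized.
#'
#' @param config An [model_config()] object (grid fields are read from it),
#'   or `NULL` to use the defaults.
#' @param lo,hi,step Optional overrides of the grid bounds/step.
#' @return Numeric vector of interval midpoints.
#' @export
bmi_grid <- function(config = NULL, lo = NULL, hi = NULL, step = NULL) {
  if (is.null(config)) config <- model_config()
  lo <- lo %||% config$bmi_grid_lo
  hi <- hi %||% config$bmi_grid_hi
  step <- step %||% config$bmi_grid_step
  seq(lo + step / 2, hi - step / 2, by = step)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
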