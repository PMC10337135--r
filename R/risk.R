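#' Relative risk at a given BMI
#'
#' Evaluates the relative-risk (RR) curve of a disease for a given sex, age
#' and BMI from a relative-risk specification table (see
#' [default_rr_spec()]).
#'
#' Two functional forms are supported:
#' * `per5_loglinear`: the band RR is the risk ratio per 5 kg/m^2 of BMI
#'   above the TMREL, so `RR(bmi) = rr_band ^ ((bmi - tmrel) / 5)`. Below
#'   the TMREL the curve is floored at 1 (risk reversal under low BMI is
#'   not modelled). Age bands are matched on `age`; diseases flagged
#'   `extend_age = TRUE` clamp ages outside the printed bands to the
#'   nearest band, while restricted-applicability diseases (liver cancer
#'   35-79 years, breast cancer in women above 60) return RR = 1 outside
#'   their window.
#' * `categorical`: the RR is a step function of BMI band (e.g. BMI 15-25
#'   vs 25-50); values below/above the outermost bands are clamped to the
#'   nearest band. Printed sub-unity values in the low-BMI band are used
#'   as printed.
#'
#' @param rr_spec Relative-risk specification tibble (schema of
#'   [default_rr_spec()]).
#' @param disease_id One canonical disease id, see [disease_ids()].
#' @param sex `"male"` or `"female"`.
#' @param age Age in years (scalar).
#' @param bmi Numeric vector of BMI values, kg/m^2.
#' @param tmrel Theoretical minimum-risk BMI. Default 22.
#' @return Numeric vector of RR values, same length as `bmi`.
#' @export
#' @examples
#' rr <- default_rr_spec()
#' rr_at_bmi(rr, "chd", "male", 45, 27) # 1.50: one 5-unit step above TMREL
#' rr_at_bmi(rr, "hhd", "female", 50, 30) # 2.03: categorical 25-50 band
rr_at_bmi <- function(rr_spec, disease_id, sex, age, bmi, tmrel = 22) {
  stopifnot(length(disease_id) == 1, length(sex) == 1, length(age) == 1)
  rows <- rr_spec[rr_spec$disease_id == disease_id, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop(
      "relative-risk specification gap: no bands for disease ", disease_id,
      call. = FALSE
    )
  }
  form <- unique(rows$form)
  if (length(form) != 1) {
    stop(
      "relative-risk specification for ", disease_id,
      " mixes functional forms", call. = FALSE
    )
  }

  if (form == "categorical") {
    # Categorical specs are sex- and age-invariant here; step function of BMI.
    val <- categorical_rr_values(rows, bmi)
    return(val)
  }

  # per5_loglinear: find the band for this sex/age
  sex_rows <- rows[rows$sex %in% c("both", sex), , drop = FALSE]
  extend <- isTRUE(rows$extend_age[1])
  if (nrow(sex_rows) == 0) {
    if (extend) {
      stop(
        "relative-risk specification gap for ", disease_id,
        ": no band for sex ", sex, call. = FALSE
      )
    }
    return(rep(1, length(bmi))) # outside applicability (e.g. breast, men)
  }
  band <- sex_rows[age >= sex_rows$age_lo & age <= sex_rows$age_hi, ,
    drop = FALSE
  ]
  if (nrow(band) == 0) {
    if (!extend) {
      return(rep(1, length(bmi))) # outside applicability window
    }
    # clamp to youngest/oldest printed band
    if (age < min(sex_rows$age_lo)) {
      band <- sex_rows[which.min(sex_rows$age_lo), , drop = FALSE]
    } else if (age > max(sex_rows$age_hi)) {
      band <- sex_rows[which.max(sex_rows$age_hi), , drop = FALSE]
    } else {
      stop(
        "relative-risk specification gap for ", disease_id, ", sex ", sex,
        ", age ", age, ": age falls between bands", call. = FALSE
      )
    }
  }
  if (nrow(band) > 1) {
    stop(
      "relative-risk specification for ", disease_id,
      " has overlapping bands at sex ", sex, ", age ", age, call. = FALSE
    )
  }
  rr_band <- band$rr[1]
  out <- rr_band^(pmax(bmi - tmrel, 0) / 5)
  pmax(out, 0)
}

categorical_rr_values <- function(rows, bmi) {
  rows <- rows[order(rows$bmi_lo), , drop = FALSE]
  val <- rep(NA_real_, length(bmi))
  for (k in seq_len(nrow(rows))) {
    inband <- bmi >= rows$bmi_lo[k] & bmi < rows$bmi_hi[k]
    val[inband] <- rows$rr[k]
  }
  val[bmi < rows$bmi_lo[1]] <- rows$rr[1]
  val[bmi >= rows$bmi_hi[nrow(rows)]] <- rows$rr[nrow(rows)]
  val
}

#' Relative-risk curve as a function of BMI
#'
#' Convenience wrapper around [rr_at_bmi()] returning a vectorized
#' `function(bmi)` for a fixed disease/sex/age context.
#'
#' @inheritParams rr_at_bmi
#' @return A function mapping a numeric BMI vector to RR values.
#' @export
rr_curve <- function(rr_spec, disease_id, sex, age, tmrel = 22) {
  force(rr_spec); force(disease_id); force(sex); force(age); force(tmrel)
  function(bmi) rr_at_bmi(rr_spec, disease_id, sex, age, bmi, tmrel = tmrel)
}

#' Discretize a normal BMI distribution on a grid
#'
#' Evaluates the normal density at the grid midpoints, truncates tail mass
#' outside the grid and renormalizes. A degenerate distribution (`sd = 0`)
#' puts all mass on the grid point nearest the mean.
#'
#' @param mean,sd Mean and standard deviation of the BMI distribution,
#'   kg/m^2 (`sd = 0` gives a point mass).
#' @param grid Grid midpoints from [bmi_grid()].
#' @return Numeric vector of probability weights summing to 1.
#' @export
discretize_bmi <- function(mean, sd, grid) {
  if (sd < 0) stop("BMI distribution sd must be non-negative", call. = FALSE)
  if (sd == 0) {
    w <- numeric(length(grid))
    w[which.min(abs(grid - mean))] <- 1
    return(w)
  }
  w <- dnorm(grid, mean, sd)
  s <- sum(w)
  if (s <= 0) {
    stop(
      "BMI distribution has no mass on the grid (mean ", mean,
      ", sd ", sd, ")", call. = FALSE
    )
  }
  w / s
}

resolve_dist_weights <- function(dist, grid, what) {
  if (is.numeric(dist) && length(dist) == length(grid)) {
    s <- sum(dist)
    if (s <= 0) stop(what, " weights sum to zero", call. = FALSE)
    return(dist / s)
  }
  if (is.list(dist) && !is.null(dist$mean)) {
    sd <- dist$sd %||% 0
    return(discretize_bmi(dist$mean, sd, grid))
  }
  stop(
    what, " must be list(mean=, sd=) or a weight vector on the grid",
    call. = FALSE
  )
}

resolve_rr_values <- function(curve, grid) {
  if (is.function(curve)) {
    return(curve(grid))
  }
  if (is.numeric(curve) && length(curve) == length(grid)) {
    return(curve)
  }
  stop(
    "curve must be a function of BMI or an RR vector on the grid",
    call. = FALSE
  )
}

#' Potential impact fraction of a BMI shift
#'
#' Computes the potential impact fraction (PIF) comparing a counterfactual
#' BMI distribution to a reference distribution under a relative-risk
#' curve:
#' \deqn{PIF = \frac{\sum_x P_{ref}(x) RR(x) - \sum_x P_{cf}(x) RR(x)}
#'                  {\sum_x P_{ref}(x) RR(x)}}
#' evaluated on the discretized BMI grid. The PIF is 0 when the two
#' distributions coincide and positive when the counterfactual moves mass
#' toward lower risk; `1 - PIF` is the incidence multiplier applied to
#' disease inflow in the life table (see [incidence_multiplier()]).
#'
#' Distributions may be given as `list(mean =, sd =)` (normal, discretized
#' via [discretize_bmi()]; `sd = 0` is a point mass evaluated exactly) or
#' as explicit probability weights on the grid. The curve may be a
#' function of BMI (e.g. [rr_curve()]) or a precomputed RR vector on the
#' grid.
#'
#' @param reference,counterfactual BMI distributions (see Details).
#' @param curve Relative-risk curve or RR vector on the grid.
#' @param grid Grid midpoints from [bmi_grid()].
#' @return The PIF, a scalar in `(-Inf, 1]`.
#' @export
#' @examples
#' g <- bmi_grid()
#' curve <- rr_curve(default_rr_spec(), "chd", "male", 45)
#' pif(list(mean = 28, sd = 4), list(mean = 27, sd = 4), curve, g)
pif <- function(reference, counterfactual, curve, grid) {
  1 - incidence_multiplier(reference, counterfactual, curve, grid)
}

#' Incidence multiplier of a BMI shift
#'
#' The ratio of mean relative risk under the counterfactual BMI
#' distribution to that under the reference distribution,
#' `1 - PIF`. Multiplies disease incidence in the multistate life table.
#'
#' @inheritParams pif
#' @return Non-negative scalar multiplier (1 when the distributions
#'   coincide).
#' @export
incidence_multiplier <- function(reference, counterfactual, curve, grid) {
  e_ref <- mean_rr(reference, curve, grid)
  e_cf <- mean_rr(counterfactual, curve, grid)
  if (e_ref <= 0) {
    stop("mean relative risk under the reference distribution is not positive",
      call. = FALSE
    )
  }
  e_cf / e_ref
}

mean_rr <- function(dist, curve, grid) {
  # Point masses are evaluated exactly at the mean, off the grid.
  if (is.list(dist) && !is.null(dist$mean) && identical(dist$sd %||% 0, 0) &&
    is.function(curve)) {
    return(curve(dist$mean))
  }
  w <- resolve_dist_weights(dist, grid, "distribution")
  rrv <- resolve_rr_values(curve, grid)
  sum(w * rrv)
}

#' Overweight prevalence of a normal BMI distribution
#'
#' `P(BMI >= cutoff)` for a normal distribution; a point mass (`sd = 0`)
#' gives 0 or 1.
#'
#' @param mean,sd Mean and standard deviation, kg/m^2.
#' @param cutoff Overweight threshold, default 25 kg/m^2.
#' @return Prevalence in `[0, 1]`, vectorized over `mean`/`sd`.
#' @export
overweight_prevalence <- function(mean, sd, cutoff = 25) {
  ifelse(sd == 0, as.numeric(mean >= cutoff), 1 - pnorm(cutoff, mean, sd))
}
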