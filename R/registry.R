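#' Canonical registry of the 11 BMI-related diseases
#'
#' The model tracks eleven non-communicable diseases for which excess BMI is
#' an established risk factor: three cardiovascular diseases (coronary heart
#' disease, stroke, hypertensive heart disease), type 2 diabetes, chronic
#' kidney disease, cirrhosis, and five cancers (colorectal, kidney, liver,
#' breast, pancreas). Exposure-to-incidence lag times are 5 years for the
#' non-cancer diseases and 10 years for the cancers, and remission is
#' modelled for cancers only.
#'
#' @return A tibble with one row per disease: `disease_id`, `disease_name`,
#'   `group` (reporting group), `is_cancer`, `lag_years`.
#' @export
#' @examples
#' disease_registry()
disease_registry <- function() {
  tibble::tibble(
    disease_id = c(
      "chd", "stroke", "hhd", "t2dm", "ckd", "cirrhosis",
      "colorectal_cancer", "kidney_cancer", "liver_cancer",
      "breast_cancer", "pancreatic_cancer"
    ),
    disease_name = c(
      "Coronary heart disease", "Stroke", "Hypertensive heart disease",
      "Type 2 diabetes", "Chronic kidney disease", "Cirrhosis",
      "Colorectal cancer", "Kidney cancer", "Liver cancer",
      "Breast cancer", "Pancreatic cancer"
    ),
    group = c(
      "cardiovascular", "cardiovascular", "cardiovascular",
      "type 2 diabetes", "chronic kidney disease", "cirrhosis",
      "cancer", "cancer", "cancer", "cancer", "cancer"
    ),
    is_cancer = c(rep(FALSE, 6), rep(TRUE, 5)),
    lag_years = c(rep(5L, 6), rep(10L, 5))
  )
}

#' Disease ids in the canonical registry
#' @return Character vector of the 11 canonical `disease_id`s.
#' @export
disease_ids <- function() disease_registry()$disease_id

#' Ids of the five cancers
#' @return Character vector of the cancer `disease_id`s.
#' @export
cancer_ids <- function() {
  reg <- disease_registry()
  reg$disease_id[reg$is_cancer]
}

#' Default reporting grouping of the 11 diseases
#'
#' Partitions the registry into the groups used for burden shares:
#' cardiovascular diseases (coronary heart disease + stroke + hypertensive
#' heart disease), type 2 diabetes, chronic kidney disease, cirrhosis, and
#' the five cancers pooled.
#'
#' @return Named list of character vectors partitioning [disease_ids()].
#' @export
default_grouping <- function() {
  reg <- disease_registry()
  split(reg$disease_id, reg$group)
}

assert_known_diseases <- function(ids, where = "input") {
  unknown <- setdiff(unique(ids), disease_ids())
  if (length(unknown) > 0) {
    stop(
      "schema error in ", where, ": unknown disease_id ",
      paste(unknown, collapse = ", "),
      "; known ids are ", paste(disease_ids(), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}
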