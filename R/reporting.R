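#' Aggregate burden to scenario totals
#'
#' Sums a burden table (fixture or model output) over diseases and, when
#' present, years, producing the total NCD burden and the cancer subtotal
#' per outcome and scenario. Printed subtotal rows (`total_cancer`) in a
#' fixture are ignored; the subtotal is recomputed from the five cancers.
#'
#' @param burden Burden tibble with columns `outcome`, `disease_id`,
#'   `scenario_id`, `value` (optionally `year`).
#' @return Tibble `outcome`, `scenario_id`, `measure`
#'   (`TOTAL`/`TOTAL_CANCER`), `value`.
#' @export
#' @examples
#' aggregate_totals(load_reference_burden())
aggregate_totals <- function(burden) {
  burden <- burden[burden$disease_id %in% disease_ids(), , drop = FALSE]
  check_complete_diseases(burden)
  by_disease <- dplyr::summarise(
    burden,
    value = sum(.data$value),
    .by = c("outcome", "scenario_id", "disease_id")
  )
  total <- dplyr::summarise(
    by_disease,
    measure = "TOTAL", value = sum(.data$value),
    .by = c("outcome", "scenario_id")
  )
  cancer <- dplyr::summarise(
    by_disease[by_disease$disease_id %in% cancer_ids(), ],
    measure = "TOTAL_CANCER", value = sum(.data$value),
    .by = c("outcome", "scenario_id")
  )
  dplyr::bind_rows(total, cancer) |>
    dplyr::select("outcome", "scenario_id", "measure", "value") |>
    dplyr::arrange(.data$outcome, .data$scenario_id, .data$measure)
}

check_complete_diseases <- function(burden) {
  combos <- unique(burden[, c("outcome", "scenario_id")])
  for (r in seq_len(nrow(combos))) {
    have <- unique(burden$disease_id[
      burden$outcome == combos$outcome[r] &
        burden$scenario_id == combos$scenario_id[r]
    ])
    missing <- setdiff(disease_ids(), have)
    if (length(missing) > 0) {
      stop(
        "aggregation error: burden for ", combos$outcome[r], "/",
        combos$scenario_id[r], " is missing ",
        paste(missing, collapse = ", "), call. = FALSE
      )
    }
  }
  invisible(TRUE)
}

#' Averted burden relative to business as usual
#'
#' Elementwise BAU minus scenario, per disease plus `TOTAL` and
#' `TOTAL_CANCER` rows; the BAU scenario itself averts zero by
#' definition.
#'
#' @param burden Burden tibble covering BAU and at least one scenario.
#' @return Tibble `outcome`, `scenario_id`, `disease_id` (diseases plus
#'   `TOTAL`/`TOTAL_CANCER`), `averted`.
#' @export
#' @examples
#' av <- averted(load_reference_burden())
#' subset(av, disease_id == "TOTAL" & outcome == "cases")
averted <- function(burden) {
  burden <- burden[burden$disease_id %in% disease_ids(), , drop = FALSE]
  if (!"BAU" %in% burden$scenario_id) {
    stop("averted burden needs a BAU partner scenario", call. = FALSE)
  }
  by_disease <- dplyr::summarise(
    burden,
    value = sum(.data$value),
    .by = c("outcome", "scenario_id", "disease_id")
  )
  totals <- aggregate_totals(burden) |>
    dplyr::rename(disease_id = "measure")
  all_rows <- dplyr::bind_rows(by_disease, totals)
  bau <- all_rows[all_rows$scenario_id == "BAU", ] |>
    dplyr::rename(bau_value = "value") |>
    dplyr::select(-"scenario_id")
  dplyr::inner_join(all_rows, bau, by = c("outcome", "disease_id")) |>
    dplyr::mutate(averted = .data$bau_value - .data$value) |>
    dplyr::select("outcome", "scenario_id", "disease_id", "averted") |>
    dplyr::arrange(.data$outcome, .data$scenario_id, .data$disease_id)
}

#' Burden shares by disease group
#'
#' Percent of the scenario total contributed by each group of a
#' partition of the 11 diseases (default grouping: cardiovascular
#' diseases, type 2 diabetes, chronic kidney disease, cirrhosis,
#' cancers). Shares are rounded to one decimal at presentation; internal
#' arithmetic is unrounded.
#'
#' @param burden Burden tibble.
#' @param grouping Named list of disease-id vectors partitioning
#'   [disease_ids()]; default [default_grouping()].
#' @return Tibble `outcome`, `scenario_id`, `group`, `share` (percent,
#'   one decimal).
#' @export
#' @examples
#' sh <- shares(load_reference_burden())
#' subset(sh, outcome == "deaths" & scenario_id == "BAU")
shares <- function(burden, grouping = default_grouping()) {
  ids <- unlist(grouping, use.names = FALSE)
  if (!setequal(ids, disease_ids()) || anyDuplicated(ids) > 0) {
    stop("grouping must partition the 11-disease registry", call. = FALSE)
  }
  burden <- burden[burden$disease_id %in% disease_ids(), , drop = FALSE]
  check_complete_diseases(burden)
  by_disease <- dplyr::summarise(
    burden,
    value = sum(.data$value),
    .by = c("outcome", "scenario_id", "disease_id")
  )
  lookup <- setNames(
    rep(names(grouping), lengths(grouping)),
    unlist(grouping, use.names = FALSE)
  )
  by_disease$group <- lookup[by_disease$disease_id]
  grouped <- dplyr::summarise(
    by_disease,
    value = sum(.data$value),
    .by = c("outcome", "scenario_id", "group")
  )
  grouped |>
    dplyr::mutate(
      share = round(100 * .data$value / sum(.data$value), 1),
      .by = c("outcome", "scenario_id")
    ) |>
    dplyr::select("outcome", "scenario_id", "group", "share") |>
    dplyr::arrange(.data$outcome, .data$scenario_id, .data$group)
}

#' Per-year burden trends by scenario
#'
#' Totals the burden over diseases per year and scenario and adds the
#' cumulative series, the analogue of the published trend figure.
#'
#' @param burden Burden tibble with a `year` column.
#' @return Tibble `outcome`, `scenario_id`, `year`, `value` (annual
#'   total), `cumulative`.
#' @export
trend_series <- function(burden) {
  if (!"year" %in% names(burden)) {
    stop("trend_series needs a yearly burden table", call. = FALSE)
  }
  burden <- burden[burden$disease_id %in% disease_ids(), , drop = FALSE]
  dplyr::summarise(
    burden,
    value = sum(.data$value),
    .by = c("outcome", "scenario_id", "year")
  ) |>
    dplyr::arrange(.data$outcome, .data$scenario_id, .data$year) |>
    dplyr::mutate(
      cumulative = cumsum(.data$value),
      .by = c("outcome", "scenario_id")
    )
}

#' Plot attributable-burden trends
#'
#' Cumulative attributable cases and deaths per scenario over the
#' horizon, one panel per outcome.
#'
#' @param trends Output of [trend_series()].
#' @return A ggplot object.
#' @export
plot_trends <- function(trends) {
  ggplot2::ggplot(
    trends,
    ggplot2::aes(
      x = .data$year, y = .data$cumulative, colour = .data$scenario_id
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "Cumulative attributable burden (persons)",
      colour = "Scenario"
    ) +
    ggplot2::theme_minimal()
}

#' Verify the arithmetic identities of the published results fixture
#'
#' Recomputes, from the shipped fixture, every headline identity of the
#' published tables: scenario totals from the column sums, cancer
#' subtotals from the five cancers, averted totals as BAU minus
#' scenario, and the death shares of the cardiovascular and diabetes
#' groups.
#'
#' @return Tibble `check`, `expected`, `computed`, `pass`.
#' @export
#' @examples
#' verify_reference_tables()
verify_reference_tables <- function() {
  ref <- load_reference_burden()
  tot <- aggregate_totals(ref)
  av <- averted(ref)
  sh <- shares(ref)
  printed_cancer <- ref[ref$disease_id == "total_cancer", ]

  pick_tot <- function(outcome, scen, measure) {
    tot$value[tot$outcome == outcome & tot$scenario_id == scen &
      tot$measure == measure]
  }
  pick_av <- function(outcome, scen, id) {
    av$averted[av$outcome == outcome & av$scenario_id == scen &
      av$disease_id == id]
  }
  rows <- list(
    c("cases total BAU", 669100, pick_tot("cases", "BAU", "TOTAL")),
    c("cases total S1", 661975, pick_tot("cases", "S1", "TOTAL")),
    c("cases total S2", 659010, pick_tot("cases", "S2", "TOTAL")),
    c("cases total S3", 644135, pick_tot("cases", "S3", "TOTAL")),
    c("deaths total BAU", 117348, pick_tot("deaths", "BAU", "TOTAL")),
    c("deaths total S1", 115897, pick_tot("deaths", "S1", "TOTAL")),
    c("deaths total S2", 115279, pick_tot("deaths", "S2", "TOTAL")),
    c("deaths total S3", 112275, pick_tot("deaths", "S3", "TOTAL")),
    c("averted cases S2", 10090, pick_av("cases", "S2", "TOTAL")),
    c("averted cases S3", 24965, pick_av("cases", "S3", "TOTAL")),
    c("averted deaths S1", 1451, pick_av("deaths", "S1", "TOTAL")),
    c("averted deaths S2", 2069, pick_av("deaths", "S2", "TOTAL")),
    c("averted deaths S3", 5073, pick_av("deaths", "S3", "TOTAL")),
    c(
      "cardiovascular share of BAU deaths", 58.5,
      sh$share[sh$outcome == "deaths" & sh$scenario_id == "BAU" &
        sh$group == "cardiovascular"]
    ),
    c(
      "diabetes share of BAU deaths", 18.6,
      sh$share[sh$outcome == "deaths" & sh$scenario_id == "BAU" &
        sh$group == "type 2 diabetes"]
    )
  )
  for (scen in c("BAU", "S1", "S2", "S3")) {
    for (oc in c("cases", "deaths")) {
      rows[[length(rows) + 1]] <- c(
        paste("cancer subtotal", oc, scen),
        printed_cancer$value[printed_cancer$outcome == oc &
          printed_cancer$scenario_id == scen],
        pick_tot(oc, scen, "TOTAL_CANCER")
      )
    }
  }
  out <- tibble::tibble(
    check = vapply(rows, function(r) r[1], character(1)),
    expected = as.numeric(vapply(rows, function(r) r[2], character(1))),
    computed = as.numeric(vapply(rows, function(r) r[3], character(1)))
  )
  out$pass <- out$expected == out$computed
  out
}
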