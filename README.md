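# pmslt

Proportional multistate life table (MSLT) projections of the
non-communicable disease (NCD) burden attributable to overweight in
Chilean adults, 2019–2030, under counterfactual body-mass-index (BMI)
scenarios.

## What it does

Eleven BMI-related diseases — coronary heart disease, stroke,
hypertensive heart disease, type 2 diabetes, chronic kidney disease,
cirrhosis, and colorectal, kidney, liver, breast and pancreatic cancer —
are each simulated as an illness–death life table (healthy → diseased →
dead-from-disease / dead-other) running alongside a central cohort life
table for adults aged 20–80. A scenario's year-by-year BMI distribution
is coupled to disease inflow through the potential impact fraction

    PIF = (Σ P_ref(x)·RR(x) − Σ P_cf(x)·RR(x)) / Σ P_ref(x)·RR(x)

whose complement multiplies incidence, with exposure-to-incidence lags
of 5 years (non-cancers) and 10 years (cancers). Burden attributable to
overweight is the run's difference against a reference held at the
theoretical minimum-risk exposure level of 22 kg/m². Four canonical
scenarios are built in: business as usual (mean BMI +0.4 %/yr), halved
growth (+0.2 %/yr), overweight prevalence held, and prevalence reduced
6.7 % by 2030. Monte Carlo machinery propagates relative-risk and
baseline-BMI uncertainty into percentile 95 % uncertainty intervals.

Because none of the underlying survey, registry or disease-rate data are
redistributable, the package ships (a) a deterministic synthetic
generator that emulates the study population with self-consistent rates
(anchored to the published BMI statistics: male mean 28.1 kg/m², female
29.4 kg/m², overweight prevalence 75.7 %), and (b) the published
relative-risk inputs and projection results as plain-text fixtures,
which the reporting layer reproduces exactly.

## Worked example

```r
library(pmslt)

inputs    <- generate_synthetic_inputs(synthetic_params())
scenarios <- build_canonical_scenarios(inputs$config, inputs$bmi_baseline)
burden    <- project_burden(inputs, scenarios)
subset(aggregate_totals(burden), measure == "TOTAL")
#>   outcome scenario_id measure  value
#> 1 cases   BAU         TOTAL   11782.
#> 2 cases   S1          TOTAL   11630.
#> 3 cases   S2          TOTAL   11481.
#> 4 cases   S3          TOTAL   11277.
#> 5 deaths  BAU         TOTAL    3364.
#> 6 deaths  S1          TOTAL    3336.
#> 7 deaths  S2          TOTAL    3308.
#> 8 deaths  S3          TOTAL    3269.
```

These are attributable cases and deaths summed over 2020–2030 for the
default synthetic cohort of 200 000 adults: scenarios are ordered
BAU > S1 > S2 > S3, with the halved-growth scenario closest to BAU and
the prevalence-reduction scenario averting the most (~504 cases, ~95
deaths vs BAU here). Magnitudes are properties of the synthetic rates,
not national estimates. The published scenario tables are available as a
fixture and verified cell-by-cell:

```r
all(verify_reference_tables()$pass)
#> [1] TRUE
averted(load_reference_burden()) |>
  subset(disease_id == "TOTAL" & scenario_id == "S3")
#>   outcome scenario_id disease_id averted
#> 1 cases   S3          TOTAL        24965
#> 2 deaths  S3          TOTAL         5073
```

Uncertainty intervals:

```r
mc <- run_monte_carlo(inputs, draw_spec(n_draws = 200, seed = 1))
head(mc$averted, 3)
```

See `vignettes/overweight-burden-projection.Rmd` for the model,
assumptions and design decisions.

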