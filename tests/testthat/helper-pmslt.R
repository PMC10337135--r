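# Shared fixtures, memoized so expensive model runs happen once per session.
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

default_inputs <- function() {
  memo("inputs", generate_synthetic_inputs(synthetic_params()))
}

default_scenarios <- function() {
  inputs <- default_inputs()
  memo("scenarios", build_canonical_scenarios(inputs$config, inputs$bmi_baseline))
}

default_burden <- function() {
  memo("burden", project_burden(default_inputs(), default_scenarios()))
}

bau_run <- function() {
  memo("bau_run", run_mslt(default_inputs(), default_scenarios()$BAU))
}

# A small bundle (few cohorts) for tests that only exercise mechanics.
tiny_inputs <- function(ages = 40:45) {
  memo(paste0("tiny", min(ages), max(ages)), {
    full <- default_inputs()
    mslt_inputs(
      population = full$population[full$population$age %in% ages, ],
      bmi_baseline = full$bmi_baseline[full$bmi_baseline$age %in% ages, ],
      disease_epi = full$disease_epi[full$disease_epi$age %in% ages, ],
      rr_spec = full$rr_spec,
      config = full$config
    )
  })
}

# Independent spreadsheet-style bookkeeping for a single cohort's disease
# life table: scalar rates, explicit per-year loop, written directly from
# the cycle definition (rate -> probability, incidence -> remission ->
# case fatality -> other-cause death).
oracle_lifetable <- function(i, r, f, m, mult, S0, C0, cycles) {
  S <- S0; C <- C0; Dd <- 0; Do <- 0
  cases <- numeric(cycles)
  deaths <- numeric(cycles)
  S_path <- numeric(cycles + 1); C_path <- numeric(cycles + 1)
  S_path[1] <- S; C_path[1] <- C
  mult <- rep_len(mult, cycles)
  for (t in seq_len(cycles)) {
    new <- S * (1 - exp(-i * mult[t]))
    S <- S - new; C <- C + new
    rem <- C * (1 - exp(-r))
    C <- C - rem; S <- S + rem
    dd <- C * (1 - exp(-f))
    C <- C - dd; Dd <- Dd + dd
    do_s <- S * (1 - exp(-m)); do_c <- C * (1 - exp(-m))
    S <- S - do_s; C <- C - do_c; Do <- Do + do_s + do_c
    cases[t] <- new; deaths[t] <- dd
    S_path[t + 1] <- S; C_path[t + 1] <- C
  }
  list(
    cases = cases, deaths = deaths, S = S_path, C = C_path,
    dead_disease = Dd, dead_other = Do
  )
}
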