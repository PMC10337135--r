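---
title: "Projecting overweight-attributable NCD burden with a proportional multistate life table"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting overweight-attributable NCD burden with a proportional multistate life table}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmslt)
library(dplyr)
```

## The model

`pmslt` projects the incidence and mortality of eleven non-communicable
diseases (NCDs) attributable to overweight in a closed cohort of adults
aged 20–80, simulated annually from 2019 to 2030 under counterfactual
body-mass-index (BMI) scenarios. The machinery is a *proportional
multistate life table* (MSLT): a central cohort life table runs alongside
eleven disease-specific life tables, each an illness–death model with four
states — healthy, diseased, dead from the disease, dead from other causes
— advanced by per-stratum rates of incidence $i$, remission $r$ (cancers
only), case fatality $f$ and other-cause mortality $m$.

Exposure enters through the *potential impact fraction* (PIF). For a
relative-risk curve $RR(x)$ over BMI $x$ and reference/counterfactual
exposure densities $P_{ref}, P_{cf}$,

$$\mathrm{PIF} \;=\; \frac{\sum_x P_{ref}(x)\,RR(x) \;-\; \sum_x P_{cf}(x)\,RR(x)}
{\sum_x P_{ref}(x)\,RR(x)},$$

and $1-\mathrm{PIF}$ multiplies the inflow (incidence) of the matching
disease life table. Each simulated year's BMI distribution is compared
against the frozen 2019 baseline, so the business-as-usual (BAU)
trajectory itself carries multipliers above 1: rising BMI raises
incidence. Burden *attributable to overweight* is the difference between
a trajectory's run and a reference run in which every stratum is held at
the theoretical minimum-risk exposure level (TMREL) of 22 kg/m².

### Annual cycle and event ordering

Rates are person-year rates; each annual cycle converts them to
probabilities with $q = 1 - e^{-\text{rate}}$ (standard life-table
practice, which also guarantees $q \in [0,1]$). Within a cycle, events
fire in a fixed order: incidence (scaled by the lagged multiplier), then
remission back to the healthy state, then case fatality, then other-cause
death applied to both the healthy and the diseased. The ordering of a
discrete-cycle MSLT is a genuine modelling choice — published
spreadsheet implementations do not document a canonical order — so we
fixed the simplest sequence and verify conservation of cohort mass at
every stratum-year to $10^{-9}$ relative. Other-cause mortality is
cause-deleted per table ($m - p\,f$ for that disease's background
prevalence and case fatality, floored at 0), which avoids double-counting
disease deaths; the central life table deletes all eleven and adds back
the simulated prevalence-weighted case fatality, so scenario-driven
changes in disease occurrence feed back into overall survival.

Cohorts are closed: the population aged 20–80 in 2019 is simulated with
no new entrants. Attained ages beyond 80 reuse the age-80 rates
(constant extrapolation); relative-risk age bands extend to 89 and are
clamped beyond. Incident cases are labelled by cycle *end* year, so an
11-cycle horizon reports case years 2020–2030.

### Lags and the TMREL reference

Changes in BMI affect incidence after a lag: 5 years for coronary heart
disease, stroke, hypertensive heart disease, type 2 diabetes, chronic
kidney disease and cirrhosis; 10 years for the five cancers. The
multiplier series of a scenario run is shifted by the lag with neutral
(1) values in the pre-lag head, so scenario-vs-BAU contrasts are exactly
zero until the shortest lag completes — the first divergence lands in
the 2024→2025 cycle, and cancers diverge only in the final cycle.

The TMREL reference run is *not* lagged: the counterfactual imagines
exposure held at 22 kg/m² since the distant past, so attributable burden
accrues from the first cycle. The asymmetry is deliberate and is what
produces the published pattern of attributable cases growing in every
scenario until the lags complete, then fanning out by scenario.

## Scenarios

Four canonical trajectories are built from the baseline BMI
distributions, all coinciding with the baseline in 2019:

* **BAU** — mean BMI grows 0.4 %/yr, the 2003–2017 trend continued,
  geometric in the mean with fixed standard deviation.
* **Scenario 1** — growth halved, 0.2 %/yr.
* **Scenario 2** — overweight prevalence ($P(\mathrm{BMI} \ge 25)$) held.
  The published description anchors the hold at the national average of
  76.9 %; because every scenario must coincide with the 2019 baseline at
  the start, the hold freezes *each stratum's own* baseline prevalence,
  which makes Scenario 2 the frozen-baseline trajectory and keeps the
  configured anchor purely descriptive.
* **Scenario 3** — overweight prevalence reduced linearly by 0.61 % of
  the baseline value per year, reaching a 6.7 % relative reduction by
  2030.

Prevalence mechanisms move the whole distribution by a mean shift with
fixed standard deviation; for a normal stratum the shifted mean has the
closed form $25 + \sigma\,\Phi^{-1}(\text{target})$, so the inverse
relation (shift then evaluate prevalence) is exact. Truncating or
reshaping the distribution would be alternative mechanisms; the mean
shift is the simplest one-parameter choice consistent with a
population-wide intervention and is isolated behind
`prevalence_to_mean_shift()` should a different mechanism be wanted.
Growth applies uniformly across age and sex strata, as no
stratum-specific trend rates are published.

## Relative risks

The shipped `rr_spec.csv` carries the published per-5 kg/m² relative
risks with 95 % CIs — age-banded for coronary heart disease and stroke,
sex-specific for colorectal and kidney cancer, restricted applicability
windows for liver cancer (35–79 years) and breast cancer (women above
60) — and categorical BMI-band risks for hypertensive heart disease,
type 2 diabetes, chronic kidney disease and cirrhosis. Log-linear curves
evaluate $RR_{band}^{(x - 22)/5}$ and are floored at 1 below the TMREL:
risk reversal under low BMI is deliberately not modelled, which also
keeps attributable burden non-negative. Categorical bands are used as
printed, including sub-unity low-BMI values. Ages 20–34 reuse the
youngest printed band for the fully-covered diseases; outside a
restricted applicability window the RR is 1.

PIF integrals discretize BMI on a midpoint grid from 10 to 60 kg/m² at
0.1 steps, truncating and renormalizing tail mass. The grid step is
convergence-checked in the test suite (halving the step moves the PIF by
less than $10^{-4}$ for realistic spreads); point masses (degenerate
distributions, used by the TMREL reference) are evaluated exactly off
the grid.

## The synthetic population

No survey microdata, demographic registers or disease-rate tables ship
with the package, so a synthetic generator emulates the study
population; all tests and examples run on it.

* **Population**: both sexes, single-year ages 20–80, 100 000 per sex by
  default with a gently declining age pyramid, and Gompertz all-cause
  mortality (exponential in age; ~5×10⁻⁴ at age 20 rising to ~7 % at 80
  for men, lower for women).
* **BMI**: normal per stratum. The published anchors are the sex means
  (28.1 kg/m² men, 29.4 kg/m² women) and the overweight prevalence
  (75.7 %); the per-stratum standard deviation is *solved* from the
  prevalence anchor, since two anchors exactly identify the
  two-parameter normal family. The published dispersion intervals are
  treated as population spread, not standard errors of the mean — they
  are far too wide for a national survey mean. A mild linear age
  gradient (±0.5 kg/m² across the age range) keeps the
  population-weighted mean at the anchor.
* **Disease rates**: exponentially age-increasing incidence and case
  fatality with order-of-magnitude-plausible bases, remission 0.1/yr for
  the cancers only. Prevalence is set to the illness-death steady state
  implied by $(i, r, f)$ — the equilibrium of
  $\dot p = i(1-p) - (r+f)p + f p^2$, in which all-cause mortality
  cancels — so the bundle passes `validate_epi_consistency()` by
  construction.

The generator is deterministic given its parameters. What passing tests
on this bundle show is that the *machinery* is correct — conservation,
lag onsets, scenario ordering, PIF arithmetic; they deliberately do not
show that burden magnitudes match any national estimate, because the
disease rates are not calibrated to one. The published totals are
instead shipped as a results fixture and verified exactly by the
reporting layer.

## Uncertainty

`run_monte_carlo()` propagates parameter uncertainty by re-evaluating
the full pipeline per draw (1 000 draws by default; percentile 2.5/97.5
intervals). Sampled inputs are the relative risks — lognormal with
median at the point estimate and log-sd recovered from the printed CI,
one shared deviate per disease across its bands, since the bands come
from a single meta-analysis and independence would understate
uncertainty — and the baseline mean BMI per sex (normal, sd 0.2 kg/m²;
no standard error is published for the survey means, so this is a
documented choice of survey-scale precision). Disease rates are held
fixed: their source uncertainty is not published in usable form, a known
limitation. Scenarios are rebuilt from each draw's perturbed baseline,
and draws are shared across scenarios, so averted burden intervals come
from paired per-draw differences. The point estimate uses central
parameters; percentile intervals of skewed outputs need not bracket it.

## Worked example

```{r, eval = FALSE}
inputs <- generate_synthetic_inputs(synthetic_params())
scenarios <- build_canonical_scenarios(inputs$config, inputs$bmi_baseline)
burden <- project_burden(inputs, scenarios)

totals <- aggregate_totals(burden)
subset(totals, measure == "TOTAL")
trends <- trend_series(subset(burden, outcome == "cases"))
plot_trends(trends)

mc <- run_monte_carlo(inputs, draw_spec(n_draws = 200, seed = 1))
head(mc$averted)
```

On the default bundle the four scenarios produce identical attributable
cases through 2024; the non-cancer lags complete in the 2024→2025 cycle
and the trajectories fan out with BAU highest, Scenario 1 closest to
BAU and Scenario 3 lowest — the published qualitative pattern.

The published tables themselves are reproduced through the fixture:

```{r}
checks <- verify_reference_tables()
all(checks$pass)
head(checks, 8)
```

## Numerical and design notes

* Two cells of the published cases table are typographically corrupt;
  they are repaired in the fixture as forced by the column-sum
  identities (cirrhosis/BAU 14 630 against the printed total 669 100;
  stroke/Scenario 2 78 493 against 659 010) and documented in the file
  header. Two unparseable CI bounds are stored as `NA`.
* A separately published period figure of ~2.6 million new cases is
  irreconcilable with the printed 669 100 total; the fixture stores only
  table-backed values.
* The printed percentage increases of mean BMI (4.2 % men) disagree
  slightly with the printed means themselves ((28.1−26.9)/26.9 =
  4.46 %); the generator anchors the means.
* The 10 090-case figure reported as the period total equals BAU minus
  Scenario 2 (669 100 − 659 010); the reporting layer exposes it as the
  Scenario-2 averted total.
* Whether "cases averted" counts incident cases or prevalence-years is
  not stated; incident cases are used, matching "new incident cases …
  averted or delayed".
* Problem sizes used in the shipped tests: the default synthetic bundle
  (122 strata × 11 diseases × 11 cycles) for all end-to-end checks, and
  200 Monte Carlo draws for the reproducibility check of the
  uncertainty intervals.

Out of scope by design: survey weighting, the rate-balancing
optimization of dedicated epidemiological consistency tools (replaced by
the steady-state screen above), open cohorts and age re-entry,
comorbidity interactions, life-expectancy/HALY outputs, and cost
analyses.
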