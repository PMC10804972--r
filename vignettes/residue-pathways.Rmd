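---
title: "Greenhouse-gas accounting for rice residue pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greenhouse-gas accounting for rice residue pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ricegas)
```

## The problem

In the rice-wheat systems of the Eastern Indo-Gangetic Plain, rice straw is
either burned in the field, incorporated into the soil, fed to bovine
livestock (with partial manure return), or carbonized to biochar. Each fate
changes the farm's net greenhouse-gas balance in a different way, and the
sign of the change depends strongly on field hydrology: flooded soils are
anaerobic and methanogenic, so the same residue input produces far more CH4
in a wet field than a dry one. `ricegas` implements the accounting needed to
compare the four pathways per hectare and year, in 100-year CO2-equivalent
terms, across dry, median and wet hydrologic categories.

Two kinds of fluxes are combined:

* **Soil fluxes** (CH4, N2O, change in soil organic carbon) come from a
  process-based, daily-time-step biogeochemical model that is *external* to
  this package. `ricegas` prepares the model's hydrologic inputs, parses its
  annual outputs, and aggregates them; it does not simulate soil
  biogeochemistry. A synthetic generator stands in for model output in tests.
* **Non-soil fluxes** are computed here with IPCC Tier 1/2 factor methods:
  open-burning combustion, enteric fermentation, manure storage, dung-fuelled
  cookstoves, and the carbon-permanence credits of biochar and of the
  pyrogenic carbon left by incomplete burning.

The functional unit is the residue produced by one hectare of rice at current
yield levels, held constant across years.

## Non-soil accounting

All constants live in a single validated registry:

```{r}
params <- load_params()
head(params_table(params), 8)
```

Every parameter can be overridden from a YAML/JSON file or a named list;
fractions are validated to `[0, 1]`, the stoichiometric ratios 44/12 and
44/28 are fixed, and each value carries its unit and provenance.

**Straw supply.** Fresh straw is grain yield times the production-to-straw
ratio (3.77 t/ha x 1.5 = 5.655 t/ha), converted to dry matter with the dry
matter fraction 0.86.

**Livestock fodder.** All straw is consumed by a representative regional
herd. Enteric CH4 is the herd-weighted conversion factor `Ym` (4.74% of
gross energy intake; see `weighted_ym()` for the weighting operation) applied
to the straw's gross energy and divided by methane's energy content.
Volatile-solid excretion follows the IPCC structure
`[GE(1-DE) + UE*GE] * (1-ASH)/18.45`. Manure is stored daily before either
end use, so storage CH4 (`VS * Bo * 0.67 * MCF`) and storage N2O
(`Nf * VS * EFn * 44/28`) apply to the full VS. Half the VS is returned to
the field five days before the rice season (its soil consequences belong to
the soil model, via the amendment schedule); the other half fuels cookstoves,
with Tier 1 per-TJ emission factors. The storage N2O emission factor is the
one constant whose source value is ambiguous in the literature chain behind
these defaults; the solid-storage class default 0.01 kg N2O-N/kg N is used
and is config-overridable.

```{r}
livestock_pathway(params)
```

**Biochar.** The carbon yield of pyrolysis is an empirical regression in
lignin fraction and temperature, `0.126 + 0.273*Lf + 0.539*exp(-0.004*T)`,
evaluated at 525 °C (medium-temperature pyrolysis, 450-600 °C). The biochar
carbon reaching the soil earns a credit for the fraction (0.71, SE 0.03)
still present after 100 years, converted by 44/12. The N2O-avoidance term of
the original credit formulation is omitted (negligible below 10 Mg C/ha
application), as is any CH4 suppression in soil (not established to persist).
The pyrolysis step itself is assumed clean; process energy, transport and
economics are out of scope.

```{r}
biochar_pathway(params)
```

**Burning.** All residue is assumed burned at efficiency 0.89; CH4 and N2O
use country-specific per-kg emission factors; combustion CO2 is biogenic and
not counted. The 11% of carbon left as pyrogenic char, discounted by the
fraction remaining on site (0.9895), earns the same permanence credit as
biochar carbon.

```{r}
burning_pathway(params)
```

Note a documented discrepancy: the published scenario summary lists the
burning pathway's non-soil flux as 0.4 Mg CO2-e, but the published equations
and emission factors give ~1.73 Mg combustion minus ~0.27 Mg char credit,
about 1.45 Mg net. The package follows the equations; the published 0.4 is
retained only inside `published_scenario_values()` so that published totals
can be reproduced and compared.

## Field hydrology

Daily water levels are measured in perforated field tubes over the rice
season (Julian days 183-302), positive above the soil surface and negative
below, with the tube bottom at -15 cm. Days partition into three states:
*flooded* (ponded water), *saturated* (no ponding, free water within the top
15 cm) and *drained* (deeper). A level of exactly 0 is classified saturated;
because field conventions differ, the boundary is a `classify_day()` option.

Representative fields per climate year are chosen from the flooded-day
distribution: the field at the sample median represents the median category;
dry and wet representatives are drawn uniformly (seeded) from the fields at
least one sample (n-1) standard deviation below and above the mean. Where the
published procedure is silent, the package fixes: median ties resolve to the
count closest to the median, then lexicographic field id; the SD multiplier
is configurable; the median field is excluded from the dry/wet candidate sets
so the three representatives are distinct.

`build_water_input()` then assembles an `n`-year schedule by sampling one
source climate year per simulation year with equal probability, copying its
rice-season record verbatim, and filling the wheat season with -100 cm except
Julian days 22, 340 and 352, which are 0 cm (typical irrigation events). A
fixed 365-day calendar is used; leap days are dropped on ingest, matching the
daily-model convention. `write_water_table_files()` emits one two-column
`julian_day level` file per year plus a JSON manifest with the seed and
source-year mapping (cm by default, metres optional, since model versions
differ in their expected dialect).

```{r}
fields <- gen_water_levels(n_fields = 20, climate_wetness = 0.5, seed = 1)
assign_categories(lapply(fields, summarize_field), seed = 1)
```

## Aggregating soil fluxes

Annual model output (or synthetic stand-ins) is read into a
`soil_flux_series` (kg CH4, kg N2O, signed kg C change in SOC per year;
contiguous years; element-mass outputs are converted by 16/12 and 44/28).
`season_average_soil_co2e()` reports arithmetic means over the horizon and
the net soil flux

> net = mean CH4 x GWP_CH4 + mean N2O x GWP_N2O - mean dSOC x 44/12,

with GWP100 values 27.9 and 273. The published summary does not state how
the SOC term was annualized; the mean annual stock change over the horizon is
used here, with `include_soc = FALSE` available for sensitivity. When a SOC
*stock* column is supplied it is first-differenced; the first year's change
is zero unless an initial stock is given. The default horizon is 100 years
(the permanence horizon); shorter horizons reproduce interannual views.

`residue_effect_stats()` contrasts a with-residue series against its
no-residue baseline (absolute difference, percent, ratio), guarding the
zero-baseline case with an `undefined` flag instead of an error.

## The scenario table

`build_scenario_table()` combines per-pathway/per-category soil fluxes with
per-pathway non-soil fluxes into total direct fluxes. Credits enter as
negative non-soil values so every total is exactly soil + non-soil;
incorporation has no non-soil term. Stored values are never rounded; display
rounding is half-away-from-zero to one decimal, matching tabulated
convention. `compare_to_reference()` differences unrounded totals against a
baseline pathway (burning, conventionally).

```{r}
pub <- published_scenario_values()
nonsoil <- c(livestock = livestock_pathway(params)$total_co2e_Mg,
             biochar   = biochar_pathway(params)$nonsoil_MgCO2e,
             burning   = burning_pathway(params)$net_nonsoil_MgCO2e)
build_scenario_table(pub$soil, nonsoil)
```

## The synthetic generator

The generator exists so that every pipeline stage is testable without field
data or the external model. Its defaults are fixed study conditions, not
tuning knobs.

* **Hydrographs** (`gen_water_levels()`): each field's daily level is an
  AR(1) process (persistence 0.8, marginal SD 10 cm, clipped to
  [-100, +30] cm). A field's long-run flooded propensity is drawn on the
  logit scale around the cohort wetness with spread 1.0, which reproduces the
  observed situation of nearby fields ranging from almost always drained to
  almost always flooded. At persistence 1 the process degenerates to a frozen
  walk, giving the constant-series edge case exactly.
* **Flux series** (`gen_soil_flux_series()`): annual CH4 is lognormal with
  category means {dry 0.08, median 0.22, wet 0.31} Mg/ha without residue
  return and increments {+0.03, +0.10, +0.14} Mg with it — the published
  category means and residue effects. The interannual CV defaults to 0.3, a
  fixture choice (the published interannual spread is shown graphically, not
  numerically). N2O is lognormal with mean 0.015 kg/ha/yr (the middle of the
  simulated range reported alongside the study); the SOC change is normal,
  since it is signed, with mean 0 (no residue) or +50 kg C/ha/yr (residue
  return) — a deliberately small mean annual gain, consistent with stock
  gains that diminish over a century. Gases are drawn independently; no
  CH4-N2O correlation is imposed.

What passing tests show, and what they do not: the generator reproduces the
*summary statistics* the analysis consumes (category means, residue
contrasts, cross-field wetness spread, seeded reproducibility). It does not
emulate weather-driven autocorrelation between years, CH4-N2O covariance, or
any mechanistic response of fluxes to the hydrographs, so agreement here
says nothing about the external model's biogeochemical skill on real fields.

## Calibration harness

`calibration_search()` generalizes the manual protocol used to calibrate the
crop model (grain biomass carbon stepped until simulated yield is within 10%
of the observed maximum; thermal degree days stepped until maturity matches
harvest): a parameter is stepped — multiplicatively by 1.1 per iteration by
default, the step rule and size being configurable — until a black-box
simulator's observable falls within a relative tolerance (default 0.10) of
the target. The direction is inferred from the first two evaluations unless
hinted; every evaluation is recorded in a trace; progress reversing twice
flags a possibly non-monotone response; exhausting the iteration cap raises
an error that carries the trace.

## Numerical choices and degenerate inputs

* Fractions are validated to `[0, 1]`; GWPs must exceed 1; 44/12 and 44/28
  are fixed ratios, not free parameters.
* `assign_categories()` refuses cohorts with fewer than 3 fields, identical
  counts (no spread, categories undefined), or an empty dry/wet candidate
  set (the error suggests relaxing the SD multiplier).
* All randomness is confined to explicit `seed` arguments; generators save
  and restore the caller's RNG state.
* Zero baselines in `residue_effect_stats()` flag the percent/ratio as
  undefined rather than erroring; zero-mass amendment schedules serialize as
  header-only files.
* Scenario tables serialize to JSON at 17 significant digits, so regenerated
  reports are bit-identical.

## Problem sizes

The shipped tests and the results script run at the study's own scales where
that is cheap (100-year horizons, 100-year water schedules, cohorts of 20-50
fields) and at reduced scale where only the property matters (e.g. 200
random cohorts for the selection-procedure cross-check, 40 randomized
calibration cases). All are seeded and complete in seconds.

## Limitations

* Soil biogeochemistry is external: published soil fluxes are inputs, and
  nothing here validates them against chamber measurements.
* No uncertainty propagation: the permanence fraction's SE is recorded as
  provenance only; outputs are point estimates.
* The herd model is static; no feed substitution, herd dynamics, LPG
  transition, or economics.
* The published burning non-soil value cannot be reconciled with the
  published equations (see above); totals built from computed non-soil values
  therefore differ for that pathway.
* Air-quality impacts (PM2.5, black carbon) are outside the accounting
  boundary.
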