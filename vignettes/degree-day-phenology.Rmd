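---
title: "Linear degree-day phenology for Spodoptera frugiperda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear degree-day phenology for Spodoptera frugiperda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodd)
```

## The model

Within a favourable temperature range, insect development rate is
approximately linear in temperature. Writing the rate as the reciprocal of
the stage duration, $y = 1/\text{days}$, the model is

$$y = a\,T + b,$$

with slope $a$ (1/(day·°C)) and intercept $b$ (1/day). Two biologically
meaningful quantities fall out of the fitted line:

* the **lower temperature threshold** (LTT), the temperature where the rate
  extrapolates to zero, $\mathrm{LTT} = -b/a$; and
* the **thermal requirement** (TRD), the degree-days that must accumulate
  for the stage to complete; in the ideal linear model $\mathrm{TRD} = 1/a$.

Degree-days are accumulated as
$\mathrm{DD} = \max\{0, (T_{\min}+T_{\max})/2 - \mathrm{LTT}\}$ per day,
which reduces to $T - \mathrm{LTT}$ under constant rearing temperature.
Emergence is forecast on the first day the running sum reaches the thermal
requirement.

The package ships reference tables for the Korean fall armyworm
(*Spodoptera frugiperda*) population — stage durations at six constant
temperatures, fitted rate lines, feeding amounts, viability percentages and
field eclosion records (`sf_development_times()`, `sf_rate_lines()`,
`sf_feeding_amounts()`, `sf_viability_summary()`,
`sf_observed_eclosion()`) — which double as the defaults of the synthetic
generator.

## Fitting rate lines

```{r fit}
means <- sf_development_times()
means <- means[means$temperature %in% c(20, 24, 28, 32), ]
egg <- data.frame(individual_id = 1:4, stage = "egg",
                  temperature = c(20, 24, 28, 32),
                  duration = means$mean_days[means$stage == "egg" &
                                             means$temperature %in% c(20, 24, 28, 32)])
fit_stage_model(egg, "egg", fit_level = "group_mean")
```

Two fit levels are exposed because rearing studies report only group means
while the raw data are individuals. `fit_level = "individual"` regresses
every individual's rate on temperature and is the default with raw data;
`fit_level = "group_mean"` fits the per-temperature mean rates (one point
per temperature) and is the level at which published coefficient tables are
reproducible. For balanced designs (equal numbers per temperature) the two
coincide exactly, since the OLS line through the group means of the rates
equals the line through the individuals.

The default fitting window is 20–32 °C. Rearing at 16 and 36 °C suffers
heavy mortality (31.0 % and 45.3 % larval survival) and development there
departs from linearity, so those temperatures are excluded from fitting by
default; the window is an argument, not hard-coded. Group means are not
weighted by survivor counts.

The thermal requirement is estimated by **per-temperature degree-day
averaging**: each individual contributes
$\mathrm{DD} = \text{duration} \times (T - \mathrm{LTT})$, the values are
averaged within each rearing temperature, and the reported TRD is the mean
(± SD) of the per-temperature group means — one value per temperature, so
the dispersion reflects between-temperature consistency of the thermal sum.
The SD across individuals is reported separately (`trd_individual_sd`) when
individual data are supplied, since the two dispersions answer different
questions. Fit quality is reported as $R^2$ only.

## Forecasting emergence

```{r forecast}
ltt <- lower_threshold(0.0034, -0.0490)   # egg-to-adult line
tot <- data.frame(individual_id = 1:4, stage = "egg_to_adult",
                  temperature = c(20, 24, 28, 32),
                  duration = c(49.6, 29.5, 21.9, 16.1))
trd <- thermal_requirement(tot, "egg_to_adult", ltt)$trd_mean
s <- temperature_series(seq(as.Date("2021-06-01"), by = 1, length.out = 60),
                        t_min = 24)
forecast_emergence(s, "2021-06-01", ltt, trd)
```

Accumulation is at whole-day granularity with ceiling semantics: emergence
falls on the day the sum first reaches the requirement, never interpolated
within a day, because both the rearing observations (24-h cadence) and the
field validations are reported in whole days. Sub-threshold days contribute
zero (never negative) heat. `forecast_stagewise()` chains per-stage
forecasts, each stage starting the day after the previous completes;
residual degree-days within a stage's final day are discarded, a
conservative bias of at most one day per stage boundary.
`forecast_deviation()` scores predictions against observed dates with the
convention that positive deviations mean the observation came later than
the forecast. `backcast_oviposition()` runs the accumulation backwards from
a peak-catch date to place the egg-laying window of a migrant population.
Hourly integration methods (single-sine, double-triangle) are out of scope.

## Feeding and viability

Leaf consumption is corrected for evaporation using paired untreated control
leaves:

$$\text{intake} = w_\text{before}\,
  \frac{c_\text{after}}{c_\text{before}} - w_\text{after},$$

the difference between what the leaf would have weighed from evaporation
alone and what it actually weighed. The correction is implemented from this
control-ratio intent (the two published limits hold: no evaporation reduces
it to the simple difference, no feeding gives zero). Five control leaves per
cell are reduced to one ratio by averaging the per-leaf ratios — each leaf
is an independent evaporation estimate. Values are rounded half-up at the
milligram, the balance's reporting precision. Slightly negative corrected
intakes arise from measurement noise in the first two instars (whose SD can
exceed the mean) and are retained, not clipped, to avoid inflating those
means; summaries flag them in `n_negative`. The per-temperature `total` row
is the mean of per-individual totals over individuals observed in all six
instars; with complete cohorts it equals the sum of the instar means up to
rounding. Daily intake divides mean intake by mean stage duration,
separating cumulative damage (largest under cold, slow rearing) from feeding
pressure per day (highest at 28–32 °C).

Viability endpoints (egg hatch; first-instar-to-adult survival) are
estimated as the mean of per-replicate percentages. With the triplicate
$n = 100$ design this equals the pooled percentage; with unequal exposure
the replicate mean is used, treating each replicate as the experimental
unit. Confidence intervals and dose-response curves are out of scope.

## The synthetic generator

`synth_config()` bundles the ground truth the generators draw from. Defaults
emulate the reference rearing design: 30 individuals per temperature at
20/24/28/32 °C, per-stage rate lines from the reference table, additive
Gaussian noise **on the day scale** (not the rate scale) with per-stage SDs
calibrated to the reference SDs at 24 °C (e.g. 0.7 d for eggs, 1.4 d for the
full period), durations rounded to the nearest whole day with a floor of one
day (the 24-h observation process), triplicate viability cohorts of 100, and
per-instar feeding means/SDs of reference magnitude. Hatch probabilities not
published per temperature (16, 20, 36 °C) default to 0.55–0.65, consistent
with the reported "above 50 %" behaviour outside the optimum. Leaf weights
default to 10 ± 1 g with a 5 % evaporation loss per weighing interval and
0.5 mg balance noise. Weather follows a sinusoidal seasonal mean
(`base + amplitude * sin(2*pi*t/period)`, period 365 d by default) with
day-to-day noise applied to the daily mean, so the max–min spread is exactly
the configured diurnal range. A single seed fans out to per-generator
substreams, so adding one generator never perturbs another's output.

```{r synth}
cfg <- synth_config(seed = 42)
obs <- gen_development(cfg)
fit_rate_models(obs, stages = c("egg", "larvae", "pupa"),
                fit_level = "group_mean")[, c("stage", "slope_4dp",
                                              "ltt_1dp", "trd_1dp")]
```

What the generator does *not* emulate: temperature-dependent mortality
censoring the slow individuals, within-cohort correlation between stages,
temperature-dependent noise SDs (the real SDs shrink at high temperature),
fecundity, and population dynamics. Passing recovery tests therefore show
that the estimators invert the assumed observation model, not that the
linear model is adequate for any particular field population.

## Numerical choices and limitations

* **Day-resolution artifact.** Rounding durations to whole days interacts
  with the convexity of $1/\text{duration}$: for long stages
  (egg-to-adult, ~17–53 d) the slope bias is under 5 %, but for short
  stages at warm temperatures (egg ≈ 2 d at 32 °C) rate means are inflated
  well beyond that. This is inherent to a 24-h observation cadence, and is
  why group-mean fits on tabulated mean durations — which average before
  inverting — are the reproducible route to published coefficients.
* **Threshold crossing.** The accumulator treats a requirement met exactly
  in real arithmetic as met (a `1e-9` degree-day tolerance absorbs binary
  representation error); likewise exact half-milligram weights round up.
* **Composite stages.** The `larvae` pseudo-stage sums the six instars per
  individual (individuals missing an instar are excluded); `egg_to_adult`
  rows are used directly when present, otherwise assembled as per-individual
  sums over egg–pupa.
* **Degenerate inputs** (a single temperature, zero temperature variance,
  zero slope, series too short to reach the requirement, temperatures at or
  below the threshold) raise located errors rather than returning NA.
* **Problem sizes.** Recovery properties are quantified at the reference
  scale (30 individuals × 4 temperatures) over 100 generator seeds, and the
  viability calibration over 500 seeds — sizes at which the checks are
  stable from run to run.
* Nonlinear rate models (Brière, Lactin, Sharpe–Schoolfield), upper-threshold
  estimation, and reproduction of the field forecasts themselves (the 2021
  logger series is unpublished; only the deviation scoring is reproducible)
  are out of scope.
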