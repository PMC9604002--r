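# Reference tables compiled from a published constant-temperature rearing
# study of the Korean fall armyworm (Spodoptera frugiperda) population:
# stage durations, fitted rate lines, feeding amounts, viability percentages
# and field eclosion records. These are the package's worked-example inputs
# and the defaults of the synthetic generator.

#' Reference stage durations (days, mean +/- SD) by rearing temperature
#'
#' Mean development time per life stage of *Spodoptera frugiperda* reared at
#' six constant temperatures (30 individuals per temperature, observed at 24-h
#' intervals). The `egg_to_adult` rows are the total development period.
#' Rearing at 16 and 36 C suffered heavy mortality and lies outside the
#' linear range; rate models are conventionally fitted on 20--32 C.
#'
#' @return Data frame with columns `stage`, `temperature`, `mean_days`,
#'   `sd_days`.
#' @export
sf_development_times <- function() {
  stages <- c("egg", paste0("L", 1:6), "pupa", "egg_to_adult")
  temps <- c(16, 20, 24, 28, 32, 36)
  mean_days <- c(
    10.1, 6.4, 4.1, 6.5, 6.5, 11.3, 16.7, 35.3, 97.2,  # 16 C
    7.1, 4.4, 2.2, 2.8, 3.4, 3.9, 6.8, 18.9, 49.6,     # 20 C
    4.3, 2.1, 1.8, 1.9, 2.0, 2.0, 3.8, 11.8, 29.5,     # 24 C
    3.2, 1.3, 1.3, 1.4, 1.6, 1.5, 3.1, 8.7, 21.9,      # 28 C
    2.0, 1.1, 1.1, 1.1, 1.1, 1.1, 2.5, 6.3, 16.1,      # 32 C
    2.0, 1.0, 1.0, 1.0, 1.3, 1.6, 2.4, 5.9, 15.5)      # 36 C
  sd_days <- c(
    0.7, 0.7, 0.6, 0.6, 0.5, 0.8, 0.7, 1.1, 1.2,
    0.2, 0.7, 0.4, 0.7, 0.5, 0.7, 0.5, 0.8, 1.2,
    0.7, 0.7, 0.4, 0.4, 0.4, 0.4, 0.9, 0.6, 1.4,
    0.5, 0.4, 0.5, 0.5, 0.6, 0.6, 0.4, 1.0, 1.7,
    0.3, 0.3, 0.2, 0.3, 0.2, 0.3, 0.5, 0.5, 1.1,
    0.2, 0.0, 0.0, 0.0, 0.7, 0.8, 0.6, 0.7, 0.7)
  data.frame(stage = rep(stages, times = length(temps)),
             temperature = rep(temps, each = length(stages)),
             mean_days = mean_days, sd_days = sd_days)
}

#' Reference linear rate lines, thresholds and thermal requirements
#'
#' Published regression coefficients of development rate (1/day) on rearing
#' temperature over 20--32 C for each stage, with the derived lower
#' temperature threshold (LTT, in degrees C) and the thermal requirement in
#' degree-days (TRD, mean +/- SD across the per-temperature degree-day
#' means). `larvae` is the composite first-to-sixth-instar period.
#'
#' @return Data frame with columns `stage`, `slope`, `intercept`,
#'   `r_squared`, `ltt`, `trd_mean`, `trd_sd`.
#' @export
sf_rate_lines <- function() {
  data.frame(
    stage = c("egg", paste0("L", 1:6), "larvae", "pupa", "egg_to_adult"),
    slope = c(0.0289, 0.0590, 0.0428, 0.0466, 0.0531, 0.0533, 0.0211,
              0.0070, 0.0088, 0.0034),
    intercept = c(-0.4536, -0.9278, -0.4282, -0.5761, -0.7823, -0.8039,
                  -0.2637, -0.0964, -0.1256, -0.0490),
    r_squared = c(0.9626, 0.9686, 0.9915, 0.9989, 0.9782, 0.9947, 0.9838,
                  0.9977, 0.9909, 0.9958),
    ltt = c(15.7, 15.7, 10.0, 12.4, 14.7, 15.1, 12.5, 13.8, 14.3, 14.4),
    trd_mean = c(34.3, 17.3, 23.3, 21.5, 18.8, 18.8, 47.7, 142.8, 113.4,
                 285.3),
    trd_sd = c(3.1, 1.3, 0.8, 0.2, 1.0, 0.6, 2.7, 3.5, 4.2, 7.5))
}

#' Reference corn-leaf feeding amounts (g, mean +/- SD)
#'
#' Evaporation-corrected corn-leaf consumption per larval instar and rearing
#' temperature; `total` is the whole larval period (per-individual sums).
#'
#' @return Data frame with columns `instar` (`"1"`..`"6"`, `"total"`),
#'   `temperature`, `mean_g`, `sd_g`.
#' @export
sf_feeding_amounts <- function() {
  temps <- c(16, 20, 24, 28, 32, 36)
  rows <- list(
    `1` = list(m = c(0.029, 0.026, 0.008, 0.012, 0.006, 0.027),
               s = c(0.029, 0.029, 0.007, 0.015, 0.005, 0.033)),
    `2` = list(m = c(0.040, 0.026, 0.028, 0.010, 0.009, 0.035),
               s = c(0.034, 0.028, 0.025, 0.010, 0.004, 0.035)),
    `3` = list(m = c(0.164, 0.100, 0.088, 0.104, 0.065, 0.068),
               s = c(0.106, 0.063, 0.084, 0.077, 0.059, 0.039)),
    `4` = list(m = c(0.372, 0.386, 0.364, 0.372, 0.255, 0.239),
               s = c(0.181, 0.154, 0.182, 0.273, 0.117, 0.106)),
    `5` = list(m = c(1.454, 1.172, 0.867, 0.538, 0.567, 0.495),
               s = c(0.335, 0.442, 0.385, 0.237, 0.437, 0.275)),
    `6` = list(m = c(4.526, 4.065, 2.452, 3.640, 2.716, 2.255),
               s = c(0.746, 0.990, 0.593, 1.093, 0.869, 0.403)),
    total = list(m = c(6.610, 5.776, 3.772, 4.678, 3.617, 2.896),
                 s = c(0.973, 0.829, 0.495, 1.195, 0.625, 0.449)))
  do.call(rbind, lapply(names(rows), function(k) {
    data.frame(instar = k, temperature = temps, mean_g = rows[[k]]$m,
               sd_g = rows[[k]]$s)
  }))
}

#' Reference viability percentages by temperature
#'
#' Mean egg-hatch and first-instar-to-adult survival percentages from
#' triplicate cohorts of 100 at each rearing temperature. Hatch means are
#' published only for 24--32 C.
#'
#' @return Data frame with columns `endpoint`, `temperature`, `mean_pct`.
#' @export
sf_viability_summary <- function() {
  data.frame(
    endpoint = c(rep("hatch", 3), rep("larval_survival", 6)),
    temperature = c(24, 28, 32, 16, 20, 24, 28, 32, 36),
    mean_pct = c(84.0, 85.7, 77.3, 31.0, 88.0, 97.3, 99.0, 98.7, 45.3))
}

#' Reference field eclosion records for forecast validation
#'
#' Predicted adult-emergence dates at three Korean field sites (2021 season)
#' with the observed eclosion dates and counts used to score the forecasts.
#'
#' @return Data frame with columns `location`, `predicted_date`,
#'   `observed_date`, `n_eclosions`.
#' @export
sf_observed_eclosion <- function() {
  data.frame(
    location = rep(c("Cheongju", "Boeun", "Taean"), each = 3),
    predicted_date = as.Date(rep(c("2021-09-22", "2021-09-28", "2021-09-16"),
                                 each = 3)),
    observed_date = as.Date(c("2021-09-24", "2021-09-25", "2021-09-26",
                              "2021-09-27", "2021-09-28", "2021-09-29",
                              "2021-09-20", "2021-09-21", "2021-09-22")),
    n_eclosions = c(12, 7, 6, 17, 6, 3, 10, 9, 2))
}
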